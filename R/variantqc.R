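## Variant- and sample-level quality control: fixed filter cascade,
## exact Hardy-Weinberg test, Mendel errors, method-of-moments IBD.

#' Quality-control configuration
#'
#' Defaults mirror a strict WGS rare-variant cleaning protocol: genotyping
#' rate at least 95%, Hardy-Weinberg exact p at least 1e-8, AF at most 1%
#' in at least one reference column, no Mendel errors, and removal of
#' multiallelic sites, monomorphic sites, indels, singletons (dataset- or
#' single-family-private) and any site carrying a half-called genotype.
#'
#' @param call_rate_min per-variant genotyping-rate threshold.
#' @param hwe_p_min exact-test p-value floor.
#' @param af_max reference allele-frequency ceiling.
#' @param mendel_error_max maximum tolerated Mendel errors per variant.
#' @param drop_indels,drop_singletons,drop_half_calls stage switches.
#' @param af_mode `"either"` keeps a variant when AF_all or AF_nfe is
#'   below `af_max` (disjunctive reading); `"both"` requires both.
#' @param sample_call_rate_min per-sample genotyping-rate threshold.
#' @param inbreeding_F_bounds allowed range of the inbreeding coefficient.
#' @param pihat_dup_threshold PI_HAT above which a declared-unrelated pair
#'   is flagged as duplicate/mislabelled.
#' @param pihat_sib_min PI_HAT below which a declared sibling pair is
#'   flagged as a family mismatch.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(call_rate_min = 0.95, hwe_p_min = 1e-8,
                      af_max = 0.01, mendel_error_max = 0,
                      drop_indels = TRUE, drop_singletons = TRUE,
                      drop_half_calls = TRUE, af_mode = c("either", "both"),
                      sample_call_rate_min = 0.95,
                      inbreeding_F_bounds = c(-0.15, 0.15),
                      pihat_dup_threshold = 0.9, pihat_sib_min = 0.2) {
  af_mode <- match.arg(af_mode)
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, af_max > 0, af_max <= 1,
            mendel_error_max >= 0, length(inbreeding_F_bounds) == 2)
  structure(as.list(environment()), class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on the genotype counts given the allele counts:
#' the p-value is the total probability of all heterozygote counts (same
#' allele totals, same parity) whose probability does not exceed that of
#' the observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative counts")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  n1 <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)  # rarer allele
  if (n1 == 0) return(1)
  h <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  n2 <- 2 * n - n1
  lp <- lfactorial(n) - lfactorial((n1 - h) / 2) - lfactorial(h) -
    lfactorial((n2 - h) / 2) + lfactorial(n1) + lfactorial(n2) -
    lfactorial(2 * n) + h * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, h)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Mendelian impossibility lookup: err[p1+1, p2+1, c+1] for dosages 0/1/2
.mendel_table <- local({
  a <- array(FALSE, c(3, 3, 3))
  trans <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (p1 in 0:2) for (p2 in 0:2) {
    poss <- unique(outer(trans[[p1 + 1]], trans[[p2 + 1]], "+"))
    for (cc in 0:2) a[p1 + 1, p2 + 1, cc + 1] <- !(cc %in% poss)
  }
  a
})

#' Count Mendel errors per variant
#'
#' Checks biallelic Mendelian consistency for every genotyped
#' parent-offspring trio or duo in the pedigree. Duos are checked only for
#' impossible transmissions (parent dosage 0 with child 2, or 2 with 0).
#' Missing genotypes skip the check at that site.
#'
#' @param G a [genotype_matrix()].
#' @param ped an `rv_pedigree`.
#' @return integer vector of error counts, one per variant.
#' @export
count_mendel_errors <- function(G, ped) {
  dos <- G$dosage
  errs <- integer(ncol(dos))
  ids <- rownames(dos)
  kids <- ped[ped$iid %in% ids &
                (ped$pat %in% ids | ped$mat %in% ids), , drop = FALSE]
  for (r in seq_len(nrow(kids))) {
    cg <- dos[kids$iid[r], ]
    p1 <- if (!is.na(kids$pat[r]) && kids$pat[r] %in% ids)
      dos[kids$pat[r], ] else rep(NA_integer_, ncol(dos))
    p2 <- if (!is.na(kids$mat[r]) && kids$mat[r] %in% ids)
      dos[kids$mat[r], ] else rep(NA_integer_, ncol(dos))
    trio <- !is.na(cg) & !is.na(p1) & !is.na(p2)
    if (any(trio))
      errs[trio] <- errs[trio] +
        .mendel_table[cbind(p1[trio] + 1L, p2[trio] + 1L, cg[trio] + 1L)]
    for (pp in list(p1, p2)) {
      duo <- !is.na(cg) & !is.na(pp) &
        (is.na(p1) | is.na(p2))             # only when the trio rule is off
      if (any(duo))
        errs[duo] <- errs[duo] +
          ((pp[duo] == 0L & cg[duo] == 2L) | (pp[duo] == 2L & cg[duo] == 0L))
    }
  }
  errs
}

# samples used for the HWE test: founders, samples outside the pedigree,
# and one sibling per family whose parents are not genotyped (sibships
# violate the HWE sampling assumption)
hwe_sample_subset <- function(G, ped) {
  ids <- rownames(G$dosage)
  if (is.null(ped)) return(ids)
  inped <- ped[match(ids, ped$iid), ]
  founder <- !is.na(inped$iid) & is.na(inped$pat) & is.na(inped$mat)
  outside <- is.na(inped$iid)
  keep <- ids[founder | outside]
  sibs <- inped[!founder & !outside, , drop = FALSE]
  if (nrow(sibs)) {
    parent_typed <- (sibs$pat %in% ids) | (sibs$mat %in% ids)
    orphans <- sibs[!parent_typed, , drop = FALSE]
    if (nrow(orphans)) {
      orphans <- orphans[order(orphans$fid, orphans$iid), ]
      keep <- c(keep, orphans$iid[!duplicated(orphans$fid)])
    }
  }
  keep
}

#' Apply the variant quality-control cascade
#'
#' Filters are applied in a fixed order; the report records, per stage,
#' how many variants were removed and how many remain. Stages:
#' (1) multiallelic, (2) monomorphic, (3) indel, (4) singleton — total ALT
#' count 1 or all ALT alleles within a single family, (5) half-call
#' present, (6) Mendel errors, (7) call rate, (8) Hardy-Weinberg exact
#' test (computed on founders/unrelated samples only), (9) reference AF
#' ceiling — variants absent from the AF table are removed, (10) optional
#' allow-list intersection.
#'
#' @param G a [genotype_matrix()].
#' @param ped pedigree (or `NULL` for an unrelated cohort; the
#'   single-family singleton clause and Mendel stage are then inactive).
#' @param af_table data.frame keyed by (chrom, pos, ref, alt) with columns
#'   `AF_all`, `AF_nfe`.
#' @param cfg a [qc_config()].
#' @param allow_list optional character vector of `chrom:pos:ref:alt` keys
#'   to intersect with.
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (data.frame `filter`, `removed`, `remaining`).
#' @export
filter_variants <- function(G, ped = NULL, af_table = NULL,
                            cfg = qc_config(), allow_list = NULL) {
  if (!is.null(af_table) &&
      !all(c("chrom", "pos", "ref", "alt", "AF_all", "AF_nfe") %in%
             names(af_table)))
    stop("AF table must have columns chrom, pos, ref, alt, AF_all, AF_nfe")
  dos <- G$dosage
  nv <- ncol(dos)
  keep <- rep(TRUE, nv)
  report <- data.frame(filter = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(name, drop) {
    drop <- drop & keep
    keep <<- keep & !drop
    report <<- rbind(report, data.frame(filter = name,
                                        removed = sum(drop),
                                        remaining = sum(keep)))
  }

  note("multiallelic", G$variants$multiallelic)

  nonmiss <- colSums(!is.na(dos))
  mono <- vapply(seq_len(nv), function(j) {
    x <- dos[, j]; x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1])
  }, TRUE)
  note("monomorphic", mono)

  indel <- nchar(G$variants$ref) != 1L | nchar(G$variants$alt) != 1L
  note("indel", if (cfg$drop_indels) indel else rep(FALSE, nv))

  ac <- colSums(dos, na.rm = TRUE)
  single_fam <- rep(FALSE, nv)
  if (!is.null(ped)) {
    fam <- ped$fid[match(rownames(dos), ped$iid)]
    fam[is.na(fam)] <- rownames(dos)[is.na(fam)]
    carrier <- dos > 0L & !is.na(dos)
    for (j in which(keep & ac > 0)) {
      fams <- unique(fam[carrier[, j]])
      single_fam[j] <- length(fams) == 1L
    }
  }
  note("singleton",
       if (cfg$drop_singletons) (ac == 1L) | single_fam else rep(FALSE, nv))

  has_half <- rep(FALSE, nv)
  if (nrow(G$half_calls)) has_half[unique(G$half_calls[, 2])] <- TRUE
  note("half_call", if (cfg$drop_half_calls) has_half else rep(FALSE, nv))

  mendel <- rep(0L, nv)
  if (!is.null(ped)) {
    ids <- rownames(dos)
    any_pair <- any(ped$iid %in% ids &
                      (ped$pat %in% ids | ped$mat %in% ids))
    if (any_pair) mendel <- count_mendel_errors(G, ped)
  }
  note("mendel_error", mendel > cfg$mendel_error_max)

  call_rate <- nonmiss / nrow(dos)
  note("call_rate", call_rate < cfg$call_rate_min)

  hwe_ids <- hwe_sample_subset(G, ped)
  hwe_p <- rep(1, nv)
  if (length(hwe_ids)) {
    sub <- dos[hwe_ids, , drop = FALSE]
    for (j in which(keep)) {
      x <- sub[, j]; x <- x[!is.na(x)]
      if (length(x))
        hwe_p[j] <- hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    }
  }
  note("hwe", hwe_p < cfg$hwe_p_min)

  if (!is.null(af_table)) {
    key <- variant_key(G$variants)
    m <- match(key, variant_key(af_table))
    af_all <- af_table$AF_all[m]; af_nfe <- af_table$AF_nfe[m]
    pass_af <- if (cfg$af_mode == "either")
      (af_all <= cfg$af_max) | (af_nfe <= cfg$af_max)
    else (af_all <= cfg$af_max) & (af_nfe <= cfg$af_max)
    pass_af[is.na(m)] <- FALSE
    note("af_reference", !pass_af)
  } else {
    note("af_reference", rep(FALSE, nv))
  }

  if (!is.null(allow_list)) {
    note("allow_list", !(variant_key(G$variants) %in% allow_list))
  } else {
    note("allow_list", rep(FALSE, nv))
  }

  list(genotypes = subset_genotypes(G, variants = keep), report = report)
}

#' Sample-level quality control
#'
#' Flags samples with low call rate, an inbreeding coefficient outside the
#' configured bounds (F = 1 - observed/expected heterozygosity, expected
#' from sample allele frequencies), and pairwise relationships
#' inconsistent with the pedigree: declared siblings with PI_HAT below
#' `pihat_sib_min`, declared-unrelated pairs above `pihat_dup_threshold`.
#' IBD proportions come from a method-of-moments decomposition of
#' identity-by-state counts; PI_HAT = P(IBD=1)/2 + P(IBD=2).
#'
#' @param G a [genotype_matrix()].
#' @param ped pedigree or `NULL`.
#' @param cfg a [qc_config()].
#' @return list with `samples` (per-sample metrics and flags) and `pairs`
#'   (pairwise PI_HAT with declared relation and flags).
#' @export
sample_qc <- function(G, ped = NULL, cfg = qc_config()) {
  dos <- G$dosage
  n <- nrow(dos)
  if (n < 2) stop("sample QC needs at least 2 samples")
  ids <- rownames(dos)
  call_rate <- rowMeans(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  Fhat <- rep(NA_real_, n)
  if (any(poly)) {
    sub <- dos[, poly, drop = FALSE]
    exp_het <- 2 * p[poly] * (1 - p[poly])
    for (i in seq_len(n)) {
      ok <- !is.na(sub[i, ])
      if (any(ok)) {
        e <- sum(exp_het[ok])
        if (e > 0) Fhat[i] <- 1 - sum(sub[i, ok] == 1L) / e
      }
    }
  }
  pairs <- pihat_pairs(dos, p, poly)
  rel <- declared_relation(ids, ped)
  pairs$relation <- rel[cbind(match(pairs$iid1, ids), match(pairs$iid2, ids))]
  pairs$flag <- (pairs$relation == "sib" & pairs$pihat < cfg$pihat_sib_min) |
    (pairs$relation == "unrelated" & pairs$pihat > cfg$pihat_dup_threshold)
  samples <- data.frame(
    iid = ids, call_rate = call_rate, inbreeding_F = Fhat,
    flag_call_rate = call_rate < cfg$sample_call_rate_min,
    flag_inbreeding = !is.na(Fhat) &
      (Fhat < cfg$inbreeding_F_bounds[1] | Fhat > cfg$inbreeding_F_bounds[2]),
    stringsAsFactors = FALSE)
  list(samples = samples, pairs = pairs)
}

# method-of-moments IBD estimates for all sample pairs
pihat_pairs <- function(dos, p, poly) {
  g <- dos[, poly, drop = FALSE]
  pv <- p[poly]; qv <- 1 - pv
  n <- nrow(g)
  A <- lapply(0:2, function(d) { m <- (g == d) & !is.na(g); storage.mode(m) <- "double"; m })
  M <- !is.na(g); storage.mode(M) <- "double"
  N2 <- A[[1]] %*% t(A[[1]]) + A[[2]] %*% t(A[[2]]) + A[[3]] %*% t(A[[3]])
  N0 <- A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]])
  S_pair <- M %*% t(M)
  N1 <- S_pair - N0 - N2
  # expected per-site IBS probabilities given IBD state, summed over sites
  e0_i0 <- sum(2 * pv^2 * qv^2)
  e1_i0 <- sum(4 * pv^3 * qv + 4 * pv * qv^3)
  e2_i0 <- sum(pv^4 + qv^4 + 4 * pv^2 * qv^2)
  e1_i1 <- sum(2 * pv^2 * qv + 2 * pv * qv^2)
  e2_i1 <- sum(pv^3 + qv^3 + pv^2 * qv + pv * qv^2)
  S <- ncol(g)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sc <- S_pair[idx] / S                  # scale expectations for missingness
  P0 <- N0[idx] / (e0_i0 * sc)
  P1 <- (N1[idx] - P0 * e1_i0 * sc) / (e1_i1 * sc)
  P2 <- (N2[idx] - P0 * e2_i0 * sc - P1 * e2_i1 * sc) / S_pair[idx]
  P0 <- pmin(pmax(P0, 0), 1); P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  data.frame(iid1 = rownames(g)[idx[, 1]], iid2 = rownames(g)[idx[, 2]],
             pihat = (P1 / 2 + P2) / ifelse(tot > 0, tot, 1),
             stringsAsFactors = FALSE)
}

declared_relation <- function(ids, ped) {
  n <- length(ids)
  rel <- matrix("unrelated", n, n)
  if (is.null(ped)) return(rel)
  m <- match(ids, ped$iid)
  fid <- ped$fid[m]; pat <- ped$pat[m]; mat <- ped$mat[m]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(m[i]) || is.na(m[j])) next
    pc <- (!is.na(pat[j]) && pat[j] == ids[i]) ||
      (!is.na(mat[j]) && mat[j] == ids[i]) ||
      (!is.na(pat[i]) && pat[i] == ids[j]) ||
      (!is.na(mat[i]) && mat[i] == ids[j])
    sib <- !pc && !is.na(fid[i]) && !is.na(fid[j]) && fid[i] == fid[j] &&
      ((!is.na(pat[i]) && !is.na(pat[j]) && pat[i] == pat[j]) ||
         (!is.na(mat[i]) && !is.na(mat[j]) && mat[i] == mat[j]))
    same_fam <- !is.na(fid[i]) && !is.na(fid[j]) && fid[i] == fid[j]
    rel[i, j] <- rel[j, i] <-
      if (pc) "parent_child" else if (sib) "sib"
    else if (same_fam) "family_other" else "unrelated"
  }
  rel
}
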