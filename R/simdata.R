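## Synthetic cohorts: multiplex sibships and unrelated case-control samples
## carrying rare variants, with a ground-truth record for calibration tests.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults encode the study design the pipeline assumes: multiplex
#' sibships ascertained for at least two affected siblings, rare variants
#' with population allele frequency in (1/(2e4), 0.01], disease prevalence
#' 0.15, and an unrelated case-control cohort with center/age/sex
#' covariates. Optional two-subpopulation structure with a fraction of
#' variants private to each subpopulation emulates stratification.
#'
#' @param n_families number of sibship families.
#' @param sibs_per_family single count or inclusive range `c(lo, hi)`.
#' @param n_cases,n_controls case-control cohort sizes.
#' @param n_chrom number of simulated chromosomes.
#' @param variants_per_chrom rare variants per chromosome (0 allowed).
#' @param af_low,af_high allele-frequency bounds; `af_high` must not
#'   exceed 0.01 (the rare-variant ceiling).
#' @param prevalence population disease prevalence (default 0.15).
#' @param causal_windows list of lists with elements `chrom`, `window`
#'   (index of the 10-variant window on that chromosome), `model`
#'   (`"unidirectional"` or `"mixed"`), `beta` (log-odds per ALT allele).
#' @param window_size variants per window used to index causal windows.
#' @param min_affected_sibs ascertainment condition (default 2).
#' @param n_subpops number of subpopulations (default 1).
#' @param fst_like_divergence fraction of variants private to a single
#'   subpopulation when `n_subpops > 1`.
#' @param n_centers number of sequencing centers for the covariate table.
#' @param center_beta optional log-odds shift for the last center
#'   (covariate effect on disease).
#' @param subpop_beta optional log-odds shift for subpopulations beyond
#'   the first (confounding with structure).
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 100, sibs_per_family = c(2, 4),
                       n_cases = 500, n_controls = 500,
                       n_chrom = 1, variants_per_chrom = 100,
                       af_low = 1 / (2 * 1e4), af_high = 0.01,
                       prevalence = 0.15, causal_windows = list(),
                       window_size = 10, min_affected_sibs = 2,
                       n_subpops = 1, fst_like_divergence = 0.5,
                       n_centers = 2, center_beta = 0, subpop_beta = 0,
                       seed = 1) {
  stopifnot(af_low > 0, af_high <= 0.01, af_low <= af_high,
            prevalence > 0, prevalence < 1,
            n_chrom >= 1, variants_per_chrom >= 0,
            min_affected_sibs >= 0, n_subpops >= 1, window_size >= 1,
            fst_like_divergence >= 0, fst_like_divergence <= 1)
  if (variants_per_chrom != as.integer(variants_per_chrom) ||
      variants_per_chrom < 0)
    stop("configuration error: variants_per_chrom must be a count >= 0")
  for (cw in causal_windows)
    stopifnot(is.finite(cw$beta),
              cw$model %in% c("unidirectional", "mixed"))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a founder haplotype panel
#'
#' Per-variant allele frequencies are drawn uniformly in
#' `[af_low, af_high]`; haplotypes are later drawn as independent
#' Bernoulli(AF) per site within a subpopulation. When `n_subpops > 1`, a
#' fraction `fst_like_divergence` of variants is private to one
#' subpopulation (AF zero elsewhere).
#'
#' @param cfg a [sim_config()].
#' @return object of class `haplotype_panel`: variant table, V x n_subpops
#'   AF matrix, overall AF, and causal-effect metadata.
#' @export
simulate_founder_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  V <- cfg$n_chrom * cfg$variants_per_chrom
  chrom <- rep(as.character(seq_len(cfg$n_chrom)),
               each = cfg$variants_per_chrom)
  pos <- unlist(lapply(seq_len(cfg$n_chrom), function(i)
    10000L + cumsum(sample(50:500, cfg$variants_per_chrom, replace = TRUE))),
    use.names = FALSE)
  if (V == 0L) pos <- integer(0)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  af <- matrix(runif(V, cfg$af_low, cfg$af_high), nrow = V,
               ncol = cfg$n_subpops)
  home <- rep(NA_integer_, V)
  if (cfg$n_subpops > 1 && V > 0) {
    priv <- sample(V, round(cfg$fst_like_divergence * V))
    home[priv] <- sample(cfg$n_subpops, length(priv), replace = TRUE)
    for (v in priv) af[v, -home[v]] <- 0
  }
  variants <- data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                         alt = unname(alt), stringsAsFactors = FALSE)
  panel <- structure(list(variants = variants, af = af,
                          af_overall = rowMeans(af),
                          home_subpop = home, cfg = cfg),
                     class = "haplotype_panel")
  panel$effects <- causal_effects(panel)
  panel$beta0 <- calibrate_intercept(panel)
  panel
}

# signed per-variant log-odds effects from cfg$causal_windows
causal_effects <- function(panel) {
  cfg <- panel$cfg
  beta <- numeric(nrow(panel$variants))
  for (cw in cfg$causal_windows) {
    on_chrom <- which(panel$variants$chrom == as.character(cw$chrom))
    lo <- (cw$window - 1L) * cfg$window_size + 1L
    hi <- min(cw$window * cfg$window_size, length(on_chrom))
    if (lo > length(on_chrom))
      stop("causal window ", cw$window, " on chromosome ", cw$chrom,
           " lies beyond the simulated variant set")
    idx <- on_chrom[lo:hi]
    sgn <- if (cw$model == "mixed")
      rep_len(c(1, -1), length(idx)) else rep(1, length(idx))
    beta[idx] <- sgn * cw$beta
  }
  beta
}

#' Draw founder haplotypes from a panel
#'
#' @param panel a [simulate_founder_panel()] result.
#' @param n number of haplotypes.
#' @param subpop subpopulation index.
#' @return n x V binary matrix (uses the current RNG state).
#' @export
draw_haplotypes <- function(panel, n, subpop = 1) {
  V <- nrow(panel$variants)
  matrix(rbinom(n * V, 1L, rep(panel$af[, subpop], each = n)),
         nrow = n, ncol = V)
}

# intercept of the liability logistic model, solved so that the simulated
# population prevalence matches cfg$prevalence (root finding on a fixed
# Monte-Carlo sample of genetic loads; tolerance 1e-3 on prevalence)
calibrate_intercept <- function(panel, n_ref = 20000L) {
  cfg <- panel$cfg
  if (all(panel$effects == 0)) return(qlogis(cfg$prevalence))
  idx <- which(panel$effects != 0)
  sub <- rep_len(seq_len(cfg$n_subpops), n_ref)
  load <- numeric(n_ref)
  for (s in seq_len(cfg$n_subpops)) {
    rows <- which(sub == s)
    g <- matrix(rbinom(2L * length(rows) * length(idx), 1L,
                       rep(panel$af[idx, s], each = 2L * length(rows))),
                nrow = 2L * length(rows))
    dose <- g[seq_along(rows), , drop = FALSE] +
      g[length(rows) + seq_along(rows), , drop = FALSE]
    load[rows] <- as.vector(dose %*% panel$effects[idx])
  }
  f <- function(b0) mean(plogis(b0 + load)) - cfg$prevalence
  uniroot(f, c(-30, 30), tol = 1e-6)$root
}

#' Simulate ascertained multiplex sibship families
#'
#' Each family has two founder parents drawn from the panel; every sibling
#' receives one haplotype per parent by fair Mendelian transmission with no
#' recombination within a chromosome's simulated span (preserving
#' within-window LD). Affection is Bernoulli on the logistic liability
#' scale with the calibrated intercept; families are redrawn until at
#' least `min_affected_sibs` siblings are affected. Parent genotypes are
#' masked by default (sibling-based design); the pedigree always records
#' the family structure.
#'
#' @param cfg a [sim_config()].
#' @param panel a [simulate_founder_panel()] result.
#' @param keep_parents also emit parental genotype rows (for Mendel-error
#'   QC tests)?
#' @param max_attempts rejection-sampling cap per family.
#' @return list with `genotypes` ([genotype_matrix()]), `pedigree`,
#'   `phenotypes` (siblings only), `truth`.
#' @export
simulate_families <- function(cfg, panel, keep_parents = FALSE,
                              max_attempts = 1e5) {
  stopifnot(inherits(panel, "haplotype_panel"), nrow(panel$variants) > 0)
  set.seed(derive_seed(cfg$seed, 2L))
  V <- nrow(panel$variants)
  chrom_idx <- split(seq_len(V), panel$variants$chrom)
  nsib_draw <- function() {
    if (length(cfg$sibs_per_family) == 1L) cfg$sibs_per_family
    else sample(cfg$sibs_per_family[1]:cfg$sibs_per_family[2], 1L)
  }
  ped_rows <- vector("list", cfg$n_families)
  gts <- list(); phen <- list(); subl <- character(0)
  for (f in seq_len(cfg$n_families)) {
    sp <- ((f - 1L) %% cfg$n_subpops) + 1L
    ns <- nsib_draw()
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      hap <- draw_haplotypes(panel, 4L, sp)      # rows: fa1 fa2 mo1 mo2
      sib <- matrix(0L, nrow = ns, ncol = V)
      for (ci in chrom_idx) {
        fa <- sample(2L, ns, replace = TRUE)
        mo <- sample(2L, ns, replace = TRUE) + 2L
        sib[, ci] <- hap[fa, ci, drop = FALSE] + hap[mo, ci, drop = FALSE]
      }
      pr <- plogis(panel$beta0 + as.vector(sib %*% panel$effects))
      aff <- rbinom(ns, 1L, pr)
      if (sum(aff) >= cfg$min_affected_sibs) { ok <- TRUE; break }
    }
    if (!ok)
      stop("ascertainment failed for family ", f, " after ", max_attempts,
           " attempts: could not obtain >= ", cfg$min_affected_sibs,
           " affected siblings (prevalence ", cfg$prevalence, ")")
    fid <- sprintf("F%04d", f)
    sib_ids <- sprintf("%s_S%d", fid, seq_len(ns))
    pa <- paste0(fid, "_P1"); ma <- paste0(fid, "_P2")
    ped_rows[[f]] <- data.frame(
      fid = fid,
      iid = c(pa, ma, sib_ids),
      pat = c(NA, NA, rep(pa, ns)),
      mat = c(NA, NA, rep(ma, ns)),
      sex = c(1L, 2L, sample(1:2, ns, replace = TRUE)),
      affected = c(NA, NA, aff), stringsAsFactors = FALSE)
    rows <- sib
    ids <- sib_ids
    if (keep_parents) {
      rows <- rbind(hap[1, ] + hap[2, ], hap[3, ] + hap[4, ], sib)
      ids <- c(pa, ma, sib_ids)
    }
    rownames(rows) <- ids
    gts[[f]] <- rows
    phen[[f]] <- data.frame(iid = sib_ids, affection = aff,
                            stringsAsFactors = FALSE)
    subl <- c(subl, setNames(rep(sp, length(ids)), ids))
  }
  ped <- do.call(rbind, ped_rows)
  G <- genotype_matrix(do.call(rbind, gts), panel$variants, sort = FALSE)
  truth <- make_truth(panel, setNames(as.integer(subl), names(subl)))
  list(genotypes = G,
       pedigree = pedigree(ped$fid, ped$iid, ped$pat, ped$mat, ped$sex,
                           ped$affected),
       phenotypes = do.call(rbind, phen), truth = truth)
}

#' Simulate an unrelated case-control cohort with covariates
#'
#' Individuals are drawn from the panel (two independent haplotypes each),
#' disease status from the same logistic liability model, and sampled
#' until the case and control quotas are filled. Covariates: sequencing
#' center (categorical), sex, and age — controls are 60 or older.
#'
#' @inheritParams simulate_families
#' @return list with `genotypes`, `phenotypes`, `covariates`, `truth`.
#' @export
simulate_case_control <- function(cfg, panel, max_attempts = 2000) {
  stopifnot(inherits(panel, "haplotype_panel"), nrow(panel$variants) > 0)
  set.seed(derive_seed(cfg$seed, 3L))
  need <- c(cases = cfg$n_cases, controls = cfg$n_controls)
  got <- list(cases = list(), controls = list())
  meta <- list(cases = list(), controls = list())
  # expected draws needed per quota, with head-room
  batch <- ceiling(1.3 * max(cfg$n_cases / cfg$prevalence,
                             cfg$n_controls / (1 - cfg$prevalence), 64))
  batch <- min(batch, 20000L)
  for (att in seq_len(max_attempts)) {
    ncase <- sum(vapply(got$cases, nrow, 0L))
    nctrl <- sum(vapply(got$controls, nrow, 0L))
    if (ncase >= need["cases"] && nctrl >= need["controls"]) break
    sp <- rep_len(seq_len(cfg$n_subpops), batch)
    dose <- matrix(0L, batch, nrow(panel$variants))
    for (s in seq_len(cfg$n_subpops)) {
      rows <- which(sp == s)
      h1 <- matrix(rbinom(length(rows) * nrow(panel$variants), 1L,
                          rep(panel$af[, s], each = length(rows))),
                   nrow = length(rows))
      h2 <- matrix(rbinom(length(rows) * nrow(panel$variants), 1L,
                          rep(panel$af[, s], each = length(rows))),
                   nrow = length(rows))
      dose[rows, ] <- h1 + h2
    }
    center <- sample(cfg$n_centers, batch, replace = TRUE)
    eta <- panel$beta0 + as.vector(dose %*% panel$effects) +
      cfg$center_beta * (center == cfg$n_centers) +
      cfg$subpop_beta * (sp > 1L)
    aff <- rbinom(batch, 1L, plogis(eta))
    for (lab in c("cases", "controls")) {
      want <- if (lab == "cases") aff == 1L else aff == 0L
      idx <- which(want)
      if (!length(idx)) next
      got[[lab]] <- c(got[[lab]], list(dose[idx, , drop = FALSE]))
      meta[[lab]] <- c(meta[[lab]], list(
        data.frame(center = center[idx], subpop = sp[idx],
                   affection = aff[idx])))
    }
  }
  ncase <- sum(vapply(got$cases, nrow, 0L))
  nctrl <- sum(vapply(got$controls, nrow, 0L))
  if (ncase < need["cases"] || nctrl < need["controls"])
    stop("case-control sampling failed after ", max_attempts,
         " batches: obtained ", ncase, "/", need["cases"], " cases and ",
         nctrl, "/", need["controls"], " controls (prevalence ",
         cfg$prevalence, ")")
  take <- function(lab) {
    d <- do.call(rbind, got[[lab]])[seq_len(need[[lab]]), , drop = FALSE]
    m <- do.call(rbind, meta[[lab]])[seq_len(need[[lab]]), , drop = FALSE]
    list(d = d, m = m)
  }
  ca <- take("cases"); co <- take("controls")
  n <- nrow(ca$d) + nrow(co$d)
  ids <- sprintf("CC%05d", seq_len(n))
  dose <- rbind(ca$d, co$d); rownames(dose) <- ids
  m <- rbind(ca$m, co$m)
  age <- integer(n)
  is_case <- m$affection == 1L
  age[is_case] <- as.integer(round(runif(sum(is_case), 55, 90)))
  age[!is_case] <- as.integer(round(runif(sum(!is_case), 60, 90)))
  covar <- data.frame(iid = ids, center = paste0("C", m$center),
                      age = age, sex = sample(1:2, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  G <- genotype_matrix(dose, panel$variants, sort = FALSE)
  truth <- make_truth(panel, setNames(m$subpop, ids))
  list(genotypes = G,
       phenotypes = data.frame(iid = ids, affection = m$affection,
                               stringsAsFactors = FALSE),
       covariates = covar, truth = truth)
}

make_truth <- function(panel, subpop_labels) {
  cfg <- panel$cfg
  list(af = panel$af_overall,
       af_by_subpop = panel$af,
       causal_windows = cfg$causal_windows,
       effect_signs = sign(panel$effects),
       effect_beta = panel$effects,
       beta0 = panel$beta0,
       subpop = subpop_labels,
       variant_key = variant_key(panel$variants))
}

#' Write a simulated cohort to disk
#'
#' Emits VCF v4.2 genotypes, a 6-column PED, phenotype and covariate TSVs,
#' an allele-frequency reference TSV (`AF_all`, `AF_nfe` both set to the
#' true simulated AF — a local stand-in for an external AF database) and a
#' truth JSON.
#'
#' @param sim result of [simulate_families()] or [simulate_case_control()].
#' @param panel the generating panel.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return named character vector of the files written.
#' @export
write_cohort <- function(sim, panel, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  out <- c(vcf = p(".vcf"), pheno = p(".pheno.tsv"), af = p(".af.tsv"),
           truth = p(".truth.json"))
  write_vcf(sim$genotypes, out["vcf"])
  write_tsv(sim$phenotypes, out["pheno"])
  write_tsv(af_reference(panel), out["af"])
  tr <- sim$truth
  tr$subpop <- as.list(tr$subpop)
  jsonlite::write_json(tr, out["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$pedigree)) {
    out["ped"] <- p(".ped")
    write_pedigree(sim$pedigree, out["ped"])
  }
  if (!is.null(sim$covariates)) {
    out["covar"] <- p(".covar.tsv")
    write_tsv(sim$covariates, out["covar"])
  }
  out
}

#' @rdname write_cohort
#' @export
af_reference <- function(panel) {
  data.frame(chrom = panel$variants$chrom, pos = panel$variants$pos,
             ref = panel$variants$ref, alt = panel$variants$alt,
             AF_all = panel$af_overall, AF_nfe = panel$af_overall,
             stringsAsFactors = FALSE)
}
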