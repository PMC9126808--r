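## Family-based region tests: burden and variance-component statistics on
## sibships, with p-values from the exact or Monte-Carlo within-family
## conditional permutation null.

#' Configuration for family-based region tests
#'
#' The phenotype enters as the trait residual: affection status (0/1)
#' minus an offset equal to the population prevalence, so unaffected
#' siblings contribute information. The null distribution conditions on
#' the observed multiset of sibling genotype rows within each family
#' (offspring multi-locus genotypes are exchangeable given the parents),
#' preserving all within-window LD.
#'
#' @param offset constant subtracted from 0/1 affection (default 0.15,
#'   the assumed population prevalence).
#' @param n_sims Monte-Carlo simulation budget (>= 1e3).
#' @param seed integer seed for the scan's permutation streams.
#' @param weighting `"flat"` (all weights 1) or `"beta"`
#'   (Madsen-Browning-style Beta(AF; 1, 25) weights from sample AF).
#' @param burden_alternative `"two.sided"` (deviation from the permutation
#'   mean) or `"greater"`.
#' @param exact_cap maximum number of permutation configurations for
#'   exhaustive enumeration; larger windows fall back to Monte Carlo.
#' @param min_exceed optional sequential stopping rule: stop the
#'   Monte-Carlo stream once both tests have this many exceedances
#'   (`Inf` = fixed-budget estimator).
#' @return list of class `region_test_config`.
#' @export
region_test_config <- function(offset = 0.15, n_sims = 1e6, seed = 1,
                               weighting = c("flat", "beta"),
                               burden_alternative = c("two.sided", "greater"),
                               exact_cap = 1e5, min_exceed = Inf) {
  weighting <- match.arg(weighting)
  burden_alternative <- match.arg(burden_alternative)
  stopifnot(offset > 0, offset < 1, n_sims >= 1e3, exact_cap >= 1,
            min_exceed >= 1)
  structure(as.list(environment()), class = "region_test_config")
}

#' Build per-family sibling blocks
#'
#' Siblings are pedigree members with at least one recorded parent,
#' genotyped and with non-missing affection. Residuals are
#' `affection - offset`. Missing dosages are imputed to the within-family
#' mean of the variant (genome-wide, before windowing).
#'
#' @param G a [genotype_matrix()].
#' @param ped an `rv_pedigree`.
#' @param phenotypes optional data.frame (`iid`, `affection`) overriding
#'   the pedigree affection column.
#' @param offset trait-residual offset.
#' @return list of family blocks: each has `fid`, `ids`, `t` (residuals)
#'   and `g` (sibling-by-variant dosage matrix, imputed).
#' @export
family_blocks <- function(G, ped, phenotypes = NULL, offset = 0.15) {
  ids <- rownames(G$dosage)
  aff <- ped$affected
  if (!is.null(phenotypes)) {
    m <- match(ped$iid, phenotypes$iid)
    aff <- ifelse(is.na(m), aff, phenotypes$affection[m])
  }
  sib <- !is.na(ped$pat) | !is.na(ped$mat)
  use <- sib & ped$iid %in% ids & !is.na(aff)
  blocks <- lapply(split(which(use), ped$fid[use]), function(rows) {
    g <- G$dosage[ped$iid[rows], , drop = FALSE]
    storage.mode(g) <- "double"
    if (anyNA(g))
      for (j in which(colSums(is.na(g)) > 0)) {
        mu <- mean(g[, j], na.rm = TRUE)
        g[is.na(g[, j]), j] <- if (is.nan(mu)) 0 else mu
      }
    list(fid = ped$fid[rows[1]], ids = ped$iid[rows],
         t = aff[rows] - offset, g = g)
  })
  unname(blocks)
}

#' Burden and per-variant score contributions of one family
#'
#' `B_f = sum_i t_i * sum_v w_v g_iv` and
#' `S_fv = sum_i t_i (g_iv - gbar_fv)` with `gbar_fv` the within-family
#' mean dosage.
#'
#' @param fam a family block from [family_blocks()].
#' @param weights per-variant weights (default flat).
#' @return list with scalar `B` and vector `S`.
#' @export
family_scores <- function(fam, weights = NULL) {
  if (ncol(fam$g) == 0L) stop("empty window")
  w <- if (is.null(weights)) rep(1, ncol(fam$g)) else weights
  gbar <- colMeans(fam$g)
  list(B = sum(fam$t * as.vector(fam$g %*% w)),
       S = as.vector(fam$t %*% sweep(fam$g, 2, gbar)))
}

#' Resample a family under the conditional null
#'
#' Permutes the genotype rows uniformly at random among the siblings,
#' keeping phenotypes fixed; the multiset of rows (hence all
#' between-variant LD within rows) is preserved exactly. Families of one
#' sibling are returned unchanged and marked non-informative.
#'
#' @param fam a family block.
#' @return the block with permuted rows and an `informative` flag.
#' @export
null_resample <- function(fam) {
  s <- length(fam$t)
  if (s < 2) { fam$informative <- FALSE; return(fam) }
  fam$g <- fam$g[sample.int(s), , drop = FALSE]
  fam$informative <- TRUE
  fam
}

informative_family <- function(fam) {
  length(fam$t) >= 2 && var(fam$t) > 0 &&
    any(apply(fam$g, 2, function(x) length(unique(x)) > 1))
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

#' Family-based region test
#'
#' Computes the region burden statistic `B = sum_f B_f` and the
#' variance-component statistic `Q = sum_v w_v^2 (sum_f S_fv)^2`, then
#' obtains p-values from independent within-family permutations of the
#' sibling genotype rows. If the total number of permutation
#' configurations is at most `cfg$exact_cap` the null is enumerated
#' exhaustively; otherwise Monte Carlo with the add-one estimator
#' `(1 + #extreme) / (1 + n_sims)`. Both tests consume the same
#' permutation stream. The burden p-value is two-sided by default
#' (deviation from the exact permutation mean); the variance-component
#' test is one-sided upper.
#'
#' @param families list of family blocks (full-genome columns).
#' @param window one row of a [build_windows()] table, or `NULL` to test
#'   all columns of the blocks as one region.
#' @param cfg a [region_test_config()].
#' @param weights optional per-variant weights for the window.
#' @return list of class `family_region_result`: `window_id`, `B`, `Q`,
#'   `p_burden`, `p_skat`, `method`, `n_sims`, `n_informative`,
#'   `degenerate`.
#' @export
region_test <- function(families, window = NULL, cfg = region_test_config(),
                        weights = NULL) {
  if (!is.null(window)) {
    vidx <- window$vidx_start:window$vidx_end
    families <- lapply(families, function(f) {
      f$g <- f$g[, vidx, drop = FALSE]; f
    })
  }
  V <- ncol(families[[1]]$g)
  if (V == 0L) stop("empty window")
  w <- if (is.null(weights)) rep(1, V) else weights
  stopifnot(length(w) == V, all(w >= 0))
  info <- vapply(families, informative_family, TRUE)
  obs <- lapply(families, family_scores, weights = w)
  B_obs <- sum(vapply(obs, `[[`, 0, "B"))
  S_tot <- Reduce(`+`, lapply(obs, `[[`, "S"))
  Q_obs <- sum(w^2 * S_tot^2)
  res <- list(window_id = if (is.null(window)) NA_character_ else
                window$window_id,
              B = B_obs, Q = Q_obs, n_informative = sum(info))
  if (!any(info)) {
    res <- c(res, list(p_burden = 1, p_skat = 1, method = "degenerate",
                       n_sims = 0, degenerate = TRUE))
    class(res) <- "family_region_result"
    return(res)
  }
  fams <- families[info]
  # family-centered pieces: deviations from the exact permutation mean
  cen <- lapply(fams, function(f) {
    gc <- sweep(f$g, 2, colMeans(f$g))
    # cc has mean zero across siblings because the gc columns do
    list(t = f$t, gc = gc, cc = as.vector(gc %*% w))
  })
  Bdev_obs <- sum(vapply(cen, function(z) sum(z$t * z$cc), 0))
  # observed Q restricted to informative families must include the
  # non-informative families' S contributions, which are all zero vectors
  # (constant residuals or constant rows), so Q_obs is unchanged.
  two_sided <- cfg$burden_alternative == "two.sided"
  n_cfg <- prod(vapply(fams, function(f) factorial(length(f$t)), 0))
  if (is.finite(n_cfg) && n_cfg <= cfg$exact_cap) {
    Btot <- 0; Stot <- matrix(0, 1, V)
    for (z in cen) {
      P <- perms(length(z$t))
      Bf <- apply(P, 1, function(p) sum(z$t * z$cc[p]))
      Sf <- t(apply(P, 1, function(p) as.vector(z$t %*% z$gc[p, , drop = FALSE])))
      if (V == 1L) Sf <- matrix(Sf, ncol = 1)
      m0 <- length(Btot); m1 <- length(Bf)
      Btot <- rep(Btot, times = m1) + rep(Bf, each = m0)
      Stot <- Stot[rep(seq_len(m0), times = m1), , drop = FALSE] +
        Sf[rep(seq_len(m1), each = m0), , drop = FALSE]
    }
    Qtot <- as.vector(Stot^2 %*% w^2)
    tolb <- 1e-9 * (1 + abs(Bdev_obs)); tolq <- 1e-9 * (1 + Q_obs)
    pb <- if (two_sided) mean(abs(Btot) >= abs(Bdev_obs) - tolb)
          else mean(Btot >= Bdev_obs - tolb)
    ps <- mean(Qtot >= Q_obs - tolq)
    res <- c(res, list(p_burden = pb, p_skat = ps, method = "exact",
                       n_sims = n_cfg, degenerate = FALSE))
  } else {
    mc <- fam_mc(lapply(cen, `[[`, "t"), lapply(cen, `[[`, "gc"),
                 lapply(cen, `[[`, "cc"), w^2, Bdev_obs, Q_obs,
                 cfg$n_sims, cfg$min_exceed, two_sided)
    res <- c(res, list(p_burden = (1 + mc$k_burden) / (1 + mc$n_used),
                       p_skat = (1 + mc$k_skat) / (1 + mc$n_used),
                       method = "monte_carlo", n_sims = mc$n_used,
                       degenerate = FALSE))
  }
  class(res) <- "family_region_result"
  res
}

#' Scan all windows with the family-based region tests
#'
#' One result row per window. Each window's permutation stream is seeded
#' from `(cfg$seed, window index)` so results are order-independent and
#' reproducible. Per-window failures are recorded and the scan continues.
#'
#' @param G post-QC [genotype_matrix()].
#' @param ped pedigree.
#' @param phenotypes optional phenotype table (`iid`, `affection`).
#' @param windows a [build_windows()] table.
#' @param cfg a [region_test_config()].
#' @return data.frame with window metadata, `B`, `Q`, `p_burden`,
#'   `p_skat`, `method`, `n_sims`, `n_informative`, `degenerate`.
#' @export
scan_family_genome <- function(G, ped, phenotypes = NULL, windows = NULL,
                               cfg = region_test_config()) {
  if (is.null(windows)) windows <- build_windows(G$variants)
  blocks <- family_blocks(G, ped, phenotypes, offset = cfg$offset)
  if (!length(blocks)) stop("no sibling blocks found")
  af <- colMeans(G$dosage, na.rm = TRUE) / 2
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wrow <- windows[i, ]
    set.seed(derive_seed(cfg$seed, i))
    wts <- if (cfg$weighting == "beta") {
      a <- af[wrow$vidx_start:wrow$vidx_end]
      dbeta(pmin(pmax(a, 1e-12), 1 - 1e-12), 1, 25)
    } else NULL
    r <- tryCatch(region_test(blocks, wrow, cfg, weights = wts),
                  error = function(e) e)
    rows[[i]] <- if (inherits(r, "error")) {
      message("window ", wrow$window_id, " failed: ", conditionMessage(r))
      data.frame(window_id = wrow$window_id, B = NA_real_, Q = NA_real_,
                 p_burden = NA_real_, p_skat = NA_real_, method = "error",
                 n_sims = 0, n_informative = 0, degenerate = NA)
    } else {
      data.frame(window_id = r$window_id, B = r$B, Q = r$Q,
                 p_burden = r$p_burden, p_skat = r$p_skat,
                 method = r$method, n_sims = r$n_sims,
                 n_informative = r$n_informative, degenerate = r$degenerate)
    }
  }
  out <- cbind(windows[c("window_id", "chrom", "first_snv", "last_snv",
                         "n_variants")],
               do.call(rbind, rows)[-1])
  rownames(out) <- NULL
  out
}

#' Madsen-Browning-style variant weights
#'
#' Beta(AF; 1, 25) density weights that up-weight the rarest variants.
#'
#' @param af sample allele frequencies.
#' @return numeric weight vector.
#' @export
mb_weights <- function(af) dbeta(pmin(pmax(af, 1e-12), 1 - 1e-12), 1, 25)
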