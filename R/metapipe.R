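## Meta-analysis (Fisher's combined probability), thresholds, report
## assembly, Manhattan data, and pipeline orchestration.

#' Upper tail of the chi-square distribution
#'
#' @param x statistic (>= 0).
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_survival <- function(x, df) {
  if (any(x < 0)) stop("negative chi-square statistic")
  stopifnot(df >= 1)
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values as `X2 = -2 sum log p_i`, chi-square
#' with `2k` degrees of freedom.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return list of class `meta_result`: `p_values`, `statistic`, `df`,
#'   `p_combined`.
#' @export
fisher_combine <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p))
  structure(list(p_values = p, statistic = x2, df = 2L * length(p),
                 p_combined = chi2_survival(x2, 2L * length(p))),
            class = "meta_result")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (windows).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Assemble the discovery/replication/meta report
#'
#' Keeps windows whose discovery burden or variance-component p-value is
#' at or below the suggestive threshold, attaches each replication
#' cohort's p-value (burden rows use the cohort burden test,
#' variance-component rows the SKAT-O test) and number of variants used,
#' combines discovery with the configured ethnically-comparable cohorts
#' by Fisher's method, and flags windows whose combined p falls below the
#' Bonferroni threshold.
#'
#' @param discovery a [scan_family_genome()] result table.
#' @param replication named list of [scan_cc_genome()]-style tables.
#' @param meta_cohorts names of replication cohorts entering the
#'   meta-analysis (default: all).
#' @param suggestive discovery screening threshold (default 5e-6).
#' @param alpha family-wise level for the Bonferroni flag.
#' @param n_tests number of windows scanned (defaults to
#'   `nrow(discovery)`).
#' @return data.frame, one row per (window, test) passing the screen.
#' @export
assemble_results <- function(discovery, replication = list(),
                             meta_cohorts = names(replication),
                             suggestive = 5e-6, alpha = 0.05,
                             n_tests = nrow(discovery)) {
  for (nm in names(replication)) {
    missing <- setdiff(discovery$window_id, replication[[nm]]$window_id)
    if (length(missing))
      stop("replication table '", nm, "' lacks window(s): ",
           paste(head(missing, 10), collapse = ", "))
  }
  bthr <- bonferroni_threshold(alpha, max(n_tests, 1))
  rows <- list()
  for (test in c("burden", "skat")) {
    pcol <- paste0("p_", test)
    hits <- discovery[!is.na(discovery[[pcol]]) &
                        discovery[[pcol]] <= suggestive, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      row <- data.frame(test = test, window_id = h$window_id,
                        chrom = h$chrom, first_snv = h$first_snv,
                        last_snv = h$last_snv,
                        p_discovery = h[[pcol]], n_sims = h$n_sims,
                        stringsAsFactors = FALSE)
      meta_p <- h[[pcol]]
      for (nm in names(replication)) {
        r <- replication[[nm]][replication[[nm]]$window_id == h$window_id, ]
        rp <- if (test == "burden") r$p_burden else r$p_skato
        row[[paste0("p_", nm)]] <- rp
        row[[paste0("n_used_", nm)]] <- r$n_used
        if (nm %in% meta_cohorts) meta_p <- c(meta_p, rp)
      }
      if (length(meta_p) >= 2) {
        mr <- fisher_combine(meta_p)
        row$fisher_stat <- mr$statistic
        row$p_meta <- mr$p_combined
      } else {
        row$fisher_stat <- NA_real_
        row$p_meta <- NA_real_
      }
      row$genomewide <- !is.na(row$p_meta) && row$p_meta < bthr
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(test = character(0), window_id = character(0),
                      chrom = character(0), first_snv = character(0),
                      last_snv = character(0), p_discovery = numeric(0),
                      fisher_stat = numeric(0), p_meta = numeric(0),
                      genomewide = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Manhattan-plot data table
#'
#' Per window: chromosome, genomic midpoint, cumulative genome
#' coordinate, and `-log10 p` for every p-value column present. The
#' suggestive reference line (5e-6 by default) is attached as the
#' `suggestive` attribute and column.
#'
#' @param scan a scan result table with `first_snv`/`last_snv` keys.
#' @param suggestive reference threshold.
#' @return data.frame with one row per window.
#' @export
manhattan_table <- function(scan, suggestive = 5e-6) {
  pcols <- intersect(c("p_burden", "p_skat", "p_skato"), names(scan))
  if (nrow(scan) == 0L) {
    out <- data.frame(window_id = character(0), chrom = character(0),
                      pos_mid = numeric(0), cum_pos = numeric(0))
    for (pc in pcols) out[[paste0("neglog10_", pc)]] <- numeric(0)
    out$suggestive <- numeric(0)
    attr(out, "suggestive") <- suggestive
    return(out)
  }
  pos1 <- as.numeric(vapply(strsplit(scan$first_snv, ":"), `[`, "", 2))
  pos2 <- as.numeric(vapply(strsplit(scan$last_snv, ":"), `[`, "", 2))
  mid <- (pos1 + pos2) / 2
  chroms <- unique(scan$chrom)
  span <- vapply(chroms, function(cc) max(pos2[scan$chrom == cc]), 0)
  offset <- setNames(c(0, cumsum(span))[seq_along(chroms)], chroms)
  out <- data.frame(window_id = scan$window_id, chrom = scan$chrom,
                    pos_mid = mid,
                    cum_pos = offset[scan$chrom] + mid,
                    stringsAsFactors = FALSE)
  for (pc in pcols) out[[paste0("neglog10_", pc)]] <- -log10(scan[[pc]])
  out$suggestive <- -log10(suggestive)
  rownames(out) <- NULL
  attr(out, "suggestive") <- suggestive
  out
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and thresholds for
#' [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param qc a [qc_config()].
#' @param fam a [region_test_config()].
#' @param prune a [prune_config()].
#' @param k window size in variants.
#' @param alpha replication / family-wise significance level.
#' @param suggestive discovery screening threshold.
#' @param n_pcs Jaccard PCs used as replication covariates.
#' @param use_pcs include rare-variant PCs in the replication model?
#' @param seed master seed (stage seeds are derived from it).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            fam = region_test_config(), prune = prune_config(),
                            k = 10, alpha = 0.05, suggestive = 5e-6,
                            n_pcs = 4, use_pcs = TRUE, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, suggestive > 0, suggestive < 1, k >= 1)
  sim$seed <- seed
  fam$seed <- derive_seed(seed, 101L)
  prune$seed <- derive_seed(seed, 102L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic discovery-replication pipeline
#'
#' Simulates a family discovery cohort and a case-control replication
#' cohort from one founder panel, applies the QC cascade to each, builds
#' 10-variant windows on the post-QC discovery variants, runs the
#' family-based scan, computes rare-variant Jaccard PCs for the
#' replication cohort, replays each discovery window on the replication
#' samples (using only the window's variants that are present and pass
#' QC there), meta-analyses with Fisher's method and assembles the
#' report.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for TSV outputs.
#' @return list with `report`, `discovery`, `replication`, `manhattan`,
#'   `windows`, `qc_discovery`, `qc_replication`, `pcs`, `truth`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  panel <- simulate_founder_panel(cfg$sim)
  famc <- simulate_families(cfg$sim, panel)
  ccc <- simulate_case_control(cfg$sim, panel)
  af <- af_reference(panel)

  qc_fam <- filter_variants(famc$genotypes, famc$pedigree, af, cfg$qc)
  qc_cc <- filter_variants(ccc$genotypes, NULL, af, cfg$qc)

  windows <- build_windows(qc_fam$genotypes$variants, k = cfg$k)
  discovery <- scan_family_genome(qc_fam$genotypes, famc$pedigree,
                                  famc$phenotypes, windows, cfg$fam)

  covar <- ccc$covariates
  pcs <- NULL
  if (cfg$use_pcs && ncol(qc_cc$genotypes$dosage) >= 2) {
    pcs <- rare_variant_pcs(qc_cc$genotypes, cfg$prune, k = cfg$n_pcs)
    covar <- merge(covar, pcs$pcs, by = "iid", sort = FALSE)
  }
  replication <- replicate_windows(qc_cc$genotypes, ccc$phenotypes, covar,
                                   windows, qc_fam$genotypes$variants,
                                   n_pcs = cfg$n_pcs)

  report <- assemble_results(discovery, list(cc = replication),
                             suggestive = cfg$suggestive,
                             alpha = cfg$alpha, n_tests = nrow(windows))
  manhattan <- manhattan_table(discovery, cfg$suggestive)
  out <- list(report = report, discovery = discovery,
              replication = replication, manhattan = manhattan,
              windows = windows, qc_discovery = qc_fam$report,
              qc_replication = qc_cc$report, pcs = pcs,
              truth = famc$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(discovery, file.path(out_dir, "discovery.tsv"))
    write_results(replication, file.path(out_dir, "replication.tsv"))
    write_results(report, file.path(out_dir, "report.tsv"))
    write_results(manhattan, file.path(out_dir, "manhattan.tsv"))
    write_tsv(qc_fam$report, file.path(out_dir, "qc_discovery.tsv"))
    write_tsv(qc_cc$report, file.path(out_dir, "qc_replication.tsv"))
    write_windows(windows, file.path(out_dir, "windows.tsv"))
  }
  out
}

#' Replay discovery windows on a replication cohort
#'
#' For each discovery window, tests the subset of its variants present
#' (and passing QC) in the replication genotype matrix; absent variants
#' are dropped, not imputed. Windows with no usable variant get p = 1 and
#' zero variants used.
#'
#' @param G post-QC replication [genotype_matrix()].
#' @param phenotypes,covariates replication phenotype/covariate tables.
#' @param windows discovery window table.
#' @param disc_variants discovery post-QC variant table the windows index.
#' @param n_pcs PCs used from the covariate table.
#' @return data.frame: `window_id`, `p_burden`, `p_skat`, `p_skato`,
#'   `n_used`.
#' @export
replicate_windows <- function(G, phenotypes, covariates, windows,
                              disc_variants, n_pcs = 4) {
  ids <- rownames(G$dosage)
  y <- phenotypes$affection[match(ids, phenotypes$iid)]
  X <- if (is.null(covariates)) NULL else
    cc_design(covariates[match(ids, covariates$iid), , drop = FALSE], n_pcs)
  null <- suppressWarnings(fit_null(y, X, warn_small = FALSE))
  disc_keys <- variant_key(disc_variants)
  repl_keys <- variant_key(G$variants)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    wrow <- windows[i, ]
    keys <- disc_keys[wrow$vidx_start:wrow$vidx_end]
    idx <- match(keys, repl_keys)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      Gw <- impute_window(G$dosage[, idx, drop = FALSE])
      use <- apply(Gw, 2, var) > 0
      idx <- idx[use]
    }
    if (!length(idx))
      return(data.frame(window_id = wrow$window_id, p_burden = 1,
                        p_skat = 1, p_skato = 1, n_used = 0L))
    Gw <- impute_window(G$dosage[, idx, drop = FALSE])
    r <- skato_test(null, Gw)
    data.frame(window_id = wrow$window_id, p_burden = r$p_burden,
               p_skat = r$p_skat, p_skato = r$p_skato,
               n_used = length(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
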