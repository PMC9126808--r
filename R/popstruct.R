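## Rare-variant population structure: LD pruning, random subsampling,
## Jaccard similarity and principal components.

#' Pruning / subsampling configuration
#'
#' @param r2_max maximum squared Pearson correlation of dosages allowed
#'   within a block (default 0.01).
#' @param window sliding block size in variants.
#' @param step block advance in variants.
#' @param m number of variants randomly subsampled after pruning (scaled
#'   down from the 100,000 used on real WGS data for synthetic runs).
#' @param seed subsampling seed.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(r2_max = 0.01, window = 50, step = 5,
                         m = 100000, seed = 1) {
  stopifnot(r2_max > 0, r2_max < 1, window >= step, step >= 1, m >= 1)
  structure(as.list(environment()), class = "prune_config")
}

#' Greedy windowed LD pruning on dosage correlation
#'
#' Within each sliding block, while any pair of kept variants has squared
#' Pearson correlation above `r2_max`, the later-positioned variant of
#' the worst (highest-r2) pair is removed; the block then advances by
#' `step`. Missing dosages are mean-imputed for the correlation only.
#'
#' @param G a [genotype_matrix()].
#' @param cfg a [prune_config()].
#' @return integer vector of kept variant column indices.
#' @export
ld_prune <- function(G, cfg = prune_config()) {
  p <- ncol(G$dosage)
  if (p == 0L) return(integer(0))
  dos <- impute_window(G$dosage)
  keep <- rep(TRUE, p)
  start <- 1L
  while (start <= p) {
    block <- which(keep)[which(keep) >= start &
                           which(keep) < start + cfg$window]
    if (length(block) > 1) {
      repeat {
        cm <- suppressWarnings(cor(dos[, block, drop = FALSE]))
        cm[is.na(cm)] <- 0
        diag(cm) <- 0
        r2 <- cm^2
        worst <- max(r2)
        if (worst <= cfg$r2_max) break
        ij <- which(r2 == worst, arr.ind = TRUE)[1, ]
        drop <- block[max(ij)]           # later-positioned of the pair
        keep[drop] <- FALSE
        block <- setdiff(block, drop)
        if (length(block) < 2) break
      }
    }
    start <- start + cfg$step
  }
  which(keep)
}

#' Random subsample of pruned variants
#'
#' Samples `cfg$m` variant indices without replacement from the pruned
#' set; if fewer survive pruning, all are used (with a message).
#'
#' @param kept indices from [ld_prune()].
#' @param cfg a [prune_config()].
#' @return integer vector of variant indices.
#' @export
subsample_variants <- function(kept, cfg = prune_config()) {
  if (length(kept) <= cfg$m) {
    if (length(kept) < cfg$m)
      message("only ", length(kept), " variants survive pruning; using all")
    return(kept)
  }
  set.seed(cfg$seed)
  sort(sample(kept, cfg$m))
}

#' Jaccard similarity matrix over rare-variant carrier sets
#'
#' Sample i's carrier set is the set of variants with dosage >= 1
#' (missing treated as non-carrier); the similarity is
#' `|intersection| / |union|`, with an empty union giving 0.
#'
#' @param G a [genotype_matrix()] (typically the pruned subsample).
#' @return symmetric n x n matrix with entries in [0, 1].
#' @export
jaccard_matrix <- function(G) {
  n <- nrow(G$dosage)
  if (n < 2) stop("need at least 2 samples")
  C <- G$dosage >= 1L & !is.na(G$dosage)
  storage.mode(C) <- "double"
  inter <- tcrossprod(C)
  sz <- diag(inter)
  un <- outer(sz, sz, "+") - inter
  J <- ifelse(un > 0, inter / un, 0)
  dimnames(J) <- list(rownames(G$dosage), rownames(G$dosage))
  J
}

#' Principal components of a Jaccard similarity matrix
#'
#' Double-centers the similarity matrix (PCoA-style; switchable), takes
#' the symmetric eigendecomposition, and returns the top-k eigenvectors
#' scaled by the square root of their (non-negative) eigenvalues. Sign
#' convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param J symmetric similarity matrix.
#' @param k number of components.
#' @param center double-center before decomposing (default `TRUE`).
#' @return list with `scores` (n x k), `values` (all eigenvalues,
#'   descending).
#' @export
jaccard_pca <- function(J, k = 4, center = TRUE) {
  n <- nrow(J)
  if (k > n) stop("k must not exceed the number of samples")
  stopifnot(isTRUE(all.equal(J, t(J), tolerance = 1e-8)))
  M <- if (center) {
    rm <- rowMeans(J); gm <- mean(J)
    J - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  } else J
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  scores <- sapply(seq_len(k), function(j) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    v * sqrt(max(e$values[j], 0))
  })
  scores <- matrix(scores, ncol = k,
                   dimnames = list(rownames(J), paste0("PC", seq_len(k))))
  list(scores = scores, values = e$values)
}

#' Rare-variant PCs for a cohort, end to end
#'
#' LD-prunes, subsamples, builds the Jaccard matrix and returns PC
#' coordinates formatted as a covariate table (`iid`, `PC1`...).
#'
#' @param G a [genotype_matrix()].
#' @param cfg a [prune_config()].
#' @param k number of components.
#' @return list with `pcs` (data.frame), `values`, `variants_used`.
#' @export
rare_variant_pcs <- function(G, cfg = prune_config(), k = 4) {
  kept <- ld_prune(G, cfg)
  used <- subsample_variants(kept, cfg)
  J <- jaccard_matrix(subset_genotypes(G, variants = used))
  pca <- jaccard_pca(J, k)
  pcs <- data.frame(iid = rownames(G$dosage), pca$scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(pcs = pcs, values = pca$values, variants_used = used)
}
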