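# Independent oracles and small fixture builders shared across tests.

# all permutations of 1..n as a list (insertion construction, independent
# of the package's perms helper)
perm_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_list(n - 1)) for (k in seq_len(n))
    out <- c(out, list(append(p, n, after = k - 1)))
  out
}

# brute-force enumeration of the within-family permutation null for a list
# of family blocks; recomputes every statistic from scratch
brute_force_region <- function(blocks, w) {
  pl <- lapply(blocks, function(b) perm_list(length(b$t)))
  grid <- expand.grid(lapply(pl, seq_along))
  V <- ncol(blocks[[1]]$g)
  Bs <- numeric(nrow(grid)); Qs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    Btot <- 0; Stot <- numeric(V)
    for (f in seq_along(blocks)) {
      b <- blocks[[f]]
      gperm <- b$g[pl[[f]][[grid[r, f]]], , drop = FALSE]
      Btot <- Btot + sum(b$t * (gperm %*% w))
      Stot <- Stot + as.vector(b$t %*% sweep(gperm, 2, colMeans(gperm)))
    }
    Bs[r] <- Btot; Qs[r] <- sum(w^2 * Stot^2)
  }
  B0 <- 0; S0 <- numeric(V)
  for (b in blocks) {
    B0 <- B0 + sum(b$t * (b$g %*% w))
    S0 <- S0 + as.vector(b$t %*% sweep(b$g, 2, colMeans(b$g)))
  }
  Q0 <- sum(w^2 * S0^2)
  list(p_burden = mean(abs(Bs - mean(Bs)) >= abs(B0 - mean(Bs)) - 1e-9),
       p_skat = mean(Qs >= Q0 - 1e-9),
       n_config = nrow(grid))
}

# random family blocks whose total configuration count stays small enough
# for exact enumeration
random_blocks <- function(n_fam, sib_max = 3, V = 2,
                          tvals = c(0.85, -0.15)) {
  lapply(seq_len(n_fam), function(f) {
    s <- sample(2:sib_max, 1)
    list(fid = paste0("F", f), ids = paste0(f, "_", seq_len(s)),
         t = sample(tvals, s, replace = TRUE),
         g = matrix(sample(0:2, s * V, replace = TRUE,
                           prob = c(0.6, 0.3, 0.1)), s, V))
  })
}

informative_blocks <- function(blocks) {
  Filter(function(b) length(b$t) >= 2 && var(b$t) > 0 &&
           any(apply(b$g, 2, var) > 0), blocks)
}

# combinatorial HWE oracle: counts allele-to-slot assignments per
# heterozygote configuration with exact integer arithmetic
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_alt + n_het          # alt allele count
  h_all <- seq(0, n)
  cnt <- vapply(h_all, function(h) {
    a <- (nA - h) / 2                  # hom-alt count
    b <- n - h - a                     # hom-ref count
    if (h > nA || a != round(a) || a < 0 || b < 0) return(0)
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
          h * log(2))
  }, 0)
  tot <- sum(cnt)
  stopifnot(abs(tot - choose(2 * n, nA)) < 1e-6 * tot)
  pr <- cnt / tot
  obs <- pr[h_all == n_het]
  sum(pr[pr <= obs * (1 + 1e-9) & pr > 0])
}

# genotype matrix from a plain dosage matrix
make_gm <- function(dose, chrom = "1", pos = NULL, ref = "A", alt = "C",
                    half_calls = NULL) {
  p <- ncol(dose)
  if (is.null(rownames(dose))) rownames(dose) <- sprintf("s%03d", seq_len(nrow(dose)))
  v <- data.frame(chrom = rep_len(chrom, p),
                  pos = if (is.null(pos)) seq_len(p) * 10L else pos,
                  ref = rep_len(ref, p), alt = rep_len(alt, p),
                  stringsAsFactors = FALSE)
  genotype_matrix(dose, v, half_calls = half_calls, sort = FALSE)
}

# the hand-enumerated 8-variant QC toy: exactly one survivor (v8)
qc_toy <- function() {
  ids <- c("F1_S1", "F1_S2", "F2_S1", "F2_S2", "F3_S1", "F3_S2")
  ped <- pedigree(fid = rep(c("F1", "F2", "F3"), each = 2),
                  iid = ids,
                  pat = rep(c("F1_P1", "F2_P1", "F3_P1"), each = 2),
                  mat = rep(c("F1_P2", "F2_P2", "F3_P2"), each = 2),
                  sex = rep(1:2, 3), affected = rep(c(1, 0), 3))
  # columns: v1 multiallelic, v2 monomorphic, v3 indel, v4 dataset
  # singleton, v5 single-family doubleton, v6 half-call, v7 AF 0.02 in
  # both reference columns, v8 clean
  dose <- cbind(v1 = c(0L, 1L, 0L, 1L, 0L, 0L),
                v2 = c(0L, 0L, 0L, 0L, 0L, 0L),
                v3 = c(0L, 1L, 0L, 1L, 0L, 0L),
                v4 = c(1L, 0L, 0L, 0L, 0L, 0L),
                v5 = c(1L, 1L, 0L, 0L, 0L, 0L),
                v6 = c(NA, 1L, 0L, 1L, 0L, 0L),
                v7 = c(1L, 0L, 1L, 0L, 0L, 0L),
                v8 = c(1L, 0L, 0L, 1L, 0L, 1L))
  rownames(dose) <- ids
  v <- data.frame(chrom = "1", pos = seq_len(8) * 100L,
                  ref = c("A", "A", "AT", "A", "A", "A", "A", "A"),
                  alt = c("C,T", "C", "A", "C", "C", "C", "C", "C"),
                  stringsAsFactors = FALSE)
  G <- genotype_matrix(dose, v, half_calls = matrix(c(1L, 6L), 1, 2),
                       sort = FALSE)
  af <- data.frame(chrom = "1", pos = seq_len(8) * 100L,
                   ref = v$ref, alt = v$alt,
                   AF_all = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.005,
                              0.02, 0.005),
                   AF_nfe = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.005,
                              0.02, 0.005),
                   stringsAsFactors = FALSE)
  list(G = G, ped = ped, af = af)
}
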