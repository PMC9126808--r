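two_sib_block <- function(fid = "F1", t = c(0.85, -0.15), g = c(1, 0)) {
  list(fid = fid, ids = paste0(fid, "_", seq_along(t)), t = t,
       g = matrix(g, length(t)))
}

test_that("family scores match direct arithmetic", {
  fs <- family_scores(two_sib_block())
  expect_equal(fs$B, 0.85)
  expect_equal(fs$S, 0.5)                            # 0.85*0.5 + 0.15*0.5
  # identical genotypes -> centered scores vanish
  fs2 <- family_scores(two_sib_block(g = c(1, 1)))
  expect_equal(fs2$S, 0)
  # constant residuals -> centered scores vanish
  fs3 <- family_scores(two_sib_block(t = c(0.85, 0.85)))
  expect_equal(fs3$S, 0)
  expect_error(family_scores(list(t = 1, g = matrix(0, 1, 0))), "empty")
})

test_that("null resampling permutes rows uniformly and preserves the multiset", {
  one <- list(fid = "F", ids = "a", t = 0.85, g = matrix(1, 1, 2))
  r <- null_resample(one)
  expect_false(r$informative)
  expect_identical(r$g, one$g)

  fam <- two_sib_block(g = c(2, 0))
  set.seed(42)
  swaps <- vapply(1:10000, function(i) null_resample(fam)$g[1, 1] == 0, TRUE)
  expect_gt(chisq.test(table(swaps), p = c(0.5, 0.5))$p.value, 0.001)

  fam3 <- list(fid = "F", ids = letters[1:3], t = c(0.85, -0.15, 0.85),
               g = matrix(c(0, 1, 2, 2, 1, 0), 3, 2))
  r3 <- null_resample(fam3)
  expect_identical(sort(apply(r3$g, 1, paste, collapse = ",")),
                   sort(apply(fam3$g, 1, paste, collapse = ",")))
})

test_that("the two-family toy enumerates to p = 0.5 for both tests", {
  blocks <- list(two_sib_block("F1"), two_sib_block("F2"))
  r <- region_test(blocks, NULL, region_test_config())
  expect_equal(r$method, "exact")
  expect_equal(r$B, 1.7)
  expect_equal(r$Q, 1)
  expect_equal(r$p_burden, 0.5)
  expect_equal(r$p_skat, 0.5)
  expect_equal(r$n_sims, 4)
})

test_that("degenerate windows give p = 1 with a flag", {
  blocks <- list(two_sib_block(g = c(0, 0)), two_sib_block("F2", g = c(0, 0)))
  r <- region_test(blocks, NULL, region_test_config())
  expect_true(r$degenerate)
  expect_equal(r$p_burden, 1)
  expect_equal(r$p_skat, 1)
})

test_that("zero-variance families leave the exact p unchanged", {
  blocks <- list(two_sib_block("F1"), two_sib_block("F2", g = c(2, 1)))
  base <- region_test(blocks, NULL, region_test_config())
  extra <- c(blocks, list(two_sib_block("F3", t = c(0.85, 0.85), g = c(1, 1))))
  aug <- region_test(extra, NULL, region_test_config())
  expect_equal(aug$p_burden, base$p_burden)
  expect_equal(aug$p_skat, base$p_skat)
})

test_that("relabeling variants within a window leaves B and Q unchanged", {
  set.seed(7)
  blocks <- random_blocks(3, V = 3)
  r1 <- region_test(blocks, NULL, region_test_config())
  flip <- lapply(blocks, function(b) { b$g <- b$g[, 3:1]; b })
  r2 <- region_test(flip, NULL, region_test_config())
  expect_equal(r2$B, r1$B)
  expect_equal(r2$Q, r1$Q)
  expect_equal(r2$p_burden, r1$p_burden)
  expect_equal(r2$p_skat, r1$p_skat)
})

test_that("exact enumeration agrees with the brute-force oracle", {
  set.seed(99)
  checked <- 0
  while (checked < 5) {
    blocks <- random_blocks(sample(2:3, 1), V = sample(1:3, 1))
    r <- region_test(blocks, NULL, region_test_config())
    if (r$method != "exact") next
    o <- brute_force_region(informative_blocks(blocks),
                            rep(1, ncol(blocks[[1]]$g)))
    expect_equal(r$p_burden, o$p_burden, tolerance = 1e-12)
    expect_equal(r$p_skat, o$p_skat, tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("Monte Carlo agrees with exact enumeration within 3 standard errors", {
  set.seed(15)
  blocks <- random_blocks(3, sib_max = 3, V = 2)
  blocks <- informative_blocks(blocks)
  skip_term <- length(blocks) < 2
  if (skip_term) blocks <- list(two_sib_block("F1"), two_sib_block("F2"))
  ex <- region_test(blocks, NULL, region_test_config())
  set.seed(5)
  mc <- region_test(blocks, NULL, region_test_config(n_sims = 5e4,
                                                     exact_cap = 1))
  expect_equal(mc$method, "monte_carlo")
  expect_gte(mc$p_burden, 1 / (5e4 + 1))            # estimator floor
  se_b <- sqrt(ex$p_burden * (1 - ex$p_burden) / 5e4)
  se_s <- sqrt(ex$p_skat * (1 - ex$p_skat) / 5e4)
  expect_lt(abs(mc$p_burden - ex$p_burden), 3 * se_b + 1e-4)
  expect_lt(abs(mc$p_skat - ex$p_skat), 3 * se_s + 1e-4)
})

test_that("single-variant windows give identical burden and SKAT p-values", {
  set.seed(23)
  blocks <- random_blocks(4, sib_max = 3, V = 1)
  ex <- region_test(blocks, NULL, region_test_config())
  expect_equal(ex$p_skat, ex$p_burden)
  set.seed(6)
  mc <- region_test(blocks, NULL, region_test_config(n_sims = 2000,
                                                     exact_cap = 1))
  expect_equal(mc$p_skat, mc$p_burden)              # shared stream, exact tie
})

test_that("genome scans are reproducible and order-independent", {
  cfg <- sim_config(n_families = 25, sibs_per_family = c(2, 3),
                    variants_per_chrom = 30, af_low = 0.005, seed = 17)
  fam <- simulate_families(cfg, simulate_founder_panel(cfg))
  w <- build_windows(fam$genotypes$variants)
  rcfg <- region_test_config(n_sims = 1000, seed = 5)
  s1 <- scan_family_genome(fam$genotypes, fam$pedigree, fam$phenotypes, w, rcfg)
  s2 <- scan_family_genome(fam$genotypes, fam$pedigree, fam$phenotypes, w, rcfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), nrow(w))
  expect_true(all(s1$p_burden > 0 & s1$p_burden <= 1, na.rm = TRUE))
})
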