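intercept_null <- function(y) suppressWarnings(fit_null(y))

test_that("the logistic null model is fit and validated correctly", {
  y <- rep(c(1, 0), each = 10)
  null <- intercept_null(y)
  expect_equal(unname(null$mu), rep(0.5, 20))
  expect_error(suppressWarnings(fit_null(rep(1, 10))), "constant")
  X <- cbind(a = rnorm(20), b = 0)
  X[, 2] <- X[, 1] * 2                               # collinear
  expect_error(suppressWarnings(fit_null(y, X)), "rank deficient")
  Xsep <- cbind(sep = y)                             # perfect separation
  expect_error(suppressWarnings(fit_null(y, Xsep)), "separation.*sep")
  expect_warning(fit_null(y), "2000")                # small-sample notice
})

test_that("null-model coefficients recover the simulating truth", {
  set.seed(31)
  n <- 5000
  X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  eta <- -1 + 0.5 * X[, 1] - 0.3 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  null <- suppressWarnings(fit_null(y, X))
  se <- sqrt(diag(solve(crossprod(null$X, null$v * null$X))))
  expect_lt(abs(null$coef[1] - (-1)), 3 * se[1])
  expect_lt(abs(null$coef[2] - 0.5), 3 * se[2])
  expect_lt(abs(null$coef[3] - (-0.3)), 3 * se[3])
})

test_that("burden score test matches hand arithmetic and its permutation oracle", {
  null <- intercept_null(c(1, 1, 0, 0))
  bt <- burden_test(null, matrix(c(2, 2, 0, 0), 4, 1))
  expect_equal(bt$U, 2)
  expect_equal(bt$var_U, 1)
  expect_equal(bt$stat, 4)
  expect_equal(bt$p, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(burden_test(null, matrix(0, 4, 3))$p, 1)

  # permutation oracle on a larger fixture; distinct continuous weights
  # keep the collapsed score off a coarse lattice so the chi-square tail
  # is comparable with the discrete permutation distribution
  set.seed(41)
  n <- 300
  y <- rep(c(1, 0), each = n / 2)
  Gw <- matrix(rbinom(n * 4, 2, 0.1), n, 4)
  w <- c(0.31, 0.77, 1.13, 1.91)
  null <- intercept_null(y)
  bt <- burden_test(null, Gw, w)
  cvec <- as.vector(Gw %*% w)
  B <- 1e5
  set.seed(42)
  Uperm <- crossprod(matrix(cvec[replicate(B, sample.int(n))], n, B),
                     null$res)
  # two-sided permutation p of the score
  p_perm <- mean(abs(Uperm) >= abs(bt$U) - 1e-9)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(bt$p - p_perm), 3 * se + 0.005)
})

test_that("single-variant SKAT equals the burden test exactly", {
  set.seed(13)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  X <- cbind(age = rnorm(n))
  g <- matrix(rbinom(n, 2, 0.1), n, 1)
  null <- suppressWarnings(fit_null(y, X))
  expect_equal(skat_test(null, g)$p, burden_test(null, g)$p,
               tolerance = 1e-10)
  expect_equal(skat_test(null, matrix(0, n, 2))$p, 1)
})

test_that("Liu and integration tails agree on a well-conditioned mixture", {
  set.seed(19)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  Gw <- matrix(rbinom(n * 6, 2, 0.1), n, 6)
  null <- intercept_null(y)
  p1 <- skat_test(null, Gw, method = "liu")$p
  p2 <- skat_test(null, Gw, method = "integration")$p
  expect_lt(abs(p1 - p2) / p2, 0.15)
})

test_that("SKAT-O endpoints, sandwich bound and resampling oracle hold", {
  set.seed(11)
  n <- 200
  y <- rbinom(n, 1, 0.35)
  Gw <- matrix(rbinom(n * 8, 2, 0.05), n, 8)
  y[Gw[, 1] > 0] <- rbinom(sum(Gw[, 1] > 0), 1, 0.6)
  null <- intercept_null(y)
  sk <- skato_test(null, Gw)
  expect_equal(sk$p_rho[1], sk$p_skat)               # rho = 0
  expect_equal(sk$p_rho[8], sk$p_burden)             # rho = 1
  expect_gte(sk$p_skato, min(sk$p_rho))
  expect_lte(sk$p_skato, 8 * min(sk$p_rho))

  # residual-permutation oracle for the min-p combination
  rho <- sk$rho_grid
  v <- null$mu * (1 - null$mu)
  A <- t(Gw) %*% (v * Gw) - (t(Gw) %*% v) %*% (v %*% Gw) / sum(v)
  m <- ncol(Gw)
  lam <- lapply(rho, function(r) {
    onem <- matrix(1 / m, m, m)
    Rh <- sqrt(1 - r + m * r) * onem + sqrt(1 - r) * (diag(m) - onem)
    ev <- eigen(Rh %*% A %*% Rh, symmetric = TRUE, only.values = TRUE)$values
    ev[ev > max(ev) * 1e-10]
  })
  minp_obs <- min(sk$p_rho)
  B <- 1e5; hits <- 0
  set.seed(99)
  for (chunk in 1:5) {
    R <- vapply(seq_len(B / 5), function(i) null$res[sample.int(n)],
                numeric(n))
    U <- crossprod(Gw, R)
    Qs <- colSums(U^2); Qb <- colSums(U)^2
    pm <- vapply(seq_along(rho), function(i)
      rvscan:::liu_pvalue((1 - rho[i]) * Qs + rho[i] * Qb, lam[[i]]),
      numeric(B / 5))
    hits <- hits + sum(apply(pm, 1, min) <= minp_obs)
  }
  p_oracle <- hits / B
  expect_lt(abs(sk$p_skato - p_oracle) / p_oracle, 0.10)
})

test_that("p-values are invariant to orthogonal covariates and weight scale", {
  set.seed(29)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  Gw <- matrix(rbinom(n * 5, 2, 0.06), n, 5)
  null0 <- intercept_null(y)
  base <- skato_test(null0, Gw)
  # covariate orthogonal to both phenotype residual and genotypes
  z <- rnorm(n)
  z <- residuals(lm(z ~ y + Gw))
  null1 <- suppressWarnings(fit_null(y, cbind(orth = z)))
  pert <- skato_test(null1, Gw)
  expect_lt(abs(pert$p_burden - base$p_burden), 1e-6)
  expect_lt(abs(pert$p_skat - base$p_skat), 1e-6)
  # scaling all weights leaves every p unchanged
  sc <- skato_test(null0, Gw, weights = rep(5, 5))
  expect_equal(sc$p_burden, base$p_burden, tolerance = 1e-10)
  expect_equal(sc$p_skat, base$p_skat, tolerance = 1e-10)
  expect_equal(sc$p_skato, base$p_skato, tolerance = 1e-8)
})

test_that("structure-aware PCs restore calibration under confounding", {
  # two subpopulations with disease-risk shift: omitting the PCs inflates
  # the null rejection rate, including them restores it
  cfg <- sim_config(n_cases = 300, n_controls = 300,
                    variants_per_chrom = 4000, af_low = 0.004,
                    n_subpops = 2, fst_like_divergence = 0.5,
                    subpop_beta = 1.5, seed = 47)
  panel <- simulate_founder_panel(cfg)
  cc <- simulate_case_control(cfg, panel)
  G <- cc$genotypes
  w <- build_windows(G$variants)
  ids <- rownames(G$dosage)
  truth_pc <- data.frame(iid = ids,
                         PC1 = as.numeric(cc$truth$subpop[ids] == 2))
  no_pc <- scan_cc_genome(G, cc$phenotypes, NULL, w)
  with_pc <- scan_cc_genome(G, cc$phenotypes, truth_pc, w)
  rate_no <- mean(no_pc$p_skat <= 0.05)
  rate_with <- mean(with_pc$p_skat <= 0.05)
  expect_gt(rate_no, 0.10)                            # visibly inflated
  ci <- qbinom(c(0.025, 0.975), nrow(w), 0.05) / nrow(w)
  expect_gte(rate_with, ci[1])
  expect_lte(rate_with, ci[2])
})
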