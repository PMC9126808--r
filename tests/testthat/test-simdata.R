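test_that("founder panel respects configuration bounds", {
  cfg <- sim_config(variants_per_chrom = 0, seed = 1)
  expect_equal(nrow(simulate_founder_panel(cfg)$variants), 0)

  cfg <- sim_config(n_chrom = 2, variants_per_chrom = 200, seed = 2)
  panel <- simulate_founder_panel(cfg)
  expect_true(all(panel$af_overall <= 0.01))
  expect_true(all(panel$af_overall >= cfg$af_low))
  expect_equal(nrow(panel$variants), 400)
  expect_error(sim_config(af_high = 0.05))
  expect_error(sim_config(variants_per_chrom = -1))
})

test_that("carrier haplotype fraction matches the binomial expectation", {
  panel <- simulate_founder_panel(sim_config(variants_per_chrom = 3, seed = 4))
  panel$af[1, 1] <- 0.005
  set.seed(8)
  h <- draw_haplotypes(panel, 1e4, 1)
  expect_lt(abs(mean(h[, 1]) - 0.005), 3 * sqrt(0.005 * 0.995 / 1e4))
})

test_that("homozygous-reference parents force all-zero siblings", {
  cfg <- sim_config(n_families = 5, sibs_per_family = 3,
                    variants_per_chrom = 20, min_affected_sibs = 0, seed = 6)
  panel <- simulate_founder_panel(cfg)
  panel$af[, ] <- 0
  fam <- simulate_families(cfg, panel)
  expect_true(all(fam$genotypes$dosage == 0L))
})

test_that("Mendelian transmission halves dosage from a het x hom-alt cross", {
  cfg <- sim_config(n_families = 3000, sibs_per_family = 2,
                    variants_per_chrom = 1, af_low = 0.01, af_high = 0.01,
                    min_affected_sibs = 0, seed = 31)
  panel <- simulate_founder_panel(cfg)
  panel$af[, ] <- 0.5
  fam <- simulate_families(cfg, panel, keep_parents = TRUE)
  dos <- fam$genotypes$dosage
  kids <- fam$pedigree[!is.na(fam$pedigree$pat), ]
  pd <- dos[kids$pat, 1]; md <- dos[kids$mat, 1]; cd <- dos[kids$iid, 1]
  sel <- (pd == 1 & md == 2) | (pd == 2 & md == 1)
  expect_gt(sum(sel), 500)
  expect_true(all(cd[sel] %in% 1:2))
  expect_lt(abs(mean(cd[sel] == 2) - 0.5), 3 * sqrt(0.25 / sum(sel)))
  # Mendel-consistency invariant with parents retained
  expect_equal(sum(count_mendel_errors(fam$genotypes, fam$pedigree)), 0)
})

test_that("the calibrated intercept recovers the stated prevalence", {
  cfg <- sim_config(n_families = 2000, sibs_per_family = 3,
                    variants_per_chrom = 5, min_affected_sibs = 0, seed = 21)
  fam <- simulate_families(cfg, simulate_founder_panel(cfg))
  frac <- mean(fam$phenotypes$affection)
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / nrow(fam$phenotypes)))
})

test_that("ascertainment keeps only families with enough affected siblings", {
  cfg <- sim_config(n_families = 30, sibs_per_family = c(2, 4),
                    variants_per_chrom = 10, min_affected_sibs = 2, seed = 12)
  fam <- simulate_families(cfg, simulate_founder_panel(cfg))
  naff <- tapply(fam$phenotypes$affection,
                 sub("_S[0-9]+$", "", fam$phenotypes$iid), sum)
  expect_true(all(naff >= 2))
  # impossible ascertainment fails loudly, naming the constraint
  cfg2 <- sim_config(n_families = 1, sibs_per_family = 2,
                     variants_per_chrom = 5, min_affected_sibs = 2,
                     prevalence = 0.15, seed = 13)
  panel2 <- simulate_founder_panel(cfg2)
  expect_error(simulate_families(cfg2, panel2, max_attempts = 2),
               "ascertainment")
})

test_that("case-control cohort obeys quotas, age floor and null equivalence", {
  cfg <- sim_config(n_cases = 0, n_controls = 40, variants_per_chrom = 30,
                    seed = 3)
  cc <- simulate_case_control(cfg, simulate_founder_panel(cfg))
  expect_true(all(cc$phenotypes$affection == 0))
  expect_true(all(cc$covariates$age >= 60))

  cfg <- sim_config(n_cases = 40, n_controls = 40, variants_per_chrom = 30,
                    seed = 3)
  cc <- simulate_case_control(cfg, simulate_founder_panel(cfg))
  expect_equal(sum(cc$phenotypes$affection), 40)
  ctrl <- cc$covariates$age[cc$phenotypes$affection == 0]
  expect_true(all(ctrl >= 60))

  # with no causal effects, case and control genotype loads are
  # exchangeable: the two-sample test is non-significant at alpha = 0.001
  # in at least 99 of 100 seeded runs
  nonsig <- sum(vapply(1:100, function(s) {
    cfg <- sim_config(n_cases = 50, n_controls = 50,
                      variants_per_chrom = 100, af_low = 0.005, seed = s)
    cc <- simulate_case_control(cfg, simulate_founder_panel(cfg))
    load <- rowSums(cc$genotypes$dosage)
    y <- cc$phenotypes$affection[match(rownames(cc$genotypes$dosage),
                                       cc$phenotypes$iid)]
    suppressWarnings(wilcox.test(load ~ y)$p.value) > 0.001
  }, TRUE))
  expect_gte(nonsig, 99)
})

test_that("a fixed seed reproduces every output file byte for byte", {
  cfg <- sim_config(n_families = 10, n_cases = 20, n_controls = 20,
                    variants_per_chrom = 30, seed = 9)
  mk <- function(dir) {
    panel <- simulate_founder_panel(cfg)
    out <- write_cohort(simulate_families(cfg, panel), panel, dir, "fam")
    c(out, write_cohort(simulate_case_control(cfg, panel), panel, dir, "cc"))
  }
  f1 <- mk(tempfile()); f2 <- mk(tempfile())
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("causal windows index the emitted variant set", {
  cfg <- sim_config(variants_per_chrom = 15,
                    causal_windows = list(list(chrom = 1, window = 5,
                                               model = "unidirectional",
                                               beta = 1)), seed = 2)
  expect_error(simulate_founder_panel(cfg), "beyond")
  cfg <- sim_config(variants_per_chrom = 15,
                    causal_windows = list(list(chrom = 1, window = 2,
                                               model = "mixed", beta = 1)),
                    seed = 2)
  panel <- simulate_founder_panel(cfg)
  idx <- which(panel$effects != 0)
  expect_equal(idx, 11:15)
  expect_setequal(unique(sign(panel$effects[idx])), c(1, -1))
})
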