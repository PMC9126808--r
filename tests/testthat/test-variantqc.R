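test_that("HWE exact test matches hand-enumerated cases", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 1, 0), 1)
  expect_equal(hwe_exact_test(50, 0, 0), 1)        # monomorphic
  expect_error(hwe_exact_test(-1, 0, 1), "negative")
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  # spot agreement with the combinatorial oracle
  for (cnt in list(c(3, 2, 1), c(5, 1, 4), c(2, 6, 2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
})

test_that("Mendel errors follow the trio and duo impossibility rules", {
  ped <- pedigree(rep("F1", 3), c("P1", "P2", "K"), c(NA, NA, "P1"),
                  c(NA, NA, "P2"), c(1, 2, 1), c(NA, NA, 1))
  gm <- function(p1, p2, k) {
    d <- matrix(c(p1, p2, k), 3, length(p1),
                dimnames = list(c("P1", "P2", "K"), NULL), byrow = TRUE)
    make_gm(d)
  }
  # parents 0/0 x 0/0, child het -> error; 0 x 2 child het -> fine
  expect_equal(count_mendel_errors(gm(c(0L, 0L), c(0L, 2L), c(1L, 1L)), ped),
               c(1L, 0L))
  # duo rule: one parent missing, other 0, child 2 -> error
  expect_equal(count_mendel_errors(gm(c(NA), c(0L), c(2L)), ped), 1L)
  expect_equal(count_mendel_errors(gm(c(NA), c(2L), c(0L)), ped), 1L)
  expect_equal(count_mendel_errors(gm(c(NA), c(0L), c(1L)), ped), 0L)
  # missing child genotype skips the check
  expect_equal(count_mendel_errors(gm(c(0L), c(0L), c(NA)), ped), 0L)
})

test_that("the QC cascade matches the hand enumeration on the 8-variant toy", {
  toy <- qc_toy()
  out <- filter_variants(toy$G, toy$ped, toy$af, qc_config())
  expect_equal(ncol(out$genotypes$dosage), 1L)
  expect_equal(variant_key(out$genotypes$variants), "1:800:A:C")
  expect_equal(out$report$removed,
               c(1L, 1L, 1L, 2L, 1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(out$report$remaining,
               c(7L, 6L, 5L, 3L, 2L, 2L, 2L, 2L, 1L, 1L))
  # counts are internally consistent at every stage
  input <- c(8L, head(out$report$remaining, -1))
  expect_equal(input - out$report$removed, out$report$remaining)
})

test_that("the cascade is idempotent and handles trivial inputs", {
  toy <- qc_toy()
  once <- filter_variants(toy$G, toy$ped, toy$af, qc_config())
  twice <- filter_variants(once$genotypes, toy$ped, toy$af, qc_config())
  expect_identical(twice$genotypes$dosage, once$genotypes$dosage)
  expect_true(all(twice$report$removed == 0))

  empty <- subset_genotypes(toy$G, variants = rep(FALSE, 8))
  out <- filter_variants(empty, toy$ped, toy$af, qc_config())
  expect_equal(ncol(out$genotypes$dosage), 0L)
  expect_true(all(out$report$removed == 0))

  # all-pass fixture: identity at every stage
  set.seed(3)
  dose <- matrix(rbinom(40 * 6, 1, 0.4), 40, 6)
  dose[1, ] <- 1L                                   # ensure polymorphic
  G <- make_gm(dose)
  af <- data.frame(chrom = "1", pos = seq_len(6) * 10L, ref = "A", alt = "C",
                   AF_all = 0.005, AF_nfe = 0.005)
  out <- filter_variants(G, NULL, af, qc_config(hwe_p_min = 0))
  expect_equal(out$report$remaining, rep(6L, 10))
})

test_that("AF clause is disjunctive by default and conjunctive by flag", {
  set.seed(4)
  dose <- matrix(rbinom(30 * 2, 1, 0.4), 30, 2)
  G <- make_gm(dose)
  af <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "C",
                   AF_all = c(0.02, 0.02), AF_nfe = c(0.005, 0.02))
  keep_either <- filter_variants(G, NULL, af, qc_config(hwe_p_min = 0))
  expect_equal(ncol(keep_either$genotypes$dosage), 1L)
  keep_both <- filter_variants(G, NULL, af,
                               qc_config(hwe_p_min = 0, af_mode = "both"))
  expect_equal(ncol(keep_both$genotypes$dosage), 0L)
  expect_error(filter_variants(G, NULL, af[, 1:4], qc_config()), "columns")
})

test_that("sample QC flags call rate, inbreeding and pedigree mismatches", {
  set.seed(77)
  p <- runif(2000, 0.1, 0.5)
  dose <- matrix(rbinom(200 * 2000, 2, rep(p, each = 200)), 200, 2000)
  dose <- rbind(dose, dose[1, ])                    # duplicated sample
  rownames(dose) <- c(sprintf("u%03d", 1:200), "dup")
  G <- make_gm(dose, pos = seq_len(2000) * 5L)
  sq <- sample_qc(G, NULL)
  pr <- sq$pairs[sq$pairs$iid1 == "u001" & sq$pairs$iid2 == "dup", ]
  expect_lt(abs(pr$pihat - 1), 0.05)
  expect_true(pr$flag)                              # unrelated pair, PI_HAT ~ 1
  # unrelated HWE samples: mean inbreeding coefficient near zero
  Fh <- sq$samples$inbreeding_F[1:200]
  expect_lt(abs(mean(Fh)), 3 * sd(Fh) / sqrt(200))

  # an all-missing sample is flagged for call rate
  dose2 <- dose[1:10, 1:50]
  dose2[1, ] <- NA
  G2 <- make_gm(dose2, pos = seq_len(50) * 5L)
  sq2 <- sample_qc(G2, NULL)
  expect_true(sq2$samples$flag_call_rate[1])
  # declared siblings sharing no alleles get a family-mismatch flag
  ped <- pedigree(c("F1", "F1"), rownames(dose2)[2:3], c("P", "P"),
                  c("M", "M"), c(1, 1), c(1, 1))
  sq3 <- sample_qc(G2, ped)
  pr3 <- sq3$pairs[sq3$pairs$iid1 == rownames(dose2)[2] &
                     sq3$pairs$iid2 == rownames(dose2)[3], ]
  expect_equal(pr3$relation, "sib")
})

test_that("HWE uses founders and one sibling per parentless family", {
  ped <- pedigree(c("F1", "F1", "F2", "U1"),
                  c("s1", "s2", "s3", "u1"),
                  c("P1", "P1", "P2", NA), c("M1", "M1", "M2", NA),
                  c(1, 2, 1, 1), c(1, 0, 1, 0))
  G <- make_gm(matrix(0L, 4, 2,
                      dimnames = list(c("s1", "s2", "s3", "u1"), NULL)))
  ids <- rvscan:::hwe_sample_subset(G, ped)
  expect_setequal(ids, c("s1", "s3", "u1"))        # one sib per family
})
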