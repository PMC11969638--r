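test_that("reference panels draw frequencies from Beta(1,8) under HWE", {
  pan <- sim_reference_panels(L = 20000, N = 30, genome = toy_genome(),
                              seed = 44)
  # Beta(1,8) mean is 1/9; sd of the mean over 2e4 loci ~ 7e-4
  expect_lt(abs(mean(pan$freqs) - 1 / 9), 0.003)
  # realised panel frequencies track the truth
  fa <- gsped:::allele_freqs(pan$panel_a)
  expect_gt(cor(fa, pan$freqs), 0.9)
  # HWE: homozygote share of ref allele ~ E[p^2] (= Var + mean^2)
  odd <- 2 * seq_len(20000) - 1
  hom <- mean(pan$panel_a$geno[, odd] == "1" & pan$panel_a$geno[, odd + 1] == "1")
  expect_lt(abs(hom - mean(pan$freqs^2)), 0.005)
  # determinism
  pan2 <- sim_reference_panels(L = 20000, N = 30, genome = toy_genome(),
                               seed = 44)
  expect_identical(pan$panel_a$geno, pan2$panel_a$geno)
})

test_that("with-replacement simulation follows the admixture model", {
  pan <- sim_reference_panels(L = 50, N = 8, genome = toy_genome(), seed = 3)
  # force fixed differences so origin is readable off the allele
  pan$panel_a$geno[] <- "1"
  pan$panel_b$geno[] <- "2"
  sim1 <- sim_admixed_with_replacement(pan$panel_a, pan$panel_b, 1, 5, seed = 2)
  expect_true(all(sim1$geno == "1"))
  sim0 <- sim_admixed_with_replacement(pan$panel_a, pan$panel_b, 0, 5, seed = 2)
  expect_true(all(sim0$geno == "2"))
  simh <- sim_admixed_with_replacement(pan$panel_a, pan$panel_b, 0.5, 40, seed = 7)
  frac_a <- mean(simh$geno == "1")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / (40 * 100)))
  empty <- sim_admixed_with_replacement(pan$panel_a, pan$panel_b, 0.5, 0)
  expect_equal(nrow(empty$geno), 0)
  expect_error(sim_admixed_with_replacement(pan$panel_a, pan$panel_b, 1.2, 1),
               "q_a")
})

test_that("unlinked hybrid simulation reproduces category structure", {
  pan <- sim_reference_panels(L = 400, N = 8, genome = toy_genome(), seed = 5)
  pan$panel_a$geno[] <- "1"
  pan$panel_b$geno[] <- "2"
  f1 <- sim_unlinked_hybrids(pan$panel_a, pan$panel_b,
                             hybrid_category_probs("F1"), 10, seed = 6)
  expect_equal(f1$q, rep(0.5, 10))  # every locus exactly one A copy
  odd <- 2 * seq_len(400) - 1
  expect_true(all(f1$geno$geno[, odd] == "1" & f1$geno$geno[, odd + 1] == "2"))
  bc2 <- sim_unlinked_hybrids(pan$panel_a, pan$panel_b,
                              hybrid_category_probs("BC2"), 50, seed = 7)
  # no locus may carry zero A copies in a BC2 toward A
  expect_false(any(bc2$geno$geno[, odd] == "2" & bc2$geno$geno[, odd + 1] == "2"))
  expect_error(sim_unlinked_hybrids(pan$panel_a, pan$panel_b, c(1, 1, 1), 2),
               "triplet")
})

test_that("unlinked admixture-fraction variance shrinks like 1/L", {
  pan3 <- sim_reference_panels(L = 1000, N = 4, genome = toy_genome(), seed = 8)
  pan4 <- sim_reference_panels(L = 10000, N = 4, genome = toy_genome(), seed = 8)
  probs <- hybrid_category_probs("F2")
  q3 <- sim_unlinked_hybrids(pan3$panel_a, pan3$panel_b, probs, 600,
                             genotypes = FALSE, seed = 9)$q
  q4 <- sim_unlinked_hybrids(pan4$panel_a, pan4$panel_b, probs, 600,
                             genotypes = FALSE, seed = 10)$q
  ratio <- var(q3) / var(q4)
  expect_gt(ratio, 7)
  expect_lt(ratio, 14)
})

test_that("hybrid category triplets match the general backcross formula", {
  expect_equal(unname(hybrid_category_probs("BC1")), c(0.5, 0.5, 0))
  expect_equal(unname(hybrid_category_probs("BC2")), c(0.75, 0.25, 0))
  expect_equal(hybrid_category_probs("BC1"), bc_generation_probs(1))
  expect_equal(hybrid_category_probs("BC2"), bc_generation_probs(2))
  expect_equal(unname(bc_generation_probs(4)), c(1 - 1 / 16, 1 / 16, 0))
  expect_error(hybrid_category_probs("BC9x"), "unknown category")
})

test_that("the fixed-frequency supervised MLE behaves at its boundaries", {
  # all-A alleles against near-fixed opposite panels: q_hat at the boundary
  est <- supervised_q_mle(matrix(c("1", "1", "1", "1"), nrow = 1),
                          freq_a = c(0.999, 0.999), freq_b = c(0.001, 0.001),
                          clamp = 1e-4)
  expect_equal(est$q_hat, 1, tolerance = 1e-3)
  # flat likelihood: tie-break at 0.5
  est2 <- supervised_q_mle(matrix(c("1", "2", "1", "2"), nrow = 1),
                           freq_a = c(0.3, 0.4), freq_b = c(0.3, 0.4))
  expect_equal(est2$q_hat, 0.5)
  # no informative loci
  expect_warning(
    est3 <- supervised_q_mle(matrix(NA_character_, 1, 4),
                             freq_a = c(0.3, 0.4), freq_b = c(0.3, 0.4)),
    "no informative")
  expect_equal(est3$q_hat, 0.5)
})

test_that("the supervised MLE recovers q on genuinely diverged panels", {
  set.seed(123)
  L <- 1000
  pa <- rep(0.8, L); pb <- rep(0.2, L)  # |pA - pB| = 0.6
  q_true <- 0.25
  n <- 30
  genos <- matrix(NA_character_, n, 2 * L)
  for (c0 in seq_len(2 * L)) {
    j <- ceiling(c0 / 2)
    from_a <- runif(n) < q_true
    p <- ifelse(from_a, pa[j], pb[j])
    genos[, c0] <- ifelse(runif(n) < p, "1", "2")
  }
  est <- supervised_q_mle(genos, pa, pb)
  expect_lt(abs(mean(est$q_hat) - q_true), 0.03)
  # estimator consistency: error shrinks as L grows
  err <- vapply(c(100, 1000), function(LL) {
    cols <- seq_len(2 * LL)
    abs(mean(supervised_q_mle(genos[, cols], pa[seq_len(LL)],
                              pb[seq_len(LL)])$q_hat) - q_true)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.01)
})

test_that("joint supervised EM matches the fixed-frequency MLE on strong data", {
  set.seed(55)
  L <- 400
  pa <- rep(0.9, L); pb <- rep(0.1, L)
  lab_a <- matrix(ifelse(runif(20 * 2 * L) < 0.9, "1", "2"), 20, 2 * L)
  lab_b <- matrix(ifelse(runif(20 * 2 * L) < 0.1, "1", "2"), 20, 2 * L)
  unk <- matrix(ifelse(runif(5 * 2 * L) < 0.9, "1", "2"), 5, 2 * L)  # pure A
  est <- supervised_admixture_em(unk, lab_a, lab_b)
  expect_true(all(est$q_hat > 0.9))
})

test_that("experiment runs are exactly reproducible from the seed", {
  r1 <- run_rispi_experiment("gsp", L = 60, N = 25, n_per_q = 2, reps = 2,
                             genome = toy_genome(), seed = 77)
  r2 <- run_rispi_experiment("gsp", L = 60, N = 25, n_per_q = 2, reps = 2,
                             genome = toy_genome(), seed = 77)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2 * 9 * 2)
  expect_true(all(r1$q_hat >= 0 & r1$q_hat <= 1))
  expect_error(run_rispi_experiment("gsp", L = 60, N = 10, n_per_q = 2,
                                    genome = toy_genome(), seed = 1),
               "too small")
})

test_that("linked admixture fractions come from whole pedigree categories", {
  rm1 <- toy_rec_map()
  q_bc3 <- sim_linked_admixture("BC3", 8, rm1, seed = 19)
  expect_length(q_bc3, 8)
  expect_true(all(q_bc3 > 0.5))  # BC3 toward A: expected 0.9375
  q_f1 <- sim_linked_admixture("F1", 4, rm1, seed = 20)
  expect_equal(q_f1, rep(0.5, 4))
})
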