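test_that("meiosis without recombination passes haplotypes through intact", {
  rm0 <- build_rec_map(toy_genome(), cM_per_Mb = 0, boundary_spacing_bp = 5e5)
  parent <- list(gsped:::full_gamete(rm0$lengths, 1L),
                 gsped:::full_gamete(rm0$lengths, 2L))
  out <- meiosis(parent, rm0, seed = 11)
  for (ch in names(rm0$lengths)) {
    expect_equal(nrow(out[[1]][[ch]]), 1)
    expect_equal(nrow(out[[2]][[ch]]), 1)
    # complementary: the two products carry opposite haplotypes
    expect_true(out[[1]][[ch]][1, "origin"] != out[[2]][[ch]][1, "origin"])
  }
})

test_that("a single forced crossover splits a chromosome at the boundary", {
  m1 <- matrix(c(0, 1e6, 1), nrow = 1,
               dimnames = list(NULL, c("start", "end", "origin")))
  m2 <- matrix(c(0, 1e6, 2), nrow = 1,
               dimnames = list(NULL, c("start", "end", "origin")))
  res <- gsped:::splice_chromosome(m1, m2, breakpoints = 4e5,
                                   start_slot = 1, L = 1e6)
  expect_equal(unname(res[[1]]), matrix(c(0, 4e5, 1, 4e5, 1e6, 2),
                                        nrow = 2, byrow = TRUE))
  expect_equal(unname(res[[2]]), matrix(c(0, 4e5, 2, 4e5, 1e6, 1),
                                        nrow = 2, byrow = TRUE))
})

test_that("meiosis products are complementary at every position", {
  rm1 <- toy_rec_map(spacing = 2e5, cM_per_Mb = 40)  # recombination-rich
  parent <- list(gsped:::full_gamete(rm1$lengths, 1L),
                 gsped:::full_gamete(rm1$lengths, 2L))
  set.seed(99)
  for (i in 1:10) {
    out <- meiosis(parent, rm1)
    for (ch in names(rm1$lengths)) {
      a <- out[[1]][[ch]]; b <- out[[2]][[ch]]
      # identical segment boundaries, opposite origins
      expect_equal(a[, c("start", "end")], b[, c("start", "end")])
      expect_true(all(a[, "origin"] != b[, "origin"]))
      # exact tiling of [0, L)
      expect_equal(unname(a[1, "start"]), 0)
      expect_equal(unname(a[nrow(a), "end"]), unname(rm1$lengths[[ch]]))
      if (nrow(a) > 1) expect_equal(unname(a[-1, "start"]),
                                    unname(a[-nrow(a), "end"]))
    }
  }
})

test_that("crossover counts in meiosis match the map expectation", {
  rm_m <- build_rec_map(genome_spec("1", 1e8), cM_per_Mb = 1,
                        boundary_spacing_bp = 1e6)  # ~1 Morgan
  parent <- list(gsped:::full_gamete(rm_m$lengths, 1L),
                 gsped:::full_gamete(rm_m$lengths, 2L))
  expected <- sum(rm_m$boundaries[["1"]]$r)
  set.seed(13)
  n_draws <- 2000
  counts <- vapply(seq_len(n_draws), function(i) {
    nrow(meiosis(parent, rm_m)[[1]][["1"]]) - 1L
  }, integer(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / n_draws))
})

test_that("the F2 pedigree delivers 4 samples from 8 founder slots", {
  res <- segregate(figure1_gsp(), toy_rec_map(), n_reps = 1, seed = 21)
  expect_length(res$samples, 4)
  expect_equal(nrow(res$ledger), 8)
  expect_setequal(res$ledger$pop, c("A", "B"))
  expect_true(isTRUE(check_founder_conservation(res$samples, res$ledger,
                                                toy_rec_map()$lengths)))
})

test_that("segregate is reproducible and refuses invalid pedigrees", {
  g <- create_gsp("A", "B", bc1 = TRUE)
  r1 <- segregate(g, toy_rec_map(), n_reps = 2, seed = 5)
  r2 <- segregate(g, toy_rec_map(), n_reps = 2, seed = 5)
  expect_identical(r1, r2)

  bad <- figure1_gsp()
  bad$nodes$n_samples[bad$nodes$id == "s7"] <- 3
  expect_error(segregate(bad, toy_rec_map()), "invalid GSP")
})

test_that("F1 individuals have admixture fraction 1/2 exactly, any map", {
  for (rm in list(toy_rec_map(), build_rec_map(toy_genome(), cM_per_Mb = 0,
                                               boundary_spacing_bp = 1e6))) {
    res <- segregate(create_gsp("A", "B", f1 = TRUE), rm, n_reps = 3, seed = 8)
    q <- admixture_fractions(res$samples, "A", res$ledger)
    expect_equal(q, rep(0.5, 6))
    f <- t(vapply(res$samples, ancestry_genotype_fractions, numeric(3),
                  pop = "A", ledger = res$ledger))
    expect_equal(unname(f), matrix(rep(c(0, 1, 0), each = 6), ncol = 3))
  }
})

test_that("pure-population samples give fraction 1 and triplet (1,0,0)", {
  res <- segregate(gsped:::gsp_pure("A"), toy_rec_map(), n_reps = 1, seed = 3)
  expect_equal(admixture_fractions(res$samples, "A", res$ledger), c(1, 1))
  f <- ancestry_genotype_fractions(res$samples[[1]], "A", res$ledger)
  expect_equal(unname(f), c(1, 0, 0))
  expect_warning(q0 <- admixture_fraction(res$samples[[1]], "Z", res$ledger),
                 "not in ledger")
  expect_equal(q0, 0)
})

test_that("ancestry-genotype fractions always sum to one exactly", {
  res <- segregate(gsp_bc1xbc2("A", "B"), toy_rec_map(), n_reps = 2, seed = 17)
  f <- t(vapply(res$samples, ancestry_genotype_fractions, numeric(3),
                pop = "A", ledger = res$ledger))
  expect_equal(rowSums(f), rep(1, nrow(f)))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("all founder material is conserved across pedigrees and replicates", {
  rm1 <- toy_rec_map()
  set.seed(404)
  for (g in list(create_gsp("A", "B", f1 = TRUE, f2 = TRUE, bc1 = TRUE,
                            bc2 = TRUE),
                 gsp_bc1xbc2("A", "B"),
                 create_bc_ladder(3, "A", "B"),
                 random_valid_gsp(6))) {
    res <- segregate(g, rm1, n_reps = 2)
    expect_true(isTRUE(check_founder_conservation(res$samples, res$ledger,
                                                  rm1$lengths)))
  }
})

test_that("segments serialise to CSV and back", {
  res <- segregate(create_gsp("A", "B", f1 = TRUE), toy_rec_map(),
                   n_reps = 1, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_segments(res$samples, res$ledger, f)
  back <- read_segments(f)
  expect_equal(back$ledger, res$ledger)
  orig <- res$samples[[order(vapply(res$samples, `[[`, character(1), "id"))[1]]]
  got <- back$samples[[1]]
  expect_equal(got$id, orig$id)
  for (ch in names(orig$gametes[[1]])) {
    expect_equal(unname(got$gametes[[1]][[ch]]),
                 unname(orig$gametes[[1]][[ch]]))
  }
})
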