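test_that("read_plink_map parses the standard 4-column dialect, 1-based to 0-based", {
  f <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 m1 0 100", "1 m2 0 200000", "2 m3 0 500"), f)
  mm <- read_plink_map(f)
  expect_s3_class(mm, "marker_map")
  expect_equal(nrow(mm), 3)
  expect_equal(length(unique(mm$chrom)), 2)
  expect_equal(mm$bp, c(99, 199999, 499))
  expect_true(all(is.na(mm$genetic_pos)))  # all-zero cM column means unknown
})

test_that("read_plink_map rejects degenerate input", {
  f <- withr::local_tempfile(fileext = ".map")
  writeLines(character(0), f)
  expect_error(read_plink_map(f), "no markers")

  writeLines(c("1 m1 0 100", "1 m2 0 100"), f)
  expect_error(read_plink_map(f), "m2")

  writeLines(c("1 m1 0 xyz"), f)
  expect_error(read_plink_map(f), "non-numeric")

  writeLines(c("1 m1 0 100", "1 m1 0 200"), f)
  expect_error(read_plink_map(f), "duplicate")
})

test_that("write_plink_map / read_plink_map round-trip is the identity", {
  mm <- marker_map(c("1", "1", "2"), c("a", "b", "c"), bp = c(0, 5000, 17),
                   genetic_pos = c(0.1, 2.5, 0.3))
  f <- withr::local_tempfile(fileext = ".map")
  write_plink_map(mm, f)
  back <- read_plink_map(f)
  expect_equal(as.data.frame(back), as.data.frame(mm))
})

test_that("build_rec_map applies the Haldane map function", {
  gs <- genome_spec("1", 2e6)
  rm <- build_rec_map(gs, cM_per_Mb = 1, boundary_spacing_bp = 1e6)
  b <- rm$boundaries[["1"]]
  expect_equal(b$bp, 1e6)
  expect_equal(b$r, 0.5 * (1 - exp(-0.02)))  # 1 cM/Mb over 1 Mb = 0.01 Morgan
  expect_equal(unname(rm$lengths), 2e6)
})

test_that("zero rate gives zero recombination; negative rate errors", {
  rm0 <- build_rec_map(toy_genome(), cM_per_Mb = 0, boundary_spacing_bp = 1e6)
  expect_true(all(unlist(lapply(rm0$boundaries, `[[`, "r")) == 0))
  expect_error(build_rec_map(toy_genome(), cM_per_Mb = -1,
                             boundary_spacing_bp = 1e6), "cM_per_Mb")
})

test_that("r is monotone in the rate and bounded by 1/2", {
  rates <- c(0.1, 1, 10, 100, 1e4)
  rs <- vapply(rates, function(cm) {
    build_rec_map(genome_spec("1", 2e6), cM_per_Mb = cm,
                  boundary_spacing_bp = 1e6)$boundaries[["1"]]$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(rs >= 0 & rs <= 0.5))
})

test_that("marker-spaced boundaries use genetic positions when present", {
  mm <- marker_map(c("1", "1", "1"), c("a", "b", "c"),
                   bp = c(0, 1e6, 3e6), genetic_pos = c(0, 5, 6))
  rm <- build_rec_map(mm, boundary_spacing_bp = "markers")
  expect_equal(rm$boundaries[["1"]]$bp, c(1e6, 3e6))
  expect_equal(rm$boundaries[["1"]]$r,
               0.5 * (1 - exp(-2 * c(0.05, 0.01))))
  expect_equal(unname(rm$lengths[["1"]]), 3e6 + 1)  # covers the last marker
})

test_that("pig-like genome has 18 chromosomes totalling 2.35 Gb", {
  pg <- pig_genome()
  expect_equal(nrow(pg), 18)
  expect_equal(sum(pg$length), 2.35e9)
  rm <- build_rec_map(pg, cM_per_Mb = 1, boundary_spacing_bp = 1e6)
  expect_equal(length(rm$lengths), 18)
  expect_equal(sum(rm$lengths), 2.35e9)
})

test_that("crossover masks honour the map and are reproducible", {
  rm0 <- build_rec_map(toy_genome(), cM_per_Mb = 0, boundary_spacing_bp = 5e5)
  m <- sample_crossover_mask(rm0, "1", seed = 5)
  expect_length(m$breakpoints, 0)
  expect_true(m$start_slot %in% 1:2)
  expect_error(sample_crossover_mask(rm0, "nope"), "unknown chromosome")

  rm1 <- toy_rec_map()
  expect_identical(sample_crossover_mask(rm1, "2", seed = 42),
                   sample_crossover_mask(rm1, "2", seed = 42))
})

test_that("breakpoint counts match the map's switch probabilities", {
  # single boundary at r = 0.5 (very long interval): present ~50% of draws
  rm_half <- build_rec_map(genome_spec("1", 2e9), cM_per_Mb = 100,
                           boundary_spacing_bp = 1e9)
  expect_equal(rm_half$boundaries[["1"]]$r, 0.5, tolerance = 1e-6)
  set.seed(31)
  hits <- sum(replicate(10000, length(sample_crossover_mask(rm_half, "1")$breakpoints)))
  expect_gt(hits, 0.5 * 10000 - 3 * sqrt(10000 * 0.25))
  expect_lt(hits, 0.5 * 10000 + 3 * sqrt(10000 * 0.25))

  # ~1-Morgan chromosome: mean breakpoints per meiosis ~ sum(r)
  rm_m <- build_rec_map(genome_spec("1", 1e8), cM_per_Mb = 1,
                        boundary_spacing_bp = 1e6)
  expected <- sum(rm_m$boundaries[["1"]]$r)
  set.seed(77)
  n_draws <- 4000
  counts <- replicate(n_draws, length(sample_crossover_mask(rm_m, "1")$breakpoints))
  se <- sqrt(expected / n_draws)  # Poisson-binomial variance < mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("recombination maps round-trip through CSV", {
  rm1 <- toy_rec_map()
  f <- withr::local_tempfile(fileext = ".csv")
  write_rec_map(rm1, f)
  back <- read_rec_map(f)
  expect_equal(back$lengths, rm1$lengths)
  expect_equal(back$boundaries, rm1$boundaries)
})
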