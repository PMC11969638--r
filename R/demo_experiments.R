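#' Expected ancestry-genotype frequencies of hybrid categories
#'
#' For a hybrid category between populations A and B, the expected
#' fractions of loci (equivalently, genome) carrying 2, 1 or 0 copies of
#' A ancestry.  Backcrosses are toward A; `bc_generation_probs()` gives
#' the general g-th generation backcross triplet
#' `(1 - 2^-g, 2^-g, 0)`.
#'
#' @param category one of `"pure_a"`, `"pure_b"`, `"F1"`, `"F2"`,
#'   `"BC1"`, `"BC2"`, `"BC1xBC2"` (all backcrosses toward A).
#' @return Named numeric triplet `c(f2, f1, f0)`, summing to 1.
#' @examples
#' hybrid_category_probs("F2")       # 0.25 0.50 0.25
#' hybrid_category_probs("BC1xBC2")  # 0.5625 0.375 0.0625
#' @export
hybrid_category_probs <- function(category) {
  tab <- list(
    pure_a  = c(1, 0, 0),
    pure_b  = c(0, 0, 1),
    F1      = c(0, 1, 0),
    F2      = c(0.25, 0.5, 0.25),
    BC1     = c(0.5, 0.5, 0),
    BC2     = c(0.75, 0.25, 0),
    BC1xBC2 = c(0.5625, 0.375, 0.0625)
  )
  if (!category %in% names(tab)) {
    stop_("unknown category: ", category, "; known: ",
          paste(names(tab), collapse = ", "))
  }
  setNames(tab[[category]], c("f2", "f1", "f0"))
}

#' @rdname hybrid_category_probs
#' @param g backcross generation (>= 1).
#' @export
bc_generation_probs <- function(g) {
  stopifnot(g >= 1)
  setNames(c(1 - 2^-g, 2^-g, 0), c("f2", "f1", "f0"))
}

#' Simulate two reference panels from one population
#'
#' Draws allele frequencies for `L` biallelic loci from a
#' `Beta(beta_a, beta_b)` distribution (default `Beta(1, 8)`, an
#' SNP-ascertainment-like skew toward rare minor alleles), then simulates
#' two panels, A and B, each of `N` diploids, from the *same* frequencies
#' under Hardy-Weinberg equilibrium.  Because both panels come from one
#' population, any apparent power to assign individuals between them is
#' spurious.  Loci are spread uniformly across the supplied genome so the
#' pedigree-segregation pathway can run on them.
#'
#' @param L number of loci.
#' @param N diploids per panel.
#' @param beta_a,beta_b Beta shape parameters of the allele-frequency
#'   distribution.
#' @param genome a [genome_spec()] the loci are placed on.
#' @param seed optional integer seed.
#' @return List with `panel_a`, `panel_b` (both [genotype_matrix()], pops
#'   `"A"` and `"B"`), `freqs` (true frequency of allele "1") and `map`.
#' @export
sim_reference_panels <- function(L, N, beta_a = 1, beta_b = 8,
                                 genome = pig_genome(), seed = NULL) {
  if (L < 1 || N < 1) stop_("L and N must be >= 1")
  if (beta_a <= 0 || beta_b <= 0) stop_("Beta shapes must be > 0")
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(L, beta_a, beta_b)

  # evenly spread loci along the concatenated genome
  total <- sum(genome$length)
  pos <- floor((seq_len(L) - 0.5) / L * total)
  ends <- cumsum(genome$length)
  ci <- findInterval(pos, c(0, ends), rightmost.closed = TRUE)
  bp <- pos - c(0, ends)[ci]
  map <- marker_map(chrom = genome$chrom[ci],
                    marker_id = paste0("m", seq_len(L)),
                    bp = bp)

  draw_panel <- function(prefix, popl) {
    rnd <- matrix(runif(N * 2L * L), nrow = N)
    al <- ifelse(sweep(rnd, 2L, rep(p, each = 2L), "<"), "1", "2")
    genotype_matrix(al, ids = paste0(prefix, "_", seq_len(N)),
                    pops = rep(popl, N), map = map)
  }
  panel_a <- draw_panel("A", "A")
  panel_b <- draw_panel("B", "B")
  list(panel_a = panel_a, panel_b = panel_b, freqs = p, map = map)
}

# observed frequency of allele "1" per locus in a geno_matrix
allele_freqs <- function(geno, allele = "1") {
  g <- geno$geno
  L <- ncol(g) / 2L
  a <- g[, 2L * seq_len(L) - 1L, drop = FALSE] == allele
  b <- g[, 2L * seq_len(L), drop = FALSE] == allele
  (colSums(a, na.rm = TRUE) + colSums(b, na.rm = TRUE)) /
    (colSums(!is.na(a)) + colSums(!is.na(b)))
}

#' Simulate admixed individuals by sampling with replacement
#'
#' The classical (RISPI-prone) simulator: per individual, per locus, per
#' gene copy, the copy's origin is population A with probability `q_a`,
#' and its allele is then drawn uniformly *with replacement* from that
#' panel's `2N` gene copies at the locus -- the admixture model of
#' structure-style programs applied to sample frequencies as if they were
#' population frequencies.
#'
#' @param panel_a,panel_b [genotype_matrix()] panels sharing a map.
#' @param q_a admixture fraction for population A, in `[0, 1]`.
#' @param n number of individuals to simulate.
#' @param seed optional integer seed.
#' @return A [genotype_matrix()] with `n` rows (pops `"sim"`).
#' @export
sim_admixed_with_replacement <- function(panel_a, panel_b, q_a, n,
                                         seed = NULL) {
  if (q_a < 0 || q_a > 1) stop_("q_a must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(panel_a)
  if (n_loci(panel_b) != L) stop_("panels differ in locus count")
  out <- matrix(NA_character_, nrow = n, ncol = 2L * L)
  if (n > 0) {
    ga <- panel_a$geno; gb <- panel_b$geno
    M <- 2L * L
    ncell <- n * M
    # source column: either member of the cell's locus pair, at random
    base_col <- matrix(rep(2L * rep(seq_len(L), each = 2L) - 1L, each = n),
                       nrow = n)
    src_col <- base_col + (runif(ncell) < 0.5)
    from_a <- matrix(runif(ncell) < q_a, nrow = n)
    pick_a <- cbind(sample.int(nrow(ga), ncell, replace = TRUE),
                    as.vector(src_col))
    pick_b <- cbind(sample.int(nrow(gb), ncell, replace = TRUE),
                    as.vector(src_col))
    out <- matrix(ifelse(as.vector(from_a), ga[pick_a], gb[pick_b]), nrow = n)
  }
  genotype_matrix(out, ids = if (n > 0) paste0("wr_", seq_len(n)) else character(0),
                  pops = rep("sim", n), map = panel_a$map)
}

#' Simulate hybrids with unlinked loci
#'
#' The hybridlab-style simulator: each locus independently receives 2, 1
#' or 0 gene copies of population-A ancestry according to the hybrid
#' category's expected triplet, then alleles are drawn with replacement
#' from the corresponding panels.  The recorded admixture fraction is the
#' fraction of all `2L` gene copies with A ancestry -- with independent
#' loci its variance shrinks like `1/L`, which is the unrealistic
#' narrowing the linked (pedigree) simulation corrects.
#'
#' @inheritParams sim_admixed_with_replacement
#' @param probs a triplet `c(f2, f1, f0)` (see [hybrid_category_probs()]).
#' @param genotypes if `FALSE`, skip allele drawing and return only the
#'   admixture fractions (cheap at very large `L`).
#' @return A list with `geno` (a [genotype_matrix()] or `NULL`) and `q`
#'   (numeric vector of admixture fractions).
#' @export
sim_unlinked_hybrids <- function(panel_a, panel_b, probs, n,
                                 genotypes = TRUE, seed = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L || any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop_("probs must be a nonnegative triplet summing to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(panel_a)
  copies <- matrix(sample(c(2L, 1L, 0L), n * L, replace = TRUE, prob = probs),
                   nrow = n)
  q <- rowSums(copies) / (2 * L)
  geno <- NULL
  if (genotypes && n > 0) {
    ga <- panel_a$geno; gb <- panel_b$geno
    out <- matrix(NA_character_, nrow = n, ncol = 2L * L)
    for (j in seq_len(L)) {
      cols <- c(2L * j - 1L, 2L * j)
      cp <- copies[, j]
      for (s in 1:2) {
        from_a <- cp >= s  # A-origin copies occupy the first slots
        pick_a <- cbind(sample.int(nrow(ga), n, replace = TRUE),
                        sample(cols, n, replace = TRUE))
        pick_b <- cbind(sample.int(nrow(gb), n, replace = TRUE),
                        sample(cols, n, replace = TRUE))
        out[, cols[s]] <- ifelse(from_a, ga[pick_a], gb[pick_b])
      }
    }
    geno <- genotype_matrix(out, ids = paste0("ul_", seq_len(n)),
                            pops = rep("sim", n), map = panel_a$map)
  }
  list(geno = geno, q = q)
}

#' Supervised maximum-likelihood admixture estimate
#'
#' Estimates each individual's admixture fraction `q` under the admixture
#' model with known reference allele frequencies: each gene copy comes
#' from population A with probability `q`, and its allele is then
#' distributed according to A's frequencies (likewise B).  The MLE over
#' `q` in `[0, 1]` is found by EM; a completely flat likelihood (equal
#' frequencies everywhere, or no informative loci) yields the tie-break
#' value 0.5.  Frequencies are clamped away from 0 and 1 before
#' evaluation to keep the log-likelihood finite at fixed loci; pass
#' `clamp = 1/(2N + 1)` to mimic adding a pseudo-count to a reference
#' sample of `N` diploids.
#'
#' @param genos a character matrix (individuals x `2L` allele columns), a
#'   single allele vector, or a [genotype_matrix()].
#' @param freq_a,freq_b per-locus frequencies of `ref_allele` in the two
#'   reference populations.
#' @param ref_allele the allele the frequencies refer to.
#' @param clamp frequencies are clamped to `[clamp, 1 - clamp]`.
#' @param tol EM convergence tolerance on `q`.
#' @param max_iter maximum EM iterations.
#' @return A tibble with one row per individual: `id`, `q_hat`, `loglik`,
#'   `iters`.
#' @export
supervised_q_mle <- function(genos, freq_a, freq_b, ref_allele = "1",
                             clamp = 1e-6, tol = 1e-6, max_iter = 500L) {
  if (is_geno_matrix(genos)) {
    ids <- genos$ids
    genos <- genos$geno
  } else if (is.null(dim(genos))) {
    genos <- matrix(genos, nrow = 1)
    ids <- "1"
  } else {
    ids <- rownames(genos) %||% as.character(seq_len(nrow(genos)))
  }
  L <- ncol(genos) / 2L
  stopifnot(length(freq_a) == L, length(freq_b) == L)
  pa <- pmin(pmax(freq_a, clamp), 1 - clamp)
  pb <- pmin(pmax(freq_b, clamp), 1 - clamp)

  cnt <- ref_allele_counts(genos, ref_allele)
  G1 <- cnt$g1; G0 <- cnt$g0
  n_obs <- rowSums(G1 + G0)
  if (any(n_obs == 0L)) warn_("individual(s) with no informative loci; q_hat = 0.5")

  n <- nrow(genos)
  q <- rep(0.5, n)
  iters <- rep(0L, n)
  active <- n_obs > 0L
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    qa <- q[active]
    n1 <- qa %o% pa;       z1 <- n1 / (n1 + (1 - qa) %o% pb)
    n0 <- qa %o% (1 - pa); z0 <- n0 / (n0 + (1 - qa) %o% (1 - pb))
    q_new <- rowSums(G1[active, , drop = FALSE] * z1 +
                       G0[active, , drop = FALSE] * z0) / n_obs[active]
    moved <- abs(q_new - qa) >= tol
    q[active] <- q_new
    iters[active] <- it
    active[active] <- moved
  }
  ll <- rowSums(G1 * log(q %o% pa + (1 - q) %o% pb) +
                  G0 * log(q %o% (1 - pa) + (1 - q) %o% (1 - pb)))
  ll[n_obs == 0L] <- 0
  tibble(id = ids, q_hat = q, loglik = ll, iters = iters)
}

#' Supervised admixture estimation with joint frequency re-estimation
#'
#' The package's stand-in for a supervised ADMIXTURE run: labeled
#' reference individuals anchor the two clusters, but cluster allele
#' frequencies are re-estimated at every EM step from the labeled
#' individuals *plus* the unknowns, each unknown contributing to the two
#' clusters in proportion to the posterior origin of each of its gene
#' copies.  This joint re-estimation is how supervised
#' structure/ADMIXTURE analyses actually treat a data set and matters
#' when the unknowns hold a large share of the total genetic material.
#' A small symmetric pseudo-count keeps frequencies off the boundary.
#'
#' @param unknowns a [genotype_matrix()] (or character matrix) of the
#'   individuals whose admixture fractions are estimated.
#' @param labeled_a,labeled_b [genotype_matrix()] (or character matrix)
#'   reference individuals of the two clusters.
#' @param ref_allele allele whose frequency is modelled.
#' @param pseudo symmetric pseudo-count added per cluster per locus.
#' @param tol convergence tolerance: the EM stops when no admixture
#'   fraction moves by more than this between iterations (default 1e-4,
#'   an order below the precision at which fractions are interpreted).
#' @param max_iter maximum EM iterations.
#' @return A tibble: `id`, `q_hat` (fraction from cluster A), `loglik`,
#'   `iters`.
#' @export
supervised_admixture_em <- function(unknowns, labeled_a, labeled_b,
                                    ref_allele = "1", pseudo = 0.5,
                                    tol = 1e-4, max_iter = 200L) {
  ids <- if (is_geno_matrix(unknowns)) unknowns$ids else
    rownames(unknowns) %||% as.character(seq_len(nrow(as.matrix(unknowns))))
  cnt <- ref_allele_counts(unknowns, ref_allele)
  G1 <- cnt$g1; G0 <- cnt$g0                # n x L counts of ref / alt copies
  ca <- ref_allele_counts(labeled_a, ref_allele)
  cb <- ref_allele_counts(labeled_b, ref_allele)
  cA1 <- colSums(ca$g1); cAt <- colSums(ca$g1 + ca$g0)
  cB1 <- colSums(cb$g1); cBt <- colSums(cb$g1 + cb$g0)

  n <- nrow(G1)
  n_obs <- rowSums(G1 + G0)
  cG1 <- colSums(G1)
  cGt <- colSums(G1 + G0)
  q <- rep(0.5, n)
  pA <- (cA1 + pseudo) / (cAt + 2 * pseudo)
  pB <- (cB1 + pseudo) / (cBt + 2 * pseudo)
  it <- 0L
  repeat {
    it <- it + 1L
    # posterior that a ref-allele (z1) or alt-allele (z0) copy came from A
    n1 <- q %o% pA;       z1 <- n1 / (n1 + (1 - q) %o% pB)
    n0 <- q %o% (1 - pA); z0 <- n0 / (n0 + (1 - q) %o% (1 - pB))
    WA1 <- G1 * z1
    S <- WA1 + G0 * z0
    q_new <- rowSums(S) / n_obs
    csWA1 <- colSums(WA1)
    csS <- colSums(S)
    pA <- (cA1 + csWA1 + pseudo) / (cAt + csS + 2 * pseudo)
    pB <- (cB1 + cG1 - csWA1 + pseudo) / (cBt + cGt - csS + 2 * pseudo)
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol || it >= max_iter) break
  }
  ll <- rowSums(G1 * log(q %o% pA + (1 - q) %o% pB) +
                  G0 * log(q %o% (1 - pA) + (1 - q) %o% (1 - pB)))
  tibble(id = ids, q_hat = q, loglik = ll, iters = it)
}

# per-locus counts of the reference and alternate allele copies, NA-aware
ref_allele_counts <- function(geno, ref_allele = "1") {
  g <- if (is_geno_matrix(geno)) geno$geno else as.matrix(geno)
  L <- ncol(g) / 2L
  odd <- 2L * seq_len(L) - 1L
  x1 <- g[, odd, drop = FALSE] == ref_allele
  x2 <- g[, odd + 1L, drop = FALSE] == ref_allele
  g1 <- (!is.na(x1) & x1) + (!is.na(x2) & x2)
  g0 <- (!is.na(x1) & !x1) + (!is.na(x2) & !x2)
  list(g1 = g1, g0 = g0)
}

#' Run the resampling-bias (RISPI) experiment
#'
#' The motivating experiment: two reference panels drawn from a *single*
#' population, so true assignment power is nil; admixed individuals are
#' then simulated across a grid of nominal admixture fractions and their
#' `q` re-estimated by the supervised MLE.  With
#' `method = "with_replacement"` the estimates track the nominal values
#' -- a pure resampling artefact.  With `method = "gsp"` individuals are
#' built by pedigree segregation and painting (alleles used without
#' replacement; reference frequencies computed from the retained,
#' non-founder individuals), and the estimates centre on 0.5 at every
#' nominal value.
#'
#' @details
#' Mirroring the original experimental design, each replicate forms *one*
#' analysis data set holding new individuals at every nominal `q`
#' together with the reference individuals, and the whole set is analysed
#' at once with [supervised_admixture_em()].  In the pedigree arm the
#' nine grid pedigrees are segregated together as one disjoint-union GSP
#' so founder consumption is globally conservative; the labeled
#' references are the retained (non-founder) individuals.  In the
#' with-replacement arm the labeled references are the full panels (no
#' material is consumed there).  With `n_per_q = 2` the union pedigree
#' consumes 20 individuals per population per union replicate, so
#' `N >= 20 * ceiling(n_per_q / 2)` is required for the pedigree arm.
#'
#' @param method `"with_replacement"` or `"gsp"`.
#' @param L loci per panel.
#' @param N diploids per panel.
#' @param n_per_q new individuals per nominal `q` per replicate.
#' @param reps number of replicates (fresh panels each).
#' @param q_grid nominal admixture fractions (must lie on the
#'   [gsp_for_q()] grid when `method = "gsp"`).
#' @param genome genome the loci are spread over.
#' @param cM_per_Mb assumed recombination rate for the pedigree arm.
#' @param seed integer seed.
#' @return A tibble: `method`, `L`, `N`, `n_per_q`, `rep`, `q_nominal`,
#'   `id`, `q_hat`.
#' @export
run_rispi_experiment <- function(method = c("with_replacement", "gsp"),
                                 L = 1000, N = 50, n_per_q = 2, reps = 40,
                                 q_grid = c(0, 1/8, 1/4, 3/8, 1/2,
                                            5/8, 3/4, 7/8, 1),
                                 genome = pig_genome(), cM_per_Mb = 1,
                                 seed = NULL) {
  method <- match.arg(method)
  rep_seeds <- derive_seeds(reps, seed)

  if (method == "gsp") {
    # one disjoint-union pedigree realising the whole grid; target sample
    # nodes tracked per q
    specs <- lapply(q_grid, gsp_for_q, pop_a = "A", pop_b = "B")
    parts <- Map(function(sp, i) prefix_gsp(sp$gsp, sprintf("q%d_", i)),
                 specs, seq_along(specs))
    union_gsp <- make_gsp(
      do.call(rbind, lapply(parts, function(g) g$nodes)),
      do.call(rbind, lapply(parts, function(g) g$edges)),
      do.call(c, lapply(parts, function(g) attr(g, "sample_categories"))),
      c("A", "B")
    )
    target_nodes <- lapply(seq_along(specs), function(i)
      paste0(sprintf("q%d_", i), sub("^s", "", specs[[i]]$target_nodes)))
    u <- as.integer(ceiling(n_per_q / 2))
    founders_per_pop <- table(union_gsp$nodes$hpop1[union_gsp$nodes$kind == "founder"])
    if (any(founders_per_pop * u > N)) {
      stop_("N = ", N, " too small: the union pedigree needs ",
            max(founders_per_pop) * u, " founders per population")
    }
  }

  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    pan <- sim_reference_panels(L, N, genome = genome)
    if (method == "with_replacement") {
      sims <- lapply(q_grid, function(q)
        sim_admixed_with_replacement(pan$panel_a, pan$panel_b, q, n_per_q)$geno)
      unknowns <- genotype_matrix(
        do.call(rbind, sims),
        ids = sprintf("wr_q%d_%d", rep(seq_along(q_grid), each = n_per_q),
                      seq_len(length(q_grid) * n_per_q)),
        pops = rep("sim", length(q_grid) * n_per_q), map = pan$map
      )
      est <- supervised_admixture_em(unknowns, pan$panel_a, pan$panel_b)
      q_nom <- rep(q_grid, each = n_per_q)
    } else {
      rec_map <- build_rec_map(pan$map, cM_per_Mb = cM_per_Mb,
                               boundary_spacing_bp = "markers")
      both <- combine_panels(pan$panel_a, pan$panel_b)
      seg <- segregate(union_gsp, rec_map, n_reps = u)
      painted <- segments2markers(seg$samples, seg$ledger, both,
                                  plan = permutation_plan())
      node_of <- vapply(seg$samples, `[[`, character(1), "node")
      keep <- unlist(lapply(target_nodes, function(tn)
        which(node_of %in% tn)[seq_len(n_per_q)]))
      unknowns <- subset_geno(painted$simulated, keep)
      ret <- painted$retained
      est <- supervised_admixture_em(
        unknowns,
        subset_geno(ret, ret$pops == "A"),
        subset_geno(ret, ret$pops == "B")
      )
      q_nom <- rep(q_grid, each = n_per_q)
    }
    out[[r]] <- tibble(method = method, L = L, N = N, n_per_q = n_per_q,
                       rep = r, q_nominal = q_nom, id = est$id,
                       q_hat = est$q_hat)
  }
  do.call(rbind, out)
}

#' Combine genotype matrices row-wise
#' @param ... [genotype_matrix()] objects sharing a map.
#' @return A single `geno_matrix`.
#' @export
combine_panels <- function(...) {
  parts <- list(...)
  genotype_matrix(do.call(rbind, lapply(parts, function(p) p$geno)),
                  ids = unlist(lapply(parts, `[[`, "ids")),
                  pops = unlist(lapply(parts, `[[`, "pops")),
                  map = parts[[1]]$map,
                  phased = all(vapply(parts, `[[`, logical(1), "phased")))
}

#' Subset a genotype matrix by individuals
#' @param geno a [genotype_matrix()].
#' @param i row indices or a logical vector.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(geno, i) {
  genotype_matrix(geno$geno[i, , drop = FALSE], ids = geno$ids[i],
                  pops = geno$pops[i], map = geno$map, phased = geno$phased)
}

#' Segment-based admixture fractions for a hybrid category
#'
#' Convenience wrapper: simulates `n` individuals of the requested
#' category through its preset pedigree on `rec_map` and returns their
#' segment-length admixture fractions for the recurrent/first population.
#'
#' @param category `"F1"`, `"F2"`, `"BC1"`, `"BC2"`, `"BCg"` for g >= 3
#'   (e.g. `"BC3"`), or `"BC1xBC2"`.
#' @param n number of individuals (rounded up to whole pedigree
#'   replicates).
#' @param rec_map a [build_rec_map()] map.
#' @param pop_a,pop_b population labels; fractions are reported for
#'   `pop_a`.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` admixture fractions.
#' @export
sim_linked_admixture <- function(category, n, rec_map,
                                 pop_a = "A", pop_b = "B", seed = NULL) {
  spec <- switch(category,
    F1 = list(gsp = create_gsp(pop_a, pop_b, f1 = TRUE), target = "F1"),
    F2 = list(gsp = create_gsp(pop_a, pop_b, f2 = TRUE), target = "F2"),
    BC1 = list(gsp = create_gsp(pop_a, pop_b, bc1 = TRUE), target = "BC1"),
    BC2 = list(gsp = create_gsp(pop_a, pop_b, bc2 = TRUE), target = "BC2"),
    BC1xBC2 = list(gsp = gsp_bc1xbc2(pop_a, pop_b), target = "BC1xBC2"),
    {
      g <- suppressWarnings(as.integer(sub("^BC", "", category)))
      if (is.na(g)) stop_("unknown category: ", category)
      list(gsp = create_bc_ladder(g, pop_a, pop_b), target = paste0("BC", g))
    }
  )
  cats <- attr(spec$gsp, "sample_categories")
  st <- gsp_sample_table(spec$gsp)
  per_rep <- sum(st$n_samples[cats[st$id] == spec$target])
  res <- segregate(spec$gsp, rec_map, n_reps = ceiling(n / per_rep),
                   seed = seed)
  keep <- vapply(res$samples, function(s) s$category == spec$target, logical(1))
  q <- admixture_fractions(res$samples[keep], pop_a, res$ledger)
  q[seq_len(n)]
}
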