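#' Genotype matrices
#'
#' The package's genotype container: `N` individuals by `2L` allele
#' columns (two adjacent entries per locus, the "a" and "b" gene copies),
#' with one population label per individual and per-locus metadata from a
#' [marker_map()].  Missing alleles are `NA` internally (written as "0" in
#' PLINK files).
#'
#' @param geno character (or coercible) matrix, `N x 2L`.
#' @param ids individual ids (unique).
#' @param pops population label per individual (each individual belongs to
#'   exactly one population).
#' @param map a [marker_map()] with `L` rows, or `NULL` if no positional
#'   metadata exists (some permutation modes then become unavailable).
#' @param phased set `TRUE` only if the data are phased so that the "a"
#'   entries form one haplotype and the "b" entries the other.
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(geno, ids, pops, map = NULL, phased = FALSE) {
  geno <- as.matrix(geno)
  mode(geno) <- "character"
  if (length(ids) != nrow(geno)) stop_("ids must match rows of geno")
  if (length(pops) != nrow(geno)) stop_("pops must match rows of geno")
  if (anyDuplicated(ids)) stop_("duplicate individual ids")
  if (ncol(geno) %% 2L != 0L) stop_("geno needs an even number of columns")
  if (!is.null(map)) {
    stopifnot(is_marker_map(map))
    if (nrow(map) * 2L != ncol(geno)) {
      stop_("map has ", nrow(map), " loci but geno has ", ncol(geno) / 2L)
    }
  }
  structure(list(geno = geno, ids = as.character(ids),
                 pops = as.character(pops), map = map,
                 phased = isTRUE(phased)),
            class = "geno_matrix")
}

is_geno_matrix <- function(x) inherits(x, "geno_matrix")

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "individuals x", ncol(x$geno) / 2L,
      "loci;", length(unique(x$pops)), "population(s)",
      if (x$phased) "(phased)" else "", "\n")
  invisible(x)
}

n_loci <- function(geno) ncol(geno$geno) / 2L

#' Permutation plans
#'
#' Describes how genotypes are scrambled within populations before founder
#' assignment.  `preserve_individuals` selects the permuted unit:
#' `TRUE` moves whole individuals, `"BY_CHROM"` moves each individual's
#' homologous chromosome pair independently per chromosome (preserving
#' within-chromosome LD), and `FALSE` scrambles single gene copies per
#' locus.  With `preserve_individuals = FALSE`, setting
#' `preserve_haplotypes = TRUE` makes whole per-chromosome haplotype
#' blocks the shuffled unit instead of single gene copies (only meaningful
#' for phased data).  All modes permute strictly within populations, so
#' per-population allele frequencies are conserved exactly.
#'
#' @param preserve_individuals `TRUE`, `"BY_CHROM"`, or `FALSE`.
#' @param preserve_haplotypes logical.
#' @param seed optional integer seed.
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(preserve_individuals = TRUE,
                             preserve_haplotypes = FALSE,
                             seed = NULL) {
  pi_ok <- isTRUE(preserve_individuals) || isFALSE(preserve_individuals) ||
    identical(preserve_individuals, "BY_CHROM")
  if (!pi_ok) stop_("preserve_individuals must be TRUE, FALSE or \"BY_CHROM\"")
  structure(list(preserve_individuals = preserve_individuals,
                 preserve_haplotypes = isTRUE(preserve_haplotypes),
                 seed = seed, src_row = NULL, src_col = NULL),
            class = "permutation_plan")
}

#' Permute genotypes within populations
#'
#' Applies a [permutation_plan()] to a [genotype_matrix()].  The filled
#' plan records, for every output cell, the original (row, column) address
#' of the gene copy now occupying it -- a within-population bijection, so
#' the permutation is exactly invertible (see [unpermute_genotypes()])
#' and no allele ever changes population.
#'
#' Missing alleles are permuted like any observed value, so per-locus
#' allele and missingness counts are conserved.
#'
#' @param geno a [genotype_matrix()].
#' @param plan a [permutation_plan()].
#' @return A list with `geno` (the permuted matrix) and `plan` (with the
#'   provenance maps `src_row`, `src_col` filled in).
#' @export
permute_genotypes <- function(geno, plan = permutation_plan()) {
  stopifnot(is_geno_matrix(geno), inherits(plan, "permutation_plan"))
  if (!is.null(plan$seed)) set.seed(plan$seed)
  N <- nrow(geno$geno)
  M <- ncol(geno$geno)
  mode_pi <- plan$preserve_individuals
  ph <- plan$preserve_haplotypes
  needs_chrom <- identical(mode_pi, "BY_CHROM") ||
    (isFALSE(mode_pi) && ph)
  if (needs_chrom && is.null(geno$map)) {
    stop_("this permutation mode needs chromosome metadata (a marker map)")
  }
  if (ph && !geno$phased) {
    warn_("preserve_haplotypes = TRUE but data are not flagged as phased; proceeding")
  }

  src_row <- matrix(rep(seq_len(N), M), nrow = N)
  src_col <- matrix(rep(seq_len(M), each = N), nrow = N)
  pops <- unique(geno$pops)
  chrom_cols <- NULL
  if (!is.null(geno$map)) {
    loci_by_chrom <- split(seq_len(n_loci(geno)), geno$map$chrom)
    chrom_cols <- lapply(loci_by_chrom, function(j) {
      list(a = 2L * j - 1L, b = 2L * j, all = as.vector(rbind(2L * j - 1L, 2L * j)))
    })
  }

  for (p in pops) {
    rows <- which(geno$pops == p)
    n <- length(rows)
    if (isTRUE(mode_pi)) {
      perm <- sample.int(n)
      src_row[rows, ] <- src_row[rows[perm], , drop = FALSE]
    } else if (identical(mode_pi, "BY_CHROM")) {
      # chromosome-level sub-streams: independent and reproducible per
      # (population, chromosome)
      ch_seeds <- derive_seeds(length(chrom_cols))
      for (k in seq_along(chrom_cols)) {
        set.seed(ch_seeds[k])
        cc <- chrom_cols[[k]]$all
        perm <- sample.int(n)
        src_row[rows, cc] <- src_row[rows[perm], cc, drop = FALSE]
      }
    } else if (!ph) {
      # free scrambling: per locus, all 2n gene copies shuffled
      for (j in seq_len(M / 2L)) {
        cols <- c(2L * j - 1L, 2L * j)
        cells_r <- rep(rows, 2L)
        cells_c <- rep(cols, each = n)
        perm <- sample.int(2L * n)
        src_row[cbind(cells_r, cells_c)] <- cells_r[perm]
        src_col[cbind(cells_r, cells_c)] <- cells_c[perm]
      }
    } else {
      # haplotype blocks per chromosome are the shuffled units
      for (k in seq_along(chrom_cols)) {
        ca <- chrom_cols[[k]]$a
        cb <- chrom_cols[[k]]$b
        # 2n haplotype slots: (row, strand); permute source units onto them
        unit_row <- rep(rows, 2L)
        unit_strand <- rep(c(1L, 2L), each = n)
        perm <- sample.int(2L * n)
        for (s in seq_len(2L * n)) {
          dest_cols <- if (unit_strand[s] == 1L) ca else cb
          srcu <- perm[s]
          src_cols <- if (unit_strand[srcu] == 1L) ca else cb
          src_row[unit_row[s], dest_cols] <- unit_row[srcu]
          src_col[unit_row[s], dest_cols] <- src_cols
        }
      }
    }
  }

  out <- geno
  out$geno <- matrix(geno$geno[cbind(as.vector(src_row), as.vector(src_col))],
                     nrow = N)
  plan$src_row <- src_row
  plan$src_col <- src_col
  list(geno = out, plan = plan)
}

#' Invert a filled permutation plan
#'
#' Recovers the original genotype matrix from a permuted one using the
#' provenance map recorded in the plan.
#'
#' @param permuted the permuted [genotype_matrix()].
#' @param plan the filled plan returned by [permute_genotypes()].
#' @return The original `geno_matrix`.
#' @export
unpermute_genotypes <- function(permuted, plan) {
  stopifnot(is_geno_matrix(permuted), !is.null(plan$src_row))
  out <- permuted
  g <- permuted$geno
  orig <- g
  orig[cbind(as.vector(plan$src_row), as.vector(plan$src_col))] <- as.vector(g)
  out$geno <- orig
  out
}
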