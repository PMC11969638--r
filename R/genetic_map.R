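#' Marker maps
#'
#' A marker map lists genotyped markers with their chromosome, identifier,
#' optional genetic position (centiMorgans) and physical position.  Physical
#' positions are stored 0-based internally; the PLINK `.map` readers and
#' writers convert from/to the 1-based convention of the file format.
#'
#' @param chrom chromosome id per marker (character or integer).
#' @param marker_id unique marker ids.
#' @param bp 0-based physical positions; strictly increasing within each
#'   chromosome.
#' @param genetic_pos optional genetic positions in cM (`NA` when unknown).
#' @return A tibble of class `marker_map` with columns `chrom`, `marker_id`,
#'   `genetic_pos`, `bp`.
#' @export
marker_map <- function(chrom, marker_id, bp, genetic_pos = NA_real_) {
  chrom <- as.character(chrom)
  marker_id <- as.character(marker_id)
  bp <- as.numeric(bp)
  genetic_pos <- rep_len(as.numeric(genetic_pos), length(bp))
  if (length(chrom) != length(bp) || length(marker_id) != length(bp)) {
    stop_("marker map columns differ in length")
  }
  if (length(bp) == 0L) stop_("no markers")
  if (anyDuplicated(marker_id)) {
    stop_("duplicate marker ids: ",
          paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  }
  if (any(!is.finite(bp)) || any(bp < 0)) stop_("bp positions must be >= 0")
  for (ch in unique(chrom)) {
    b <- bp[chrom == ch]
    if (any(diff(b) <= 0)) {
      bad <- marker_id[chrom == ch][which(diff(b) <= 0)[1] + 1L]
      stop_("bp positions not strictly increasing on chromosome ", ch,
            " at marker ", bad)
    }
  }
  out <- tibble(chrom = chrom, marker_id = marker_id,
                genetic_pos = genetic_pos, bp = bp)
  class(out) <- c("marker_map", class(out))
  out
}

is_marker_map <- function(x) inherits(x, "marker_map")

#' Read a PLINK .map file
#'
#' Reads the standard 4-column whitespace-separated PLINK marker map
#' (chromosome, marker id, genetic position in cM, physical position in bp).
#' Physical positions are 1-based in the file and converted to 0-based
#' internal coordinates.  A genetic position of 0 for every marker is
#' treated as "unknown" (the PLINK convention when no genetic map exists).
#'
#' @param path path to a `.map` file.
#' @return A [marker_map()].
#' @export
read_plink_map <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) stop_("no markers in ", path)
  )
  if (nrow(tab) == 0L) stop_("no markers in ", path)
  if (ncol(tab) != 4L) stop_("expected 4 columns in ", path, ", found ", ncol(tab))
  g <- suppressWarnings(as.numeric(tab[[3]]))
  bp <- suppressWarnings(as.numeric(tab[[4]]))
  if (anyNA(bp)) {
    stop_("non-numeric bp position at marker ", tab[[2]][which(is.na(bp))[1]])
  }
  if (anyNA(g)) {
    stop_("non-numeric genetic position at marker ", tab[[2]][which(is.na(g))[1]])
  }
  if (all(g == 0)) g <- NA_real_
  marker_map(chrom = tab[[1]], marker_id = tab[[2]], bp = bp - 1, genetic_pos = g)
}

#' Write a marker map to PLINK .map format
#'
#' Inverse of [read_plink_map()]: internal 0-based bp become 1-based,
#' unknown genetic positions are written as 0.
#'
#' @param map a [marker_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plink_map <- function(map, path) {
  stopifnot(is_marker_map(map))
  g <- ifelse(is.na(map$genetic_pos), 0, map$genetic_pos)
  tab <- data.frame(map$chrom, map$marker_id, g, format(map$bp + 1, scientific = FALSE, trim = TRUE))
  write.table(tab, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a recombination map
#'
#' Converts a marker map or a bare genome specification into a
#' recombination map: for each chromosome, an ordered set of interior
#' boundary positions, each carrying the probability `r` that a gamete
#' switches parental haplotype there during one meiosis.  `r` is obtained
#' from the genetic distance `d` (in Morgans) spanned by the interval
#' ending at the boundary through the Haldane map function
#' `r = 0.5 * (1 - exp(-2 d))`, which assumes crossovers occur without
#' interference.  When the source map carries no genetic positions,
#' distance is `cM_per_Mb` times physical distance (default 1 cM/Mb, a
#' standard genome-average rate).
#'
#' @param source a [marker_map()] or a [genome_spec()].
#' @param cM_per_Mb recombination rate used when genetic positions are
#'   absent; must be >= 0.
#' @param boundary_spacing_bp `"markers"` to place boundaries at marker
#'   positions (marker-map sources only), or a positive integer: boundaries
#'   at every multiple of this spacing.
#' @return An object of class `recomb_map`: a list with `lengths` (named
#'   numeric, bp per chromosome) and `boundaries` (per chromosome, a list
#'   with numeric vectors `bp` and `r`).
#' @examples
#' gs <- genome_spec("1", 2e6)
#' rm <- build_rec_map(gs, cM_per_Mb = 1, boundary_spacing_bp = 1e6)
#' rm$boundaries[["1"]]$r  # 0.5 * (1 - exp(-0.02))
#' @export
build_rec_map <- function(source, cM_per_Mb = 1,
                          boundary_spacing_bp = "markers") {
  if (!is.finite(cM_per_Mb) || cM_per_Mb < 0) stop_("cM_per_Mb must be >= 0")
  at_markers <- identical(boundary_spacing_bp, "markers")
  if (!at_markers) {
    boundary_spacing_bp <- as.numeric(boundary_spacing_bp)
    if (!is.finite(boundary_spacing_bp) || boundary_spacing_bp <= 0) {
      stop_("boundary_spacing_bp must be a positive number or \"markers\"")
    }
  }

  if (is_genome_spec(source)) {
    if (at_markers) {
      stop_("boundary_spacing_bp = \"markers\" needs a marker map source")
    }
    lengths <- setNames(source$length, source$chrom)
    per_chrom_markers <- NULL
  } else if (is_marker_map(source)) {
    # chromosome covers all of its markers: length = last marker bp + 1
    lengths <- vapply(split(source$bp, source$chrom)[unique(source$chrom)],
                      function(b) max(b) + 1, numeric(1))
    per_chrom_markers <- split(source, source$chrom)[unique(source$chrom)]
  } else {
    stop_("source must be a marker_map or genome_spec")
  }
  if (any(lengths <= 0)) stop_("zero-length chromosome in source")

  boundaries <- lapply(names(lengths), function(ch) {
    L <- lengths[[ch]]
    mm <- if (is.null(per_chrom_markers)) NULL else per_chrom_markers[[ch]]
    has_gen <- !is.null(mm) && !anyNA(mm$genetic_pos)
    if (at_markers) {
      if (nrow(mm) < 2L) return(list(bp = numeric(0), r = numeric(0)))
      bp <- mm$bp[-1L]
      d <- if (has_gen) diff(mm$genetic_pos) / 100
           else diff(mm$bp) * cM_per_Mb / 1e6 / 100
    } else {
      bp <- seq(boundary_spacing_bp, L - 1, by = boundary_spacing_bp)
      bp <- bp[bp > 0 & bp < L]
      if (length(bp) == 0L) return(list(bp = numeric(0), r = numeric(0)))
      if (has_gen) {
        # interpolate the cumulative genetic map at boundary positions
        cum <- approx(x = mm$bp, y = mm$genetic_pos, xout = c(0, bp),
                      rule = 2, ties = "ordered")$y
        d <- diff(cum) / 100
      } else {
        d <- diff(c(0, bp)) * cM_per_Mb / 1e6 / 100
      }
    }
    list(bp = as.numeric(bp), r = 0.5 * (1 - exp(-2 * d)))
  })
  names(boundaries) <- names(lengths)
  structure(list(lengths = lengths, boundaries = boundaries),
            class = "recomb_map")
}

is_recomb_map <- function(x) inherits(x, "recomb_map")

#' @export
print.recomb_map <- function(x, ...) {
  nb <- vapply(x$boundaries, function(b) length(b$bp), integer(1))
  cat("recomb_map:", length(x$lengths), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp,",
      sum(nb), "boundaries\n")
  invisible(x)
}

#' Sample the crossover realisation of one meiosis on one chromosome
#'
#' Draws which parental haplotype the gamete starts on (a fair coin,
#' i.e. independent assortment) and which recombination-map boundaries are
#' crossover points: each boundary is included independently with its
#' switch probability `r` (Markov switching, no interference).
#'
#' Uses the session RNG unless `seed` is given, so callers running many
#' meioses can seed once upstream.
#'
#' @param rec_map a [build_rec_map()] result.
#' @param chrom chromosome id present in `rec_map`.
#' @param seed optional integer seed for a reproducible single draw.
#' @return A list with `chrom`, `start_slot` (1 or 2) and `breakpoints`
#'   (strictly increasing bp positions, possibly empty).
#' @export
sample_crossover_mask <- function(rec_map, chrom, seed = NULL) {
  stopifnot(is_recomb_map(rec_map))
  chrom <- as.character(chrom)
  if (!chrom %in% names(rec_map$lengths)) {
    stop_("unknown chromosome: ", chrom)
  }
  if (!is.null(seed)) set.seed(seed)
  b <- rec_map$boundaries[[chrom]]
  start_slot <- sample.int(2L, 1L)
  keep <- runif(length(b$bp)) < b$r
  list(chrom = chrom, start_slot = start_slot, breakpoints = b$bp[keep])
}

#' Serialise a recombination map to CSV
#'
#' One row per chromosome length (`type = "length"`) followed by one row
#' per boundary (`type = "boundary"` with its switch probability `r`).
#'
#' @param rec_map a `recomb_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rec_map <- function(rec_map, path) {
  stopifnot(is_recomb_map(rec_map))
  rows <- do.call(rbind, lapply(names(rec_map$lengths), function(ch) {
    b <- rec_map$boundaries[[ch]]
    rbind(
      data.frame(chrom = ch, type = "length",
                 bp = rec_map$lengths[[ch]], r = NA_real_),
      if (length(b$bp)) data.frame(chrom = ch, type = "boundary",
                                   bp = b$bp, r = b$r)
    )
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recombination map written by [write_rec_map()]
#' @param path CSV path.
#' @return A `recomb_map`.
#' @export
read_rec_map <- function(path) {
  tab <- read.csv(path, colClasses = c(chrom = "character"))
  lens <- tab[tab$type == "length", ]
  lengths <- setNames(lens$bp, lens$chrom)
  boundaries <- lapply(lens$chrom, function(ch) {
    b <- tab[tab$type == "boundary" & tab$chrom == ch, ]
    if (any(b$r < 0 | b$r > 0.5)) stop_("r outside [0, 0.5] on chromosome ", ch)
    list(bp = as.numeric(b$bp), r = as.numeric(b$r))
  })
  names(boundaries) <- lens$chrom
  structure(list(lengths = lengths, boundaries = boundaries),
            class = "recomb_map")
}

#' @importFrom utils write.csv read.csv
NULL
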