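#' Genome specification
#'
#' A genome specification is an ordered table of chromosomes and their
#' physical lengths in base pairs.  It is the minimal description of a
#' genome needed to simulate recombination when no marker map is available:
#' users who know only the chromosome count and total genome size of their
#' organism can still run linked simulations under an assumed recombination
#' rate (e.g., 1 cM/Mb).
#'
#' @param chrom character or integer vector of unique chromosome ids.
#' @param length numeric vector of positive chromosome lengths in bp.
#' @return A tibble of class `genome_spec` with columns `chrom` and `length`.
#' @examples
#' genome_spec(c("1", "2"), c(2e6, 1e6))
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (length(chrom) != length(length)) stop_("chrom and length differ in length")
  if (anyDuplicated(chrom)) stop_("duplicate chromosome ids")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop_("chromosome lengths must be positive and finite")
  }
  out <- tibble(chrom = chrom, length = as.numeric(length))
  class(out) <- c("genome_spec", class(out))
  out
}

#' A pig-like genome: 18 autosomes totalling 2.35 Gb
#'
#' Chromosome lengths proportioned like the 18 pig (Sus scrofa 11.1)
#' autosomes and rescaled so that the total physical length is exactly
#' 2.35e9 bp.  This is the fixture genome used throughout the package's
#' simulation experiments on hybrids and backcrosses.
#'
#' @return A [genome_spec()] with 18 chromosomes summing to 2.35e9 bp.
#' @examples
#' sum(pig_genome()$length)
#' @export
pig_genome <- function() {
  # approximate Sus scrofa 11.1 autosome lengths, Mb
  mb <- c(274, 151, 133, 131, 104, 171, 121, 139, 139, 69,
          79, 61, 208, 142, 140, 80, 63, 56)
  total <- 2.35e9
  len <- round(mb / sum(mb) * total)
  len[1] <- len[1] + (total - sum(len))  # absorb rounding residual
  genome_spec(as.character(seq_along(len)), len)
}

is_genome_spec <- function(x) inherits(x, "genome_spec")
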