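#' Paint alleles from permuted founders onto segregated segments
#'
#' Completes a simulation: the input genotypes are permuted within
#' populations according to `plan`, the permuted individuals are assigned,
#' in order, to the founder nodes of each population (ascending founder
#' id, replicate-major), and every simulated sample's alleles are then
#' copied marker by marker from the assigned founder individual's
#' haplotype that the marker's segment descends from.  A marker at
#' position `p` belongs to the segment with `start <= p < end`.
#' Individuals not consumed as founders are returned as the retained
#' (pure) reference, so every input gene copy appears exactly once across
#' the simulated and retained outputs.
#'
#' @param samples,ledger output of [segregate()].
#' @param geno a [genotype_matrix()] with a marker map; all simulated
#'   markers come from here.
#' @param group_map named character vector mapping GSP founder population
#'   labels to population labels in `geno` (default: identity).
#' @param plan a [permutation_plan()].
#' @return A list with:
#'   * `simulated`: `geno_matrix` of the simulated samples (pops column
#'     holds the hybrid category when known, else the sample node id);
#'   * `retained`: `geno_matrix` of the permuted individuals not used as
#'     founders;
#'   * `assignments`: tibble mapping (rep, founder, pop, group) to the
#'     input row and id each founder was painted from;
#'   * `plan`: the filled permutation plan.
#' @export
segments2markers <- function(samples, ledger, geno, group_map = NULL,
                             plan = permutation_plan()) {
  stopifnot(is_geno_matrix(geno))
  if (is.null(geno$map)) stop_("geno needs a marker map to paint from")

  # founder table: one row per (rep, founder); both haplotype slots of a
  # founder must carry the same population so whole individuals can be
  # assigned
  led <- ledger[order(ledger$rep, ledger$founder, ledger$hap), ]
  f_tab <- led[led$hap == 1L, c("rep", "founder", "pop")]
  pop2 <- led$pop[led$hap == 2L]
  if (any(f_tab$pop != pop2)) {
    stop_("founders with differing haplotype population labels cannot be painted from whole individuals")
  }
  gsp_pops <- unique(f_tab$pop)
  if (is.null(group_map)) group_map <- setNames(gsp_pops, gsp_pops)
  if (any(!gsp_pops %in% names(group_map))) {
    stop_("group_map is missing GSP population(s): ",
          paste(setdiff(gsp_pops, names(group_map)), collapse = ", "))
  }
  if (any(!group_map[gsp_pops] %in% geno$pops)) {
    stop_("group_map points at group(s) absent from the genotype data")
  }

  perm <- permute_genotypes(geno, plan)
  pg <- perm$geno$geno

  # assign permuted individuals, in order, to founders: replicate-major,
  # ascending founder id within replicate (f_tab is already sorted so)
  assign_rows <- integer(nrow(f_tab))
  for (g in unique(group_map[gsp_pops])) {
    g_pops <- gsp_pops[group_map[gsp_pops] == g]
    idx <- which(f_tab$pop %in% g_pops)
    avail <- which(geno$pops == g)
    if (length(idx) > length(avail)) {
      stop_("population ", g, ": ", length(idx), " founders required but only ",
            length(avail), " individuals available")
    }
    assign_rows[idx] <- avail[seq_along(idx)]
  }
  assignments <- tibble(rep = f_tab$rep, founder = f_tab$founder,
                        pop = f_tab$pop,
                        group = unname(group_map[f_tab$pop]),
                        row = assign_rows,
                        ind_id = geno$ids[assign_rows])

  # per-slot lookups: the input row painted from, and the haplotype
  slot_row <- integer(max(ledger$slot))
  slot_hap <- integer(max(ledger$slot))
  key_f <- paste(f_tab$rep, f_tab$founder)
  slot_row[led$slot] <- assign_rows[match(paste(led$rep, led$founder), key_f)]
  slot_hap[led$slot] <- led$hap

  map <- geno$map
  chroms <- unique(map$chrom)
  loci_by_chrom <- split(seq_len(nrow(map)), map$chrom)[chroms]
  bp_by_chrom <- split(map$bp, map$chrom)[chroms]

  L2 <- ncol(geno$geno)
  sim <- matrix(NA_character_, nrow = length(samples), ncol = L2)
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    for (gi in 1:2) {
      gam <- s$gametes[[gi]]
      for (ch in chroms) {
        j <- loci_by_chrom[[ch]]
        if (length(j) == 0L) next
        bp <- bp_by_chrom[[ch]]
        mat <- gam[[ch]]
        if (is.null(mat)) stop_("sample gametes lack chromosome ", ch)
        seg <- findInterval(bp, mat[, 1L])
        if (any(seg == 0L) || any(bp >= mat[nrow(mat), 2L])) {
          stop_("internal error: marker outside all segments on chromosome ", ch)
        }
        slots <- mat[seg, 3L]
        src_col <- ifelse(slot_hap[slots] == 1L, 2L * j - 1L, 2L * j)
        dest_col <- if (gi == 1L) 2L * j - 1L else 2L * j
        sim[si, dest_col] <- pg[cbind(slot_row[slots], src_col)]
      }
    }
  }

  cats <- vapply(samples, function(s) {
    if (!is.na(s$category)) s$category
    else if (!is.na(s$node)) s$node
    else "sim"
  }, character(1))
  simulated <- genotype_matrix(
    sim, ids = vapply(samples, `[[`, character(1), "id"),
    pops = cats, map = map, phased = TRUE
  )
  keep <- setdiff(seq_len(nrow(pg)), assign_rows)
  retained <- genotype_matrix(pg[keep, , drop = FALSE],
                              ids = geno$ids[keep], pops = geno$pops[keep],
                              map = map, phased = geno$phased)
  list(simulated = simulated, retained = retained,
       assignments = assignments, plan = perm$plan)
}

#' Write genotypes to PLINK .ped/.map text files
#'
#' Standard 6 leading columns (family = population label, individual id,
#' father 0, mother 0, sex 0, phenotype -9) followed by the `2L` allele
#' fields; missing alleles become "0".  Round-trips through
#' [read_plink_ped()].
#'
#' @param geno a [genotype_matrix()] with a marker map.
#' @param prefix output path prefix; writes `prefix.ped` and `prefix.map`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(is_geno_matrix(geno))
  if (is.null(geno$map)) stop_("geno needs a marker map to write .map")
  if (nrow(geno$map) * 2L != ncol(geno$geno)) stop_("locus count mismatch")
  al <- geno$geno
  al[is.na(al)] <- "0"
  ped <- cbind(geno$pops, geno$ids, "0", "0", "0", "-9", al)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_plink_map(geno$map, paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read genotypes from PLINK .ped/.map text files
#'
#' @param prefix path prefix of a `.ped`/`.map` pair.
#' @param pops optional data frame with columns `id`, `group` assigning a
#'   population to every individual; defaults to the .ped family column.
#' @return A [genotype_matrix()].
#' @export
read_plink_ped <- function(prefix, pops = NULL) {
  map <- read_plink_map(paste0(prefix, ".map"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  if (ncol(ped) != 6L + 2L * nrow(map)) {
    stop_("ped has ", ncol(ped) - 6L, " allele columns but map describes ",
          2L * nrow(map))
  }
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  dimnames(al) <- NULL
  al[al == "0"] <- NA_character_
  ids <- ped[[2]]
  grp <- ped[[1]]
  if (!is.null(pops)) {
    pops <- as.data.frame(pops)
    missing <- setdiff(ids, pops$id)
    if (length(missing)) {
      stop_("pops table is missing individual(s): ",
            paste(missing, collapse = ", "))
    }
    unknown <- setdiff(pops$id, ids)
    if (length(unknown)) {
      stop_("pops table has unknown individual(s): ",
            paste(unknown, collapse = ", "))
    }
    grp <- pops$group[match(ids, pops$id)]
  }
  genotype_matrix(al, ids = ids, pops = grp, map = map)
}

#' Serialise simulated segments to CSV
#'
#' One row per segment with its sample, gamete, half-open 0-based
#' coordinates and founder-slot provenance.  [read_segments()] restores
#' the samples and ledger.
#'
#' @param samples,ledger output of [segregate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(samples, ledger, path) {
  rows <- lapply(samples, function(s) {
    per_g <- lapply(1:2, function(gi) {
      gam <- s$gametes[[gi]]
      do.call(rbind, lapply(names(gam), function(ch) {
        mat <- gam[[ch]]
        data.frame(sample_id = s$id, gamete_index = gi, chrom = ch,
                   start = mat[, 1L], end = mat[, 2L], slot = mat[, 3L])
      }))
    })
    do.call(rbind, per_g)
  })
  tab <- do.call(rbind, rows)
  m <- match(tab$slot, ledger$slot)
  tab$rep <- ledger$rep[m]
  tab$founder_node <- ledger$founder[m]
  tab$haplotype <- ledger$hap[m]
  tab$population <- ledger$pop[m]
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read segments written by [write_segments()]
#' @param path CSV path.
#' @return A list with `samples` and `ledger`, as from [segregate()].
#' @export
read_segments <- function(path) {
  tab <- read.csv(path, colClasses = c(chrom = "character",
                                       sample_id = "character",
                                       founder_node = "character",
                                       population = "character"))
  led <- unique(tab[, c("slot", "rep", "founder_node", "haplotype", "population")])
  led <- led[order(led$slot), ]
  ledger <- tibble(slot = led$slot, rep = led$rep, founder = led$founder_node,
                   hap = led$haplotype, pop = led$population)
  samples <- lapply(split(tab, tab$sample_id), function(st) {
    gametes <- lapply(1:2, function(gi) {
      gt <- st[st$gamete_index == gi, ]
      gams <- lapply(split(gt, gt$chrom), function(ct) {
        ct <- ct[order(ct$start), ]
        matrix(c(ct$start, ct$end, ct$slot), ncol = 3,
               dimnames = list(NULL, c("start", "end", "origin")))
      })
      gams[order(names(gams))]
    })
    # recover the sample node from the conventional id format when possible
    node <- sub("^gsp[0-9]+-rep[0-9]+-(.*)-[0-9]+$", "\\1", st$sample_id[1])
    if (identical(node, st$sample_id[1])) node <- NA_character_
    list(id = st$sample_id[1], gametes = gametes,
         rep = st$rep[1], node = node, index = NA_integer_,
         category = NA_character_)
  })
  names(samples) <- NULL
  list(samples = samples, ledger = ledger)
}
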