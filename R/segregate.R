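# A gamete is a named list over chromosomes; each element is a numeric
# matrix with columns (start, end, origin): half-open 0-based segments
# labelled by the integer id of the founder haplotype ("slot") they
# descend from.  Segments tile [0, chromosome length) exactly.

full_gamete <- function(lengths, slot) {
  lapply(lengths, function(L) matrix(c(0, L, slot), nrow = 1,
                                     dimnames = list(NULL, c("start", "end", "origin"))))
}

# collapse abutting segments with the same origin so segment lists stay
# minimal and canonical
merge_adjacent <- function(mat) {
  n <- nrow(mat)
  if (n <= 1L) return(mat)
  new_run <- c(TRUE, !(mat[-1L, 3L] == mat[-n, 3L] & mat[-1L, 1L] == mat[-n, 2L]))
  if (all(new_run)) return(mat)
  idx <- which(new_run)
  out <- mat[idx, , drop = FALSE]
  out[, 2L] <- mat[c(idx[-1L] - 1L, n), 2L]
  out
}

# rows of mat overlapping [lo, hi), clamped to it
clip_segments <- function(mat, lo, hi) {
  keep <- mat[, 2L] > lo & mat[, 1L] < hi
  out <- mat[keep, , drop = FALSE]
  if (nrow(out)) {
    out[1L, 1L] <- max(out[1L, 1L], lo)
    out[nrow(out), 2L] <- min(out[nrow(out), 2L], hi)
  }
  out
}

# one chromosome of one meiosis: child 1 copies the parent haplotype
# `start_slot` up to the first breakpoint, switching at each; child 2 is
# the exact complement
splice_chromosome <- function(mat1, mat2, breakpoints, start_slot, L) {
  if (length(breakpoints) == 0L) {
    if (start_slot == 1L) return(list(mat1, mat2)) else return(list(mat2, mat1))
  }
  bounds <- c(0, breakpoints, L)
  n_int <- length(bounds) - 1L
  use1 <- rep(c(start_slot == 1L, start_slot != 1L), length.out = n_int)
  a_pieces <- vector("list", n_int)
  b_pieces <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (use1[i]) {
      a_pieces[[i]] <- clip_segments(mat1, lo, hi)
      b_pieces[[i]] <- clip_segments(mat2, lo, hi)
    } else {
      a_pieces[[i]] <- clip_segments(mat2, lo, hi)
      b_pieces[[i]] <- clip_segments(mat1, lo, hi)
    }
  }
  list(merge_adjacent(do.call(rbind, a_pieces)),
       merge_adjacent(do.call(rbind, b_pieces)))
}

#' Simulate one meiosis
#'
#' Draws one crossover realisation per chromosome (independent assortment
#' of the starting haplotype, then independent switching at each
#' recombination-map boundary) and returns the two complementary gamete
#' products: at every base pair the second product carries the opposite
#' parental haplotype from the first.  Segregating the complement along
#' with each gamete is what lets a pedigree deliver all founder material
#' exactly once (it is also an antithetic-variates device).
#'
#' @param parent a list of two gametes (the parent's haploid genomes), as
#'   produced by [segregate()] internals or [full_gamete] founders.
#' @param rec_map a [build_rec_map()] recombination map covering the same
#'   chromosomes.
#' @param seed optional integer seed.
#' @return A list of two gametes.
#' @export
meiosis <- function(parent, rec_map, seed = NULL) {
  stopifnot(is_recomb_map(rec_map))
  if (!identical(names(parent[[1]]), names(rec_map$lengths)) ||
      !identical(names(parent[[2]]), names(rec_map$lengths))) {
    stop_("genome mismatch between parent gametes and recombination map")
  }
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(rec_map$lengths)
  g1 <- vector("list", length(chroms)); names(g1) <- chroms
  g2 <- g1
  for (ch in chroms) {
    b <- rec_map$boundaries[[ch]]
    start_slot <- sample.int(2L, 1L)
    keep <- runif(length(b$bp)) < b$r
    res <- splice_chromosome(parent[[1]][[ch]], parent[[2]][[ch]],
                             b$bp[keep], start_slot, rec_map$lengths[[ch]])
    g1[[ch]] <- res[[1]]
    g2[[ch]] <- res[[2]]
  }
  list(g1, g2)
}

#' Segregate founder genomes through a GSP
#'
#' Performs the gene-dropping simulation: for each replicate, every founder
#' is instantiated with two fresh haploid genome "slots" labelled by
#' population, founders undergo one meiosis each and their two gamete
#' products are dealt down their edges; at each non-founder (processed in
#' topological order, so parents first) the gametes arriving on the two
#' parent edges are paired in uniformly random order, a random subset of
#' the united pairs becomes the simulated samples, and every remaining
#' pair undergoes one meiosis whose pooled products are dealt, in random
#' order, down the outgoing edges according to their gamete counts.
#'
#' Each (replicate, node) operation is driven by its own pre-derived
#' sub-seed, so results are reproducible node by node.
#'
#' @param gsp a [load_gsp()]/[create_gsp()] pedigree; must pass
#'   [validate_gsp()].
#' @param rec_map a [build_rec_map()] recombination map.
#' @param n_reps number of independent replicates; each consumes a fresh
#'   set of founders.
#' @param seed optional integer seed.
#' @param gsp_index integer used in sample ids when simulating from
#'   several GSPs.
#' @return A list with:
#'   * `samples`: a list of simulated individuals, each a list with `id`,
#'     `gametes` (two gamete segment lists), `rep`, `node`, `index`, and
#'     `category` (from the GSP's `sample_categories` attribute, if any);
#'   * `ledger`: a tibble of every founder haplotype slot consumed, with
#'     columns `slot`, `rep`, `founder`, `hap`, `pop`.
#' @examples
#' rm <- build_rec_map(genome_spec("1", 1e6), boundary_spacing_bp = 5e5)
#' res <- segregate(create_gsp("A", "B", f1 = TRUE), rm, seed = 1)
#' length(res$samples)
#' @export
segregate <- function(gsp, rec_map, n_reps = 1, seed = NULL, gsp_index = 1) {
  stopifnot(is_gsp(gsp), is_recomb_map(rec_map))
  if (n_reps < 1) stop_("n_reps must be >= 1")
  val <- validate_gsp(gsp)
  if (!val$valid) {
    stop_("invalid GSP; validate_gsp() reports: ",
          paste(val$violations$message, collapse = "; "))
  }
  topo <- gsp_topo_order(gsp)
  founders <- gsp_founders(gsp)
  samp_tab <- gsp_sample_table(gsp)
  cats <- attr(gsp, "sample_categories")
  lengths <- rec_map$lengths
  nodes_tab <- gsp$nodes

  sub_seeds <- matrix(derive_seeds(n_reps * length(topo), seed),
                      nrow = n_reps)
  colnames(sub_seeds) <- topo

  out_edges <- lapply(setNames(topo, topo), function(nd) gsp_out_edges(gsp, nd))
  in_edges <- lapply(setNames(topo, topo), function(nd)
    if (nd %in% founders) NULL else gsp_in_edges(gsp, nd))

  samples <- list()
  ledger_rows <- vector("list", n_reps)
  slot_counter <- 0L

  for (r in seq_len(n_reps)) {
    # fresh founder slots for this replicate
    f_rows <- nodes_tab[match(founders, nodes_tab$id), ]
    slot1 <- slot_counter + seq_along(founders) * 2L - 1L
    slot2 <- slot1 + 1L
    slot_counter <- slot_counter + 2L * length(founders)
    ledger_rows[[r]] <- tibble(
      slot = c(rbind(slot1, slot2)),
      rep = r,
      founder = rep(founders, each = 2L),
      hap = rep(1:2, times = length(founders)),
      pop = c(rbind(f_rows$hpop1, f_rows$hpop2))
    )
    slot1 <- setNames(slot1, founders)
    slot2 <- setNames(slot2, founders)

    # inbox[[node]][[1 or 2]] collects gametes arriving on each parent edge
    inbox <- lapply(setNames(topo, topo), function(nd)
      if (nd %in% founders) NULL else list(list(), list()))

    deal <- function(products, oe) {
      if (nrow(oe) == 0L) return(invisible())
      shuffled <- products[sample.int(length(products))]
      pos <- 1L
      for (j in seq_len(nrow(oe))) {
        child <- oe$child[j]
        k <- oe$gametes[j]
        slot_idx <- which(in_edges[[child]]$parent == oe$parent[j])
        box <- inbox[[child]][[slot_idx]]
        inbox[[child]][[slot_idx]] <<- c(box, shuffled[pos:(pos + k - 1L)])
        pos <- pos + k
      }
    }

    for (nd in topo) {
      set.seed(sub_seeds[r, nd])
      if (nd %in% founders) {
        parent <- list(full_gamete(lengths, slot1[[nd]]),
                       full_gamete(lengths, slot2[[nd]]))
        deal(meiosis(parent, rec_map), out_edges[[nd]])
      } else {
        a <- inbox[[nd]][[1]]
        b <- inbox[[nd]][[2]]
        G <- length(a)
        pairs_b <- b[sample.int(G)]
        s_row <- samp_tab[samp_tab$parent == nd, ]
        keep_idx <- integer(0)
        if (nrow(s_row) == 1L) {
          s_x <- s_row$n_samples
          keep_idx <- sample.int(G, s_x)
          for (k in seq_along(keep_idx)) {
            i <- keep_idx[k]
            sid <- sprintf("gsp%d-rep%d-%s-%d", gsp_index, r, nd, k)
            samples[[length(samples) + 1L]] <- list(
              id = sid,
              gametes = list(a[[i]], pairs_b[[i]]),
              rep = r, node = nd, index = k,
              category = if (!is.null(cats)) unname(cats[s_row$id]) else NA_character_
            )
          }
        }
        rest <- setdiff(seq_len(G), keep_idx)
        if (length(rest)) {
          prods <- vector("list", 2L * length(rest))
          for (k in seq_along(rest)) {
            i <- rest[k]
            m <- meiosis(list(a[[i]], pairs_b[[i]]), rec_map)
            prods[[2L * k - 1L]] <- m[[1]]
            prods[[2L * k]] <- m[[2]]
          }
          deal(prods, out_edges[[nd]])
        }
      }
    }
  }
  list(samples = samples, ledger = do.call(rbind, ledger_rows))
}

slot_pop_lookup <- function(ledger) {
  v <- character(max(ledger$slot))
  v[ledger$slot] <- ledger$pop
  v
}

#' Segment-based admixture fraction of a simulated individual
#'
#' The cumulative length of all genome segments (over both gametes) whose
#' founder haplotype carries population label `pop`, divided by twice the
#' total genome length.
#'
#' @param sample one element of `segregate()$samples`.
#' @param pop population label.
#' @param ledger the founder-slot ledger returned by [segregate()].
#' @return A fraction in `[0, 1]`.  Unknown `pop` gives 0 with a warning.
#' @export
admixture_fraction <- function(sample, pop, ledger) {
  if (!pop %in% ledger$pop) {
    warn_("population label not in ledger: ", pop)
    return(0)
  }
  v <- slot_pop_lookup(ledger)
  tot <- 0; hit <- 0
  for (g in sample$gametes) {
    for (mat in g) {
      len <- mat[, 2L] - mat[, 1L]
      tot <- tot + sum(len)
      hit <- hit + sum(len[v[mat[, 3L]] == pop])
    }
  }
  hit / tot
}

#' @rdname admixture_fraction
#' @param samples a list of simulated individuals.
#' @return `admixture_fractions()`: a numeric vector, one value per sample.
#' @export
admixture_fractions <- function(samples, pop, ledger) {
  vapply(samples, admixture_fraction, numeric(1), pop = pop, ledger = ledger)
}

#' Genome fractions by ancestry-genotype copy number
#'
#' Intersects the two gametes of a simulated individual and returns the
#' fractions of the genome on which the individual carries 2, 1 or 0
#' copies of ancestry from population `pop`.  The three fractions sum to
#' one exactly.
#'
#' @inheritParams admixture_fraction
#' @return Named numeric vector `c(f2, f1, f0)`.
#' @export
ancestry_genotype_fractions <- function(sample, pop, ledger) {
  if (!pop %in% ledger$pop) {
    warn_("population label not in ledger: ", pop)
    return(c(f2 = 0, f1 = 0, f0 = 1))
  }
  v <- slot_pop_lookup(ledger)
  g1 <- sample$gametes[[1]]
  g2 <- sample$gametes[[2]]
  acc <- c(0, 0, 0)  # lengths with 2, 1, 0 copies
  tot <- 0
  for (ch in names(g1)) {
    m1 <- g1[[ch]]; m2 <- g2[[ch]]
    L <- m1[nrow(m1), 2L]
    tot <- tot + L
    bounds <- sort(unique(c(m1[, 1L], m2[, 1L], L)))
    starts <- bounds[-length(bounds)]
    len <- diff(bounds)
    o1 <- v[m1[findInterval(starts, m1[, 1L]), 3L]] == pop
    o2 <- v[m2[findInterval(starts, m2[, 1L]), 3L]] == pop
    copies <- o1 + o2
    acc[1] <- acc[1] + sum(len[copies == 2L])
    acc[2] <- acc[2] + sum(len[copies == 1L])
    acc[3] <- acc[3] + sum(len[copies == 0L])
  }
  setNames(acc / tot, c("f2", "f1", "f0"))
}

#' Verify that simulated samples conserve all founder material
#'
#' The defining guarantee of the simulation: across the samples of each
#' replicate, the segments originating from any one founder haplotype must
#' tile that haplotype's genome exactly -- no base pair duplicated, none
#' lost.  This function checks the guarantee exactly, slot by slot.
#'
#' @param samples,ledger output of [segregate()].
#' @param lengths named chromosome lengths (e.g. `rec_map$lengths`).
#' @return `TRUE` if every slot's genome is tiled exactly; otherwise
#'   `FALSE` with attribute `"bad_slots"`.
#' @export
check_founder_conservation <- function(samples, ledger, lengths) {
  # gather all segments per slot
  per_slot <- vector("list", max(ledger$slot))
  for (s in samples) {
    for (g in s$gametes) {
      for (ch in names(g)) {
        mat <- g[[ch]]
        for (i in seq_len(nrow(mat))) {
          sl <- mat[i, 3L]
          per_slot[[sl]] <- c(per_slot[[sl]], list(c(mat[i, 1L], mat[i, 2L],
                                                     match(ch, names(lengths)))))
        }
      }
    }
  }
  bad <- integer(0)
  for (sl in ledger$slot) {
    segs <- per_slot[[sl]]
    if (is.null(segs)) { bad <- c(bad, sl); next }
    m <- do.call(rbind, segs)
    ok <- TRUE
    for (ci in seq_along(lengths)) {
      mm <- m[m[, 3L] == ci, , drop = FALSE]
      if (nrow(mm) == 0L) { ok <- FALSE; break }
      mm <- mm[order(mm[, 1L]), , drop = FALSE]
      tiles <- mm[1L, 1L] == 0 && mm[nrow(mm), 2L] == lengths[[ci]] &&
        (nrow(mm) == 1L || all(mm[-1L, 1L] == mm[-nrow(mm), 2L]))
      if (!tiles) { ok <- FALSE; break }
    }
    if (!ok) bad <- c(bad, sl)
  }
  if (length(bad)) return(structure(FALSE, bad_slots = bad))
  TRUE
}
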