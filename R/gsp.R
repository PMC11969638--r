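#' Genomic simulation pedigrees (GSPs)
#'
#' A GSP is a loop-free directed pedigree with three node kinds: founders
#' (whose two haploid genomes carry population labels), non-founders, and
#' sample nodes (where the simulated individuals are collected).  Edges run
#' from parent to non-founder child and carry the number of gametes
#' segregated down them.  The gamete accounting is what guarantees that
#' every founder gene copy is delivered exactly once to a simulated sample:
#' nothing is duplicated (no sampling with replacement) and nothing is lost.
#'
#' `load_gsp()` assembles and structurally checks a GSP from a node table
#' and an edge table; gamete accounting is checked separately by
#' [validate_gsp()].
#'
#' @param nodes a data frame with columns `id`; `kind` (one of `"founder"`,
#'   `"nonfounder"`, `"sample"`); `hpop1`, `hpop2` (founders only: the
#'   population label of each haploid genome); `parent` and `n_samples`
#'   (sample nodes only).  Missing entries may be `NA`.
#' @param edges a data frame with columns `parent`, `child`, `gametes`
#'   (positive integer counts); children must be non-founders.
#' @return An object of class `gsp`: a list with tibbles `nodes` and
#'   `edges`.
#' @export
load_gsp <- function(nodes, edges) {
  nodes <- as_tibble(as.data.frame(nodes))
  edges <- as_tibble(as.data.frame(edges))
  need_n <- c("id", "kind")
  if (!all(need_n %in% names(nodes))) stop_("nodes table needs columns id, kind")
  if (!all(c("parent", "child", "gametes") %in% names(edges))) {
    stop_("edges table needs columns parent, child, gametes")
  }
  for (col in c("hpop1", "hpop2", "parent", "n_samples")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA
  }
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  nodes$hpop1 <- as.character(nodes$hpop1)
  nodes$hpop2 <- as.character(nodes$hpop2)
  nodes$parent <- as.character(nodes$parent)
  nodes$n_samples <- as.numeric(nodes$n_samples)
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$gametes <- as.numeric(edges$gametes)

  if (anyDuplicated(nodes$id)) stop_("duplicate node ids")
  bad_kind <- setdiff(nodes$kind, c("founder", "nonfounder", "sample"))
  if (length(bad_kind)) stop_("unknown node kind: ", paste(bad_kind, collapse = ", "))

  founders <- nodes$id[nodes$kind == "founder"]
  nonf <- nodes$id[nodes$kind == "nonfounder"]
  samp <- nodes[nodes$kind == "sample", ]

  dangling <- setdiff(c(edges$parent, edges$child), nodes$id)
  if (length(dangling)) stop_("edge refers to unknown node: ",
                              paste(dangling, collapse = ", "))
  if (any(!is.finite(edges$gametes) | edges$gametes < 1 |
          edges$gametes != round(edges$gametes))) {
    stop_("edge gamete counts must be positive integers")
  }
  if (any(edges$child %in% founders)) {
    stop_("founder listed as a child of another node: ",
          paste(intersect(edges$child, founders), collapse = ", "))
  }
  if (any(!edges$child %in% nonf)) {
    stop_("edge children must be nonfounder nodes: ",
          paste(setdiff(edges$child, nonf), collapse = ", "))
  }
  if (any(edges$parent %in% samp$id) || any(edges$child %in% samp$id)) {
    stop_("sample nodes cannot appear in the edge table")
  }
  if (any(is.na(nodes$hpop1[nodes$kind == "founder"])) ||
      any(is.na(nodes$hpop2[nodes$kind == "founder"]))) {
    stop_("founders need hpop1 and hpop2 population labels")
  }
  in_counts <- table(factor(edges$child, levels = nonf))
  if (any(in_counts != 2L)) {
    stop_("each nonfounder must have exactly two incoming parent edges; ",
          "offending: ", paste(names(in_counts)[in_counts != 2L], collapse = ", "))
  }
  if (nrow(samp)) {
    if (anyNA(samp$parent) || any(!samp$parent %in% nonf)) {
      stop_("each sample node needs a nonfounder parent")
    }
    if (anyDuplicated(samp$parent)) {
      stop_("a nonfounder may have at most one sample node")
    }
    if (any(!is.finite(samp$n_samples) | samp$n_samples < 1 |
            samp$n_samples != round(samp$n_samples))) {
      stop_("sample nodes need integer n_samples >= 1")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "gsp")
}

is_gsp <- function(x) inherits(x, "gsp")

#' @export
print.gsp <- function(x, ...) {
  k <- table(x$nodes$kind)
  cat("gsp:", k[["founder"]] %||% 0, "founders,",
      sum(x$nodes$kind == "nonfounder"), "nonfounders,",
      sum(x$nodes$n_samples[x$nodes$kind == "sample"], na.rm = TRUE),
      "samples per replicate\n")
  invisible(x)
}

gsp_founders <- function(gsp) sort(gsp$nodes$id[gsp$nodes$kind == "founder"])
gsp_nonfounders <- function(gsp) gsp$nodes$id[gsp$nodes$kind == "nonfounder"]
gsp_sample_table <- function(gsp) gsp$nodes[gsp$nodes$kind == "sample", ]

# incoming edges of a nonfounder, in a fixed deterministic order
gsp_in_edges <- function(gsp, id) {
  e <- gsp$edges[gsp$edges$child == id, ]
  e[order(e$parent), ]
}

gsp_out_edges <- function(gsp, id) {
  e <- gsp$edges[gsp$edges$parent == id, ]
  e[order(e$child), ]
}

# Kahn topological order over founder + nonfounder nodes; NULL if cyclic
gsp_topo_order <- function(gsp) {
  ids <- c(gsp_founders(gsp), gsp_nonfounders(gsp))
  indeg <- setNames(integer(length(ids)), ids)
  for (ch in gsp$edges$child) indeg[ch] <- indeg[ch] + 1L
  order_out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    nd <- ready[1]; ready <- ready[-1]
    order_out <- c(order_out, nd)
    kids <- gsp$edges$child[gsp$edges$parent == nd]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order_out) != length(ids)) return(NULL)
  order_out
}

# ancestor set of each node, including the node itself
gsp_ancestor_sets <- function(gsp, topo) {
  anc <- vector("list", length(topo))
  names(anc) <- topo
  for (nd in topo) {
    pars <- unique(gsp$edges$parent[gsp$edges$child == nd])
    anc[[nd]] <- unique(c(nd, unlist(anc[pars], use.names = FALSE)))
  }
  anc
}

#' Check the gamete-accounting validity of a GSP
#'
#' A GSP supports a conservative simulation (every founder gene copy used
#' exactly once) only when its gamete counts balance.  Writing `S_x` for
#' the samples drawn at node `x`, the checked conditions are:
#'
#' * `c1` - total samples equal the number of founders;
#' * `c2` - each founder segregates exactly 2 gametes, over at most 2 edges;
#' * `c3` - the two parent edges into a nonfounder carry equal gamete counts;
#' * `c4` - a nonfounder with no sample node passes on as many gametes as
#'   it receives;
#' * `c5` - a nonfounder with only a sample node receives `2 * S_x` gametes;
#' * `c6` - a nonfounder with both receives `2 * S_x` plus what it passes on;
#' * `loop` - the graph is acyclic and the two parents of every nonfounder
#'   have disjoint ancestries (no inbreeding loops, which would duplicate
#'   founder material among descendants).
#'
#' @param gsp a structurally well-formed [load_gsp()] object.
#' @return A list with `valid` (logical) and `violations`, a tibble with
#'   columns `condition` (`"c1"`..`"c6"` or `"loop"`), `message`, `nodes`.
#' @export
validate_gsp <- function(gsp) {
  stopifnot(is_gsp(gsp))
  v <- list()
  add <- function(condition, message, nodes = NA_character_) {
    v[[length(v) + 1L]] <<- tibble(condition = condition, message = message,
                                   nodes = paste(nodes, collapse = ","))
  }
  founders <- gsp_founders(gsp)
  nonf <- gsp_nonfounders(gsp)
  samp <- gsp_sample_table(gsp)
  s_of <- setNames(samp$n_samples, samp$parent)

  # c1
  total_s <- sum(samp$n_samples)
  if (total_s != length(founders)) {
    add("c1", sprintf("total samples (%d) must equal number of founders (%d)",
                      total_s, length(founders)))
  }
  # c2
  for (f in founders) {
    out <- gsp_out_edges(gsp, f)
    if (nrow(out) > 2L) add("c2", sprintf("founder %s has %d downward edges (max 2)",
                                          f, nrow(out)), f)
    if (sum(out$gametes) != 2) {
      add("c2", sprintf("founder %s segregates %g gametes (must be 2)",
                        f, sum(out$gametes)), f)
    }
  }
  # c3..c6
  for (x in nonf) {
    ine <- gsp_in_edges(gsp, x)
    if (ine$gametes[1] != ine$gametes[2]) {
      add("c3", sprintf("node %s receives unequal gametes from its parents (%g vs %g)",
                        x, ine$gametes[1], ine$gametes[2]), x)
    }
    g_in <- sum(ine$gametes)
    g_out <- sum(gsp_out_edges(gsp, x)$gametes)
    s_x <- unname(s_of[x])
    has_s <- !is.na(s_x)
    has_e <- g_out > 0
    if (!has_s && !has_e) {
      add("c4", sprintf("node %s is a dead end: no sample node and no downward edges", x), x)
    } else if (!has_s && has_e) {
      if (g_out != g_in) add("c4", sprintf(
        "node %s passes on %g gametes but receives %g", x, g_out, g_in), x)
    } else if (has_s && !has_e) {
      if (g_in != 2 * s_x) add("c5", sprintf(
        "node %s receives %g gametes but needs 2*S = %g for its %g samples",
        x, g_in, 2 * s_x, s_x), x)
    } else {
      if (g_in != 2 * s_x + g_out) add("c6", sprintf(
        "node %s receives %g gametes but needs 2*S + out = %g",
        x, g_in, 2 * s_x + g_out), x)
    }
  }
  # loop-freeness
  topo <- gsp_topo_order(gsp)
  if (is.null(topo)) {
    add("loop", "pedigree graph contains a cycle")
  } else {
    anc <- gsp_ancestor_sets(gsp, topo)
    for (x in nonf) {
      pars <- gsp_in_edges(gsp, x)$parent
      shared <- intersect(anc[[pars[1]]], anc[[pars[2]]])
      if (length(shared)) {
        add("loop", sprintf("parents of node %s share ancestor(s) %s (inbreeding loop)",
                            x, paste(shared, collapse = ",")), x)
      }
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    tibble(condition = character(0), message = character(0), nodes = character(0))
  list(valid = nrow(violations) == 0L, violations = violations)
}

# ---- preset construction -------------------------------------------------

make_gsp <- function(nodes, edges, categories, pops) {
  g <- load_gsp(nodes, edges)
  attr(g, "sample_categories") <- categories
  attr(g, "pops") <- pops
  g
}

node_row <- function(id, kind, hpop1 = NA, hpop2 = NA, parent = NA, n_samples = NA) {
  data.frame(id = id, kind = kind, hpop1 = hpop1, hpop2 = hpop2,
             parent = parent, n_samples = n_samples, stringsAsFactors = FALSE)
}

preset_f1 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_b, pop_b),
    node_row("3", "nonfounder"),
    node_row("s3", "sample", parent = "3", n_samples = 2)
  )
  edges <- data.frame(parent = c("1", "2"), child = c("3", "3"), gametes = c(2, 2))
  make_gsp(nodes, edges, c(s3 = "F1"), c(pop_a, pop_b))
}

# Topology of the published F2 worked example: founders 1,2 from pop A and
# 3,4 from pop B; F1 nodes 5 and 6; node 7 yields four F2 samples.
preset_f2 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_a, pop_a),
    node_row("3", "founder", pop_b, pop_b),
    node_row("4", "founder", pop_b, pop_b),
    node_row("5", "nonfounder"),
    node_row("6", "nonfounder"),
    node_row("7", "nonfounder"),
    node_row("s7", "sample", parent = "7", n_samples = 4)
  )
  edges <- data.frame(
    parent  = c("1", "3", "2", "4", "5", "6"),
    child   = c("5", "5", "6", "6", "7", "7"),
    gametes = c(2, 2, 2, 2, 4, 4)
  )
  make_gsp(nodes, edges, c(s7 = "F2"), c(pop_a, pop_b))
}

# Two BC1 nodes sharing one F1 node: 4 founders, 4 BC1 samples,
# all toward pop_a (the recurrent parent).
preset_bc1 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_b, pop_b),
    node_row("3", "founder", pop_a, pop_a),
    node_row("4", "founder", pop_a, pop_a),
    node_row("5", "nonfounder"),  # F1
    node_row("6", "nonfounder"),  # BC1
    node_row("7", "nonfounder"),  # BC1
    node_row("s6", "sample", parent = "6", n_samples = 2),
    node_row("s7", "sample", parent = "7", n_samples = 2)
  )
  edges <- data.frame(
    parent  = c("1", "2", "5", "3", "5", "4"),
    child   = c("5", "5", "6", "6", "7", "7"),
    gametes = c(2, 2, 2, 2, 2, 2)
  )
  make_gsp(nodes, edges, c(s6 = "BC1", s7 = "BC1"), c(pop_a, pop_b))
}

# One F1 node feeding two BC1 nodes, each feeding two BC2 nodes:
# 8 founders, 8 BC2 samples toward pop_a.
preset_bc2 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_b, pop_b),
    node_row("3", "founder", pop_a, pop_a),
    node_row("4", "founder", pop_a, pop_a),
    node_row("5", "founder", pop_a, pop_a),
    node_row("6", "founder", pop_a, pop_a),
    node_row("7", "founder", pop_a, pop_a),
    node_row("8", "founder", pop_a, pop_a),
    node_row("9", "nonfounder"),   # F1
    node_row("10", "nonfounder"),  # BC1
    node_row("11", "nonfounder"),  # BC1
    node_row("12", "nonfounder"),  # BC2
    node_row("13", "nonfounder"),  # BC2
    node_row("14", "nonfounder"),  # BC2
    node_row("15", "nonfounder"),  # BC2
    node_row("s12", "sample", parent = "12", n_samples = 2),
    node_row("s13", "sample", parent = "13", n_samples = 2),
    node_row("s14", "sample", parent = "14", n_samples = 2),
    node_row("s15", "sample", parent = "15", n_samples = 2)
  )
  edges <- data.frame(
    parent  = c("1", "2", "9", "3", "9", "4",
                "10", "5", "10", "6", "11", "7", "11", "8"),
    child   = c("9", "9", "10", "10", "11", "11",
                "12", "12", "13", "13", "14", "14", "15", "15"),
    gametes = rep(2, 14)
  )
  make_gsp(nodes, edges,
           c(s12 = "BC2", s13 = "BC2", s14 = "BC2", s15 = "BC2"),
           c(pop_a, pop_b))
}

# All four categories in one pedigree, with the published sample counts:
# one F1 (s7), two F2 (s11), one BC1 (s9), two BC2 (s10); 6 founders.
preset_all_four <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_b, pop_b),
    node_row("3", "founder", pop_a, pop_a),
    node_row("4", "founder", pop_a, pop_a),
    node_row("5", "founder", pop_a, pop_a),
    node_row("6", "founder", pop_b, pop_b),
    node_row("7", "nonfounder"),   # F1 (sampled)
    node_row("8", "nonfounder"),   # F1 (unsampled)
    node_row("9", "nonfounder"),   # BC1
    node_row("10", "nonfounder"),  # BC2
    node_row("11", "nonfounder"),  # F2
    node_row("s7", "sample", parent = "7", n_samples = 1),
    node_row("s9", "sample", parent = "9", n_samples = 1),
    node_row("s10", "sample", parent = "10", n_samples = 2),
    node_row("s11", "sample", parent = "11", n_samples = 2)
  )
  edges <- data.frame(
    parent  = c("1", "2", "5", "6", "7", "8", "8", "3", "9", "4"),
    child   = c("7", "7", "8", "8", "11", "11", "9", "9", "10", "10"),
    gametes = rep(2, 10)
  )
  make_gsp(nodes, edges,
           c(s7 = "F1", s9 = "BC1", s10 = "BC2", s11 = "F2"),
           c(pop_a, pop_b))
}

prefix_gsp <- function(g, prefix) {
  ren <- function(x) ifelse(is.na(x), x, paste0(prefix, x))
  nodes <- g$nodes
  nodes$id <- ren(nodes$id)
  nodes$parent <- ren(nodes$parent)
  edges <- g$edges
  edges$parent <- ren(edges$parent)
  edges$child <- ren(edges$child)
  cats <- attr(g, "sample_categories")
  names(cats) <- paste0(prefix, names(cats))
  make_gsp(nodes, edges, cats, attr(g, "pops"))
}

#' Preset genomic simulation pedigrees
#'
#' Builds valid GSPs for the common hybrid categories between two
#' populations.  Backcrosses are toward `pop_a` (the recurrent parent);
#' swap the arguments for the other direction.  Single-flag presets are
#' minimal pedigrees producing only the requested category.  With all four
#' flags set, one connected pedigree with 6 founders is returned yielding
#' 1 F1, 2 F2, 1 BC1 and 2 BC2 samples per replicate.  Any other
#' combination of flags returns the disjoint union of the single-category
#' presets (node ids gain a category prefix).
#'
#' Every returned GSP passes [validate_gsp()] and carries a
#' `sample_categories` attribute naming the hybrid category collected at
#' each sample node.
#'
#' @param pop_a,pop_b population labels for the founder genomes.
#' @param f1,f2,bc1,bc2 logical; which hybrid categories to produce.  At
#'   least one must be `TRUE`.
#' @return A `gsp`.
#' @examples
#' g <- create_gsp("A", "B", f2 = TRUE)
#' validate_gsp(g)$valid
#' @export
create_gsp <- function(pop_a, pop_b, f1 = FALSE, f2 = FALSE,
                       bc1 = FALSE, bc2 = FALSE) {
  flags <- c(f1 = f1, f2 = f2, bc1 = bc1, bc2 = bc2)
  if (!any(flags)) stop_("at least one of f1, f2, bc1, bc2 must be TRUE")
  if (all(flags)) return(preset_all_four(pop_a, pop_b))
  parts <- list()
  if (f1) parts$F1 <- preset_f1(pop_a, pop_b)
  if (f2) parts$F2 <- preset_f2(pop_a, pop_b)
  if (bc1) parts$BC1 <- preset_bc1(pop_a, pop_b)
  if (bc2) parts$BC2 <- preset_bc2(pop_a, pop_b)
  if (length(parts) == 1L) return(parts[[1]])
  parts <- Map(prefix_gsp, parts, paste0(names(parts), "_"))
  nodes <- do.call(rbind, lapply(parts, function(g) g$nodes))
  edges <- do.call(rbind, lapply(parts, function(g) g$edges))
  cats <- do.call(c, lapply(parts, function(g) attr(g, "sample_categories")))
  names(cats) <- sub("^(F1|F2|BC1|BC2)\\.", "", names(cats))
  make_gsp(nodes, edges, cats, c(pop_a, pop_b))
}

#' Pedigree for the BC1xBC2 hybrid category
#'
#' Builds the GSP realising the advanced-backcross hybrid category whose
#' expected ancestry-genotype triplet is (0.5625, 0.375, 0.0625) copies
#' of `pop_a` ancestry: the terminal sample node collects offspring of
#' two independent first-generation backcrosses toward `pop_a` (each
#' parental gamete carries `pop_a` ancestry with probability 3/4, so the
#' genotype fractions are (3/4)^2, 2(3/4)(1/4), (1/4)^2).  This is the
#' triplet that defines the category in genotype-frequency-class
#' inference.  By-product samples (two F1, two BC1) balance the gamete
#' accounting; 6 founders yield 6 samples of which 2 are the terminal
#' category.
#'
#' @inheritParams create_gsp
#' @return A `gsp` whose `sample_categories` attribute marks the terminal
#'   node as `"BC1xBC2"`.
#' @export
gsp_bc1xbc2 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_b, pop_b),
    node_row("2", "founder", pop_a, pop_a),
    node_row("3", "founder", pop_a, pop_a),
    node_row("4", "founder", pop_b, pop_b),
    node_row("5", "founder", pop_a, pop_a),
    node_row("6", "founder", pop_a, pop_a),
    node_row("7", "nonfounder"),   # F1 (line 1)
    node_row("8", "nonfounder"),   # BC1 (line 1) -> mix
    node_row("9", "nonfounder"),   # F1 (line 2)
    node_row("10", "nonfounder"),  # BC1 (line 2) -> mix
    node_row("11", "nonfounder"),  # terminal BC1 x BC1-type node
    node_row("s7", "sample", parent = "7", n_samples = 1),
    node_row("s8", "sample", parent = "8", n_samples = 1),
    node_row("s9", "sample", parent = "9", n_samples = 1),
    node_row("s10", "sample", parent = "10", n_samples = 1),
    node_row("s11", "sample", parent = "11", n_samples = 2)
  )
  edges <- data.frame(
    parent  = c("1", "2", "7", "3", "4", "5", "9", "6", "8", "10"),
    child   = c("7", "7", "8", "8", "9", "9", "10", "10", "11", "11"),
    gametes = rep(2, 10)
  )
  make_gsp(nodes, edges,
           c(s7 = "F1", s8 = "BC1", s9 = "F1", s10 = "BC1",
             s11 = "BC1xBC2"),
           c(pop_a, pop_b))
}

# Offspring of an F1 mated with a BC1-toward-pop_a: expected pop_a
# admixture fraction 5/8.  5 founders, 5 samples (2 of the target).
gsp_f1xbc1 <- function(pop_a, pop_b) {
  nodes <- rbind(
    node_row("1", "founder", pop_a, pop_a),
    node_row("2", "founder", pop_b, pop_b),
    node_row("3", "founder", pop_a, pop_a),
    node_row("4", "founder", pop_b, pop_b),
    node_row("5", "founder", pop_a, pop_a),
    node_row("6", "nonfounder"),  # F1 -> mix
    node_row("7", "nonfounder"),  # F1
    node_row("8", "nonfounder"),  # BC1 -> mix
    node_row("9", "nonfounder"),  # F1 x BC1
    node_row("s6", "sample", parent = "6", n_samples = 1),
    node_row("s7", "sample", parent = "7", n_samples = 1),
    node_row("s8", "sample", parent = "8", n_samples = 1),
    node_row("s9", "sample", parent = "9", n_samples = 2)
  )
  edges <- data.frame(
    parent  = c("1", "2", "3", "4", "7", "5", "6", "8"),
    child   = c("6", "6", "7", "7", "8", "8", "9", "9"),
    gametes = rep(2, 8)
  )
  make_gsp(nodes, edges,
           c(s6 = "F1", s7 = "F1", s8 = "BC1", s9 = "F1xBC1"),
           c(pop_a, pop_b))
}

# Pedigree producing unadmixed individuals of one population (founders
# crossed within the population); used for the q = 0 and q = 1 grid points.
gsp_pure <- function(pop) {
  nodes <- rbind(
    node_row("1", "founder", pop, pop),
    node_row("2", "founder", pop, pop),
    node_row("3", "nonfounder"),
    node_row("s3", "sample", parent = "3", n_samples = 2)
  )
  edges <- data.frame(parent = c("1", "2"), child = c("3", "3"), gametes = c(2, 2))
  make_gsp(nodes, edges, c(s3 = "pure"), c(pop, pop))
}

#' Backcross ladder pedigree
#'
#' A chain pedigree producing one sample each of F1, BC1, ..., BC(g-1) and
#' two samples of BCg, all toward `pop_a`.  Useful for studying how the
#' admixture-fraction distribution changes across successive backcross
#' generations from a single, conservative simulation.
#'
#' @param g backcross generation of the terminal node (integer >= 1).
#' @inheritParams create_gsp
#' @return A `gsp`; sample categories are `"F1"`, `"BC1"`, ..., `"BCg"`.
#' @export
create_bc_ladder <- function(g, pop_a, pop_b) {
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop_("g must be an integer >= 1")
  nodes <- rbind(node_row("1", "founder", pop_a, pop_a),
                 node_row("2", "founder", pop_b, pop_b))
  edges <- data.frame(parent = c("1", "2"), child = c("3", "3"),
                      gametes = c(2, 2))
  cats <- character(0)
  prev <- "3"
  nodes <- rbind(nodes, node_row("3", "nonfounder"))
  cat_of <- function(k) if (k == 0) "F1" else paste0("BC", k)
  for (k in seq_len(g)) {
    fid <- as.character(3 + 2 * k - 1)  # new recurrent-parent founder
    nid <- as.character(3 + 2 * k)      # BC_k node
    nodes <- rbind(nodes,
                   node_row(fid, "founder", pop_a, pop_a),
                   node_row(nid, "nonfounder"),
                   node_row(paste0("s", prev), "sample", parent = prev, n_samples = 1))
    cats[paste0("s", prev)] <- cat_of(k - 1)
    edges <- rbind(edges,
                   data.frame(parent = c(prev, fid), child = c(nid, nid),
                              gametes = c(2, 2)))
    prev <- nid
  }
  nodes <- rbind(nodes, node_row(paste0("s", prev), "sample",
                                 parent = prev, n_samples = 2))
  cats[paste0("s", prev)] <- cat_of(g)
  make_gsp(nodes, edges, cats, c(pop_a, pop_b))
}

#' GSP realising a nominal admixture fraction
#'
#' Returns, for each value on the admixture grid
#' `{0, 1/8, 1/4, 3/8, 1/2, 5/8, 3/4, 7/8, 1}`, a pedigree whose target
#' sample node has exactly that expected fraction of `pop_a` ancestry:
#' pure crosses for 0 and 1, F1 for 1/2, BC1 and BC2 in either direction
#' for 1/4, 3/4, 1/8, 7/8, and an F1-x-BC1 pedigree for 3/8 and 5/8.  All
#' grid values are realised exactly by a pedigree.
#'
#' @param q nominal `pop_a` admixture fraction; must be on the grid.
#' @inheritParams create_gsp
#' @return A list: `gsp`, `target_nodes` (ids of the sample nodes of the
#'   target category), `category`, `expected_q` and `exact_q` (always
#'   `TRUE` for grid values).
#' @export
gsp_for_q <- function(q, pop_a, pop_b) {
  grid <- c(0, 1/8, 1/4, 3/8, 1/2, 5/8, 3/4, 7/8, 1)
  i <- which(abs(grid - q) < 1e-9)
  if (!length(i)) stop_("q must be one of 0, 1/8, ..., 1")
  pick <- function(gsp, category) {
    cats <- attr(gsp, "sample_categories")
    list(gsp = gsp, target_nodes = names(cats)[cats == category],
         category = category, expected_q = grid[i], exact_q = TRUE)
  }
  switch(as.character(i),
    "1" = pick(gsp_pure(pop_b), "pure"),
    "2" = pick(create_gsp(pop_b, pop_a, bc2 = TRUE), "BC2"),
    "3" = pick(create_gsp(pop_b, pop_a, bc1 = TRUE), "BC1"),
    "4" = pick(gsp_f1xbc1(pop_b, pop_a), "F1xBC1"),
    "5" = pick(create_gsp(pop_a, pop_b, f1 = TRUE), "F1"),
    "6" = pick(gsp_f1xbc1(pop_a, pop_b), "F1xBC1"),
    "7" = pick(create_gsp(pop_a, pop_b, bc1 = TRUE), "BC1"),
    "8" = pick(create_gsp(pop_a, pop_b, bc2 = TRUE), "BC2"),
    "9" = pick(gsp_pure(pop_a), "pure")
  )
}
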