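# shared fixtures, all built in code at test time

toy_genome <- function() {
  genome_spec(c("1", "2", "3"), c(5e6, 3e6, 2e6))
}

toy_rec_map <- function(spacing = 5e5, cM_per_Mb = 1) {
  build_rec_map(toy_genome(), cM_per_Mb = cM_per_Mb,
                boundary_spacing_bp = spacing)
}

# the published F2 worked example, built from raw node/edge tables
figure1_gsp <- function() {
  nodes <- data.frame(
    id = c("1", "2", "3", "4", "5", "6", "7", "s7"),
    kind = c(rep("founder", 4), rep("nonfounder", 3), "sample"),
    hpop1 = c("A", "A", "B", "B", NA, NA, NA, NA),
    hpop2 = c("A", "A", "B", "B", NA, NA, NA, NA),
    parent = c(rep(NA, 7), "7"),
    n_samples = c(rep(NA, 7), 4)
  )
  edges <- data.frame(
    parent = c("1", "3", "2", "4", "5", "6"),
    child = c("5", "5", "6", "6", "7", "7"),
    gametes = c(2, 2, 2, 2, 4, 4)
  )
  load_gsp(nodes, edges)
}

# random valid GSP: a random full "mating tree" whose internal nodes each
# receive 2 + 2 gametes; non-root internal nodes take one sample and pass
# two gametes on; the root takes two samples.  Any such tree satisfies the
# gamete-accounting conditions and is loop-free.
random_valid_gsp <- function(n_founders = sample(3:8, 1)) {
  stopifnot(n_founders >= 2)
  counter <- 0L
  nodes <- list(); edges <- list()
  new_id <- function() { counter <<- counter + 1L; as.character(counter) }
  # returns id of a supplier node for a subtree with k founder leaves
  build <- function(k, is_root) {
    if (k == 1L) {
      id <- new_id()
      pop <- sample(c("A", "B"), 1)
      nodes[[length(nodes) + 1L]] <<- data.frame(
        id = id, kind = "founder", hpop1 = pop, hpop2 = pop,
        parent = NA, n_samples = NA)
      return(id)
    }
    k_left <- sample.int(k - 1L, 1)
    left <- build(k_left, FALSE)
    right <- build(k - k_left, FALSE)
    id <- new_id()
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, kind = "nonfounder", hpop1 = NA, hpop2 = NA,
      parent = NA, n_samples = NA)
    edges[[length(edges) + 1L]] <<- data.frame(
      parent = c(left, right), child = id, gametes = 2)
    s <- if (is_root) 2 else 1
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = paste0("s", id), kind = "sample", hpop1 = NA, hpop2 = NA,
      parent = id, n_samples = s)
    id
  }
  if (n_founders == 2L) {
    # degenerate tree: one internal node taking both samples
    left <- build(1L, FALSE); right <- build(1L, FALSE)
    id <- new_id()
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = id, kind = "nonfounder", hpop1 = NA, hpop2 = NA,
      parent = NA, n_samples = NA)
    edges[[length(edges) + 1L]] <- data.frame(
      parent = c(left, right), child = id, gametes = 2)
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = paste0("s", id), kind = "sample", hpop1 = NA, hpop2 = NA,
      parent = id, n_samples = 2)
  } else {
    build(n_founders, TRUE)
  }
  load_gsp(do.call(rbind, nodes), do.call(rbind, edges))
}

# small genotype matrix with known structure
toy_geno <- function(n_per_pop = c(A = 6, B = 5), L = 12, seed = 1,
                     genome = toy_genome()) {
  set.seed(seed)
  total <- sum(genome$length)
  pos <- floor((seq_len(L) - 0.5) / L * total)
  ends <- cumsum(genome$length)
  ci <- findInterval(pos, c(0, ends), rightmost.closed = TRUE)
  map <- marker_map(genome$chrom[ci], paste0("m", seq_len(L)),
                    bp = pos - c(0, ends)[ci])
  N <- sum(n_per_pop)
  al <- matrix(sample(c("1", "2"), N * 2 * L, replace = TRUE), nrow = N)
  genotype_matrix(al, ids = paste0("i", seq_len(N)),
                  pops = rep(names(n_per_pop), n_per_pop), map = map)
}

# per-population per-locus sorted allele multisets (the conserved quantity)
pop_locus_counts <- function(geno) {
  L <- ncol(geno$geno) / 2L
  lapply(split(seq_along(geno$pops), geno$pops), function(rows) {
    lapply(seq_len(L), function(j) {
      al <- as.vector(geno$geno[rows, c(2 * j - 1, 2 * j)])
      al[is.na(al)] <- "<NA>"
      sort(al)
    })
  })
}
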