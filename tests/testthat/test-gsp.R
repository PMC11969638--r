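test_that("the F2 worked-example pedigree loads and validates", {
  g <- figure1_gsp()
  expect_length(gsped:::gsp_founders(g), 4)
  expect_length(gsped:::gsp_nonfounders(g), 3)
  v <- validate_gsp(g)
  expect_true(v$valid)
  expect_equal(nrow(v$violations), 0)
  # pure function: same input, same report
  expect_identical(validate_gsp(g), validate_gsp(g))
})

test_that("structural defects are rejected at load time", {
  nodes <- data.frame(id = c("1", "2", "3"),
                      kind = c("founder", "founder", "nonfounder"),
                      hpop1 = c("A", "A", NA), hpop2 = c("A", "A", NA))
  # founder as a child
  expect_error(load_gsp(nodes, data.frame(parent = c("1", "3"),
                                          child = c("3", "2"), gametes = 2)),
               "founder")
  # three parent edges
  nodes4 <- rbind(nodes, data.frame(id = "4", kind = "founder",
                                    hpop1 = "B", hpop2 = "B"))
  expect_error(load_gsp(nodes4, data.frame(parent = c("1", "2", "4"),
                                           child = "3", gametes = 2)),
               "exactly two")
  # dangling id
  expect_error(load_gsp(nodes, data.frame(parent = c("1", "9"),
                                          child = "3", gametes = 2)),
               "unknown node")
})

test_that("every create_gsp flag combination yields a valid GSP", {
  for (mask in 1:15) {
    fl <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    g <- create_gsp("A", "B", f1 = fl[1], f2 = fl[2], bc1 = fl[3], bc2 = fl[4])
    v <- validate_gsp(g)
    expect_true(v$valid, label = paste("flags", paste(fl, collapse = ",")))
    # conservation pre-check: deliverable samples = founders
    st <- gsped:::gsp_sample_table(g)
    expect_equal(sum(st$n_samples), length(gsped:::gsp_founders(g)))
  }
  expect_error(create_gsp("A", "B"), "at least one")
})

test_that("the F2-only preset matches the published worked example", {
  g <- create_gsp("A", "B", f2 = TRUE)
  expect_length(gsped:::gsp_founders(g), 4)
  st <- gsped:::gsp_sample_table(g)
  expect_equal(st$n_samples, 4)
  expect_equal(unname(attr(g, "sample_categories")[st$id]), "F2")
})

test_that("the all-four preset has the published sample counts", {
  g <- create_gsp("A", "B", f1 = TRUE, f2 = TRUE, bc1 = TRUE, bc2 = TRUE)
  cats <- attr(g, "sample_categories")
  st <- gsped:::gsp_sample_table(g)
  counts <- tapply(st$n_samples, cats[st$id], sum)
  expect_equal(unname(c(counts[c("F1", "F2", "BC1", "BC2")])),
               c(1, 2, 1, 2))
  expect_equal(sum(st$n_samples), length(gsped:::gsp_founders(g)))  # 6 = 6
})

test_that("special pedigrees validate and carry correct categories", {
  for (g in list(gsp_bc1xbc2("C", "S"), gsped:::gsp_f1xbc1("A", "B"),
                 gsped:::gsp_pure("A"), create_bc_ladder(4, "A", "B"))) {
    expect_true(validate_gsp(g)$valid)
  }
  lad <- create_bc_ladder(3, "A", "B")
  expect_setequal(unname(attr(lad, "sample_categories")),
                  c("F1", "BC1", "BC2", "BC3"))
  for (q in c(0, 1/8, 1/4, 3/8, 1/2, 5/8, 3/4, 7/8, 1)) {
    sp <- gsp_for_q(q, "A", "B")
    expect_true(validate_gsp(sp$gsp)$valid)
    expect_equal(sp$expected_q, q)
    expect_true(length(sp$target_nodes) >= 1)
  }
  expect_error(gsp_for_q(0.3, "A", "B"), "grid|one of")
})

test_that("each accounting violation is caught with its condition id", {
  base <- figure1_gsp()

  # fewer samples than founders: breaks c1 and the node-7 intake (c5)
  g <- base
  g$nodes$n_samples[g$nodes$id == "s7"] <- 3
  v <- validate_gsp(g)
  expect_false(v$valid)
  expect_setequal(v$violations$condition, c("c1", "c5"))

  # founder segregating three gametes: c2 (and the child's intake arithmetic)
  g <- base
  g$edges$gametes[g$edges$parent == "1"] <- 3
  v <- validate_gsp(g)
  expect_true("c2" %in% v$violations$condition)

  # unbalanced parent edges into node 7: c3
  g <- base
  g$edges$gametes[g$edges$parent == "5" & g$edges$child == "7"] <- 3
  v <- validate_gsp(g)
  expect_true("c3" %in% v$violations$condition)

  # a nonfounder with no sample node and no downward edges: c4
  g <- base
  g$nodes <- g$nodes[g$nodes$id != "s7", ]
  v <- validate_gsp(g)
  expect_true("c4" %in% v$violations$condition)
})

test_that("inbreeding loops are detected", {
  # node 8 has parents 5 and 7, but 5 is an ancestor of 7
  nodes <- data.frame(
    id = c("1", "2", "3", "4", "5", "6", "7", "8", "s8"),
    kind = c(rep("founder", 4), rep("nonfounder", 4), "sample"),
    hpop1 = c("A", "A", "B", "B", rep(NA, 5)),
    hpop2 = c("A", "A", "B", "B", rep(NA, 5)),
    parent = c(rep(NA, 8), "8"),
    n_samples = c(rep(NA, 8), 4)
  )
  edges <- data.frame(
    parent = c("1", "3", "2", "4", "5", "6", "5", "7"),
    child = c("5", "5", "6", "6", "7", "7", "8", "8"),
    gametes = c(2, 2, 2, 2, 2, 2, 2, 2)
  )
  v <- validate_gsp(load_gsp(nodes, edges))
  expect_true("loop" %in% v$violations$condition)
})

test_that("random mating-tree pedigrees always validate", {
  set.seed(202)
  for (i in 1:20) {
    expect_true(validate_gsp(random_valid_gsp())$valid)
  }
})
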