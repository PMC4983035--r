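quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Fitch cost matches hand-enumerated quartet cases", {
  expect_equal(fitch_cost(quartet, c(A = 1, B = 1, C = 0, D = 0))$cost, 1L)
  expect_equal(fitch_cost(quartet, c(A = 1, B = 1, C = 1, D = 1))$cost, 0L)
  expect_equal(fitch_cost(quartet, c(A = 1, B = 0, C = 1, D = 0))$cost, 2L)
})

test_that("the returned ancestral labeling attains the reported cost", {
  set.seed(3)
  for (i in 1:25) {
    tree <- simulate_tree(sample(4:8, 1), seed = i)
    st <- random_binary_states(tree)
    fc <- fitch_cost(tree, st)
    realized <- sum(fc$labeling[tree$edge[, 1]] != fc$labeling[tree$edge[, 2]])
    expect_equal(realized, fc$cost)
    expect_equal(unname(fc$labeling[tree$tip.label]), unname(st[tree$tip.label]))
  }
})

test_that("Fitch equals the exhaustive-labeling minimum on random trees", {
  set.seed(29)
  for (i in 1:60) {
    tree <- simulate_tree(sample(4:8, 1), seed = 1000 + i)
    st <- random_binary_states(tree)
    expect_equal(fitch_cost(tree, st)$cost, brute_fitch(tree, st))
  }
})

test_that("generalized Fitch handles polytomies against brute force", {
  set.seed(61)
  for (tree in polytomy_trees()) {
    for (i in 1:20) {
      st <- random_binary_states(tree)
      fc <- fitch_cost(tree, st)
      expect_equal(fc$cost, brute_fitch(tree, st))
      realized <- sum(fc$labeling[tree$edge[, 1]] != fc$labeling[tree$edge[, 2]])
      expect_equal(realized, fc$cost)
    }
  }
})

test_that("Fitch cost agrees with phangorn on random binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(111)
  for (i in 1:10) {
    tree <- simulate_tree(sample(4:10, 1), seed = 2000 + i)
    st <- random_binary_states(tree)
    dat <- phangorn::phyDat(matrix(as.character(st[tree$tip.label]), ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_cost(tree, st)$cost,
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("Fitch cost never exceeds the smaller state count", {
  set.seed(43)
  for (i in 1:20) {
    tree <- simulate_tree(8, seed = 3000 + i)
    st <- random_binary_states(tree)
    expect_lte(fitch_cost(tree, st)$cost, min(sum(st == 0), sum(st == 1)))
  }
})

test_that("Dollo places the gain above the MRCA with minimal losses", {
  ds <- dollo_scenario(quartet, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(ds$gain_label, "n6")  # MRCA(A,B)
  expect_equal(ds$n_losses, 0L)
  expect_equal(ds$event_count, 1L)

  ds2 <- dollo_scenario(quartet, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(ds2$gain_node, 5L)  # root
  expect_setequal(ds2$loss_labels, c("B", "D"))
  expect_equal(ds2$event_count, 3L)

  ds3 <- dollo_scenario(quartet, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(ds3$gain_node, 5L)
  expect_equal(ds3$n_losses, 0L)

  ds0 <- dollo_scenario(quartet, c(A = 0, B = 0, C = 0, D = 0))
  expect_true(is.na(ds0$gain_node))
  expect_equal(ds0$event_count, 0L)
})

test_that("Dollo event count equals the single-gain brute-force minimum", {
  set.seed(53)
  for (i in 1:30) {
    tree <- simulate_tree(sample(4:8, 1), seed = 4000 + i)
    st <- random_binary_states(tree)
    expect_equal(dollo_scenario(tree, st)$event_count,
                 brute_dollo_events(tree, st))
  }
})

test_that("gains-only cost counts maximal all-present clades", {
  expect_equal(gains_only_cost(quartet, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(gains_only_cost(quartet, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_equal(gains_only_cost(quartet, c(A = 0, B = 0, C = 0, D = 0)), 0L)
  set.seed(59)
  for (i in 1:30) {
    tree <- simulate_tree(sample(4:8, 1), seed = 5000 + i)
    st <- random_binary_states(tree)
    expect_equal(gains_only_cost(tree, st), brute_gains_only(tree, st))
  }
})

test_that("event-count inequalities hold on random characters", {
  set.seed(67)
  for (i in 1:30) {
    tree <- simulate_tree(sample(5:10, 1), seed = 6000 + i)
    st <- random_binary_states(tree)
    fc <- fitch_cost(tree, st)$cost
    if (any(st == 1)) {
      expect_gte(dollo_scenario(tree, st)$event_count, fc)
      expect_gte(gains_only_cost(tree, st), 1L)
    }
  }
})

test_that("costs are invariant under consistent leaf relabeling", {
  set.seed(71)
  tree <- simulate_tree(10, seed = 99)
  st <- random_binary_states(tree)
  ## rename leaves via a fixed bijection and permute the state vector to match
  map <- stats::setNames(paste0("x", seq_along(tree$tip.label)),
                         tree$tip.label)
  tree3 <- tree
  tree3$tip.label <- unname(map[tree$tip.label])
  st3 <- stats::setNames(unname(st[names(map)]), unname(map))
  expect_equal(fitch_cost(tree3, st3)$cost, fitch_cost(tree, st)$cost)
  expect_equal(gains_only_cost(tree3, st3), gains_only_cost(tree, st))
  expect_equal(dollo_scenario(tree3, st3)$event_count,
               dollo_scenario(tree, st)$event_count)
})

test_that("scenario comparison renders the documented verdicts", {
  tree <- make_balanced16()
  st <- scattered_states16()
  m <- matrix(st[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, "Cter"))
  res <- compare_scenarios(tree, m)
  expect_equal(res$gains_only_cost, 4L)
  expect_gt(res$dollo_event_count, 4L)
  expect_equal(res$verdict, "convergence_scenario")

  clade <- stats::setNames(rep(0L, 16), tree$tip.label)
  clade[c("t1", "t2", "t3", "t4")] <- 1L
  m2 <- matrix(clade[tree$tip.label], ncol = 1,
               dimnames = list(tree$tip.label, "RD2"))
  res2 <- compare_scenarios(tree, m2)
  expect_equal(res2$gains_only_cost, 1L)
  expect_equal(res2$dollo_event_count, 1L)
  expect_equal(res2$verdict, "tie")

  allone <- matrix(1L, 16, 1, dimnames = list(tree$tip.label, "HD"))
  expect_equal(compare_scenarios(tree, allone)$verdict, "tie")
})

test_that("state validation raises the documented errors", {
  expect_error(fitch_cost(quartet, c(A = 1, B = 0, C = 1)), "leaf without state")
  expect_error(fitch_cost(quartet, c(A = 1, B = 0, C = 1, D = 2)), "0/1")
  m <- matrix(1L, 2, 1, dimnames = list(c("A", "Z"), "c"))
  expect_error(compare_scenarios(quartet, m), "taxa not in tree")
})
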