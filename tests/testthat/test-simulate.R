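test_that("simulated trees are binary, ultrametric, unit height", {
  set.seed(16)
  t2 <- simulate_tree(2)
  expect_equal(sort(t2$edge.length), c(1, 1))
  yt <- simulate_tree(50)
  expect_equal(ape::Ntip(yt), 50)
  expect_equal(yt$Nnode, 49)
  expect_true(ape::is.binary(yt))
  expect_true(ape::is.ultrametric(yt, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(yt)), 1, tolerance = 1e-12)
  set.seed(99); a <- ape::write.tree(simulate_tree(12))
  set.seed(99); b <- ape::write.tree(simulate_tree(12))
  expect_identical(a, b)
})

test_that("zero rates with pe = 1 propagate the root state to every tip", {
  set.seed(17)
  Q <- build_q(anagenetic_rates(0, 0, 0, 0, 0), space2)
  te <- build_clado_tensor(space2, clado_params(0, 0))
  yt <- simulate_tree(10)
  h <- simulate_history(yt, Q, te, space2)
  expect_true(all(h$tip_states == h$node_states[["11"]]))
  expect_true(all(vapply(h$paths, nrow, 0L) == 1))
})

test_that("single-branch tip distribution matches the expm row", {
  set.seed(18)
  r <- anagenetic_rates(.8, .6, .4, .7, 1.2)
  Q <- build_q(r, space2)
  te <- build_clado_tensor(space2, clado_params(0, 0))  # identity clado
  tree <- ape::read.tree(text = "(A:0.7,B:0.0);")
  i0 <- state_index(space2, "HC")
  rf <- rep(0, 5); rf[i0] <- 1
  n_rep <- 20000
  counts <- numeric(5)
  for (i in seq_len(n_rep)) {
    h <- simulate_history(tree, Q, te, space2, root_option = rf)
    s <- h$tip_states[["A"]]
    counts[s] <- counts[s] + 1
  }
  want <- as.numeric(Matrix::expm(Q * 0.7)[i0, ])
  tv <- sum(abs(counts / n_rep - want)) / 2
  expect_lt(tv, 0.01)
})

test_that("node-event category frequencies follow (pe, ps, pb)", {
  # simulate cladogenesis at the root of a cherry from parent HC and
  # classify the corner pair: equal (both full), subset (one full), split
  set.seed(19)
  cp <- clado_params(0.5, 0.2)
  te <- build_clado_tensor(space2, cp)
  Q <- build_q(anagenetic_rates(0, 0, 0, 0, 0), space2)
  tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  iHC <- state_index(space2, "HC")
  rf <- rep(0, 5); rf[iHC] <- 1
  n_rep <- 6000
  scen <- integer(3)
  for (i in seq_len(n_rep)) {
    h <- simulate_history(tree, Q, te, space2, root_option = rf)
    full <- sum(h$corner_states == iHC)
    scen[3 - full] <- scen[3 - full] + 1  # 2 full=equal, 1=subset, 0=split
  }
  freq <- scen / n_rep
  expect_lt(max(abs(freq - c(1 - 0.7, 0.5, 0.2))), 0.02)
})

test_that("masking honors treatment fractions and keeps the truth", {
  set.seed(20)
  tips <- stats::setNames(sample.int(space3$n_states, 40, replace = TRUE),
                          paste0("t", 1:40))
  worst <- mask_tips(tips, space3, 0, 1)
  for (i in seq_along(tips)) {
    k <- sum(space3$codes[tips[i], ] != 2)
    expect_equal(sum(worst[, i]), 2^k)
    expect_equal(unname(worst[tips[i], i]), 1L)
  }
  # 66% treatment on a 4-state set removes exactly 2 non-true states
  tip211 <- stats::setNames(state_index(space3, "211"), "x")
  m66 <- mask_tips(tip211, space3, 2 / 3, 1)
  expect_equal(sum(m66), 2)
  expect_equal(unname(m66[state_index(space3, "211"), 1]), 1L)
  m33 <- mask_tips(tip211, space3, 1 / 3, 1)
  expect_equal(sum(m33), 3)
  # entirely confirmed: single state per treated tip
  conf <- mask_tips(tips, space3, 1, 1)
  expect_true(all(colSums(conf) == 1))
  expect_true(all(conf[cbind(tips, seq_along(tips))] == 1L))
  # fraction = 0 leaves the worst case untouched; truth always kept
  expect_identical(mask_tips(tips, space3, 0, 1), worst)
  part <- mask_tips(tips, space3, 2 / 3, 0.25)
  expect_true(all(part[cbind(tips, seq_along(tips))] == 1L))
  expect_equal(sum(colSums(part) < colSums(worst)), 10)  # 25% of 40 treated
})

test_that("binary recoding collapses ambiguity onto the established set", {
  dspace <- build_dec_space(3, c("T", "W", "C"))
  tips <- stats::setNames(state_index(space3, c("211", "222", "200")),
                          c("a", "b", "c"))
  dm <- recode_dec(tips, space3, dspace)
  expect_equal(colSums(dm), c(a = 1, b = 1, c = 1))
  expect_equal(dspace$digits[which(dm[, "a"] == 1)], "200")
  expect_equal(dspace$digits[which(dm[, "b"] == 1)], "222")
  # a worst-case ambiguous mask recodes to the same singleton
  worst <- mask_tips(tips, space3, 0, 1)
  dm2 <- recode_dec(worst, space3, dspace)
  expect_identical(dm2, dm)
})
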