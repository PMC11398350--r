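test_that("sampled histories respect tensor support and no-change limits", {
  set.seed(12)
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  Q <- build_q(anagenetic_rates(1e-9, 1e-9, 1e-9, 1e-9, 1e-9), space2)
  te <- build_clado_tensor(space2, clado_params(0.25, 0.25))
  masks <- matrix(0L, 5, 2, dimnames = list(NULL, c("A", "B")))
  iH <- state_index(space2, "H")
  masks[iH, ] <- 1L
  for (rep in 1:20) {
    h <- sample_history(tree, masks, Q, te)
    expect_equal(unname(h$node_states[["3"]]), iH)
    expect_equal(unname(h$corner_states), c(iH, iH))
  }
  # corner pairs always lie in the tensor support of the node state
  Q2 <- build_q(anagenetic_rates(.5, .5, .5, .5, .5), space2)
  masks2 <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "B")))
  key <- paste(te$parent, te$left, te$right)[te$prob > 0]
  for (rep in 1:50) {
    h <- sample_history(tree, masks2, Q2, te)
    expect_true(paste(h$node_states[["3"]], h$corner_states[1],
                      h$corner_states[2]) %in% key)
  }
})

test_that("node-state frequencies match brute-force conditionals", {
  set.seed(13)
  Q <- build_q(anagenetic_rates(.6, .8, .3, .5, .7), space2)
  te <- build_clado_tensor(space2, clado_params(0.3, 0.4))
  masks <- matrix(0L, 5, 3, dimnames = list(NULL, tree3$tip.label))
  masks[c(3, 4), 1] <- 1L   # A in {H, Hc}
  masks[1, 2] <- 1L         # B = C
  masks[, 3] <- 1L          # C ambiguous
  want <- brute_force_root_marginal(tree3, masks, Q, te)
  n_draw <- 8000
  counts <- numeric(5)
  for (i in 1:n_draw) {
    h <- sample_history(tree3, masks, Q, te)
    s <- h$node_states[["4"]]
    counts[s] <- counts[s] + 1
  }
  freq <- counts / n_draw
  tol <- 4 * sqrt(pmax(want * (1 - want), 1e-4) / n_draw)
  expect_true(all(abs(freq - want) <= tol))
})

test_that("summaries are per-biome normalized and match a uniform example", {
  # uniform state frequencies over the 5 two-biome states: the affinity
  # probabilities at biome H are (0.2, 0.2, 0.6) for codes (0, 1, 2)
  loc_states <- list()
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  Q <- build_q(anagenetic_rates(.5, .5, .5, .5, .5), space2)
  te <- build_clado_tensor(space2, clado_params(1 / 3, 1 / 3))
  masks <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "B")))
  samples <- lapply(1:5, function(s) {
    h <- sample_history(tree, masks, Q, te)
    h$node_states[3] <- s           # force uniform root frequencies
    h
  })
  summ <- summarize_histories(samples, space2)
  expect_lt(max(abs(apply(summ$prob, c(1, 2), sum) - 1)), 1e-12)
  root_row <- which(summ$locations$id == "3" & summ$locations$kind == "node")
  expect_equal(unname(summ$prob[root_row, "H", ]), c(0.2, 0.2, 0.6))
  expect_equal(unname(summ$prob[root_row, "C", ]), c(0.2, 0.2, 0.6))
  # single history gives one-hot summaries
  s1 <- summarize_histories(samples[1], space2)
  expect_true(all(s1$prob %in% c(0, 1)))
})

test_that("affinity accuracy is the mean posterior mass on the truth", {
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  Q <- build_q(anagenetic_rates(.5, .5, .5, .5, .5), space2)
  te <- build_clado_tensor(space2, clado_params(1 / 3, 1 / 3))
  masks <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "B")))
  set.seed(14)
  h <- sample_history(tree, masks, Q, te)
  summ <- summarize_histories(list(h), space2)
  truth <- history_truth(h, space2)
  acc <- affinity_accuracy(truth, summ)
  expect_true(all(acc[!is.na(acc)] == 1))
  # uniform summaries score 1/3 on every present type
  summ$prob[] <- 1 / 3
  acc_u <- affinity_accuracy(truth, summ)
  expect_true(all(abs(acc_u[!is.na(acc_u)] - 1 / 3) < 1e-12))
  # hand-built two-location example: supports 0.7 and 0.9 on truth -> 0.8
  summ2 <- summ
  summ2$prob[] <- 0
  truth2 <- truth; truth2[] <- 0L
  truth2[1, 1] <- 2L; truth2[2, 1] <- 2L
  summ2$prob[, , 1] <- 1
  summ2$prob[1, 1, ] <- c(0.3, 0, 0.7)
  summ2$prob[2, 1, ] <- c(0.1, 0, 0.9)
  acc2 <- affinity_accuracy(truth2, summ2)
  expect_equal(unname(acc2["2"]), 0.8)
  expect_error(affinity_accuracy(truth[1:2, , drop = FALSE], summ),
               "misaligned")
})

test_that("null baseline pools posterior mass across replicates", {
  tree <- ape::read.tree(text = "(A:0.5,B:0.5);")
  Q <- build_q(anagenetic_rates(.5, .5, .5, .5, .5), space2)
  te <- build_clado_tensor(space2, clado_params(1 / 3, 1 / 3))
  masks <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "B")))
  set.seed(15)
  summs <- lapply(1:3, function(i)
    summarize_histories(list(sample_history(tree, masks, Q, te)), space2))
  uniform <- summs[[1]]
  uniform$prob[] <- 1 / 3
  nb <- null_baseline(list(uniform, uniform))
  expect_true(all(abs(nb - 1 / 3) < 1e-12))
  nb1 <- null_baseline(summs[1])
  nb3 <- null_baseline(summs)
  direct <- rowMeans(vapply(summs, function(s)
    c(mean(s$prob[, , 1]), mean(s$prob[, , 2]), mean(s$prob[, , 3])),
    numeric(3)))
  expect_equal(unname(nb3), unname(direct))
  expect_equal(unname(nb1), c(mean(summs[[1]]$prob[, , 1]),
                              mean(summs[[1]]$prob[, , 2]),
                              mean(summs[[1]]$prob[, , 3])))
})
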