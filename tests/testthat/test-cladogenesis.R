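test_that("closed-form outcome counts match brute-force enumeration", {
  for (n_est in 1:4) {
    cnt <- count_outcomes(n_est)
    parent <- rep(0L, 4)
    parent[seq_len(n_est)] <- 2L
    oracle <- brute_force_outcomes(parent)
    scen <- vapply(oracle, `[[`, "", "scenario")
    expect_equal(cnt$n_e, sum(scen == "equal"))
    expect_equal(cnt$n_s, sum(scen == "subset"))
    expect_equal(cnt$n_b, sum(scen == "split"))
  }
  expect_equal(unlist(count_outcomes(2)[1:3]), c(n_e = 1, n_s = 8, n_b = 4))
  expect_equal(unlist(count_outcomes(3)[1:3]), c(n_e = 1, n_s = 24, n_b = 12))
  expect_equal(unlist(count_outcomes(1)[1:3]), c(n_e = 1, n_s = 0, n_b = 0))
  expect_error(count_outcomes(0), "n_est")
})

test_that("single-established parents inherit identically", {
  cp <- clado_params(0.5, 0.3)
  ev <- enumerate_clado_events(c(2L, 1L), cp)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left[[1]], c(2L, 1L))
  expect_equal(ev$right[[1]], c(2L, 1L))
  expect_equal(ev$probability, 1)
  te <- build_clado_tensor(space2, cp)
  i <- state_index(space2, "Hc")
  sl <- clado_slice(te, i, space2)
  expect_equal(unname(sl[i, i]), 1)
  expect_equal(sum(sl), 1)
})

test_that("the worked parent-HC slice has w_s = ps/8, w_b = pb/4, w_e = pe", {
  cp <- clado_params(ps = 0.48, pb = 0.32)
  te <- build_clado_tensor(space2, cp)
  sl <- clado_slice(te, state_index(space2, "HC"), space2)
  ws <- 0.48 / 8; wb <- 0.32 / 4; we <- 1 - 0.48 - 0.32
  expected <- matrix(0, 5, 5, dimnames = list(c("H", "C", "Hc", "hC", "HC"),
                                              c("H", "C", "Hc", "hC", "HC")))
  expected["H", "C"] <- wb; expected["C", "H"] <- wb
  expected["Hc", "hC"] <- wb; expected["hC", "Hc"] <- wb
  expected["H", "HC"] <- ws; expected["C", "HC"] <- ws
  expected["Hc", "HC"] <- ws; expected["hC", "HC"] <- ws
  expected["HC", "H"] <- ws; expected["HC", "C"] <- ws
  expected["HC", "Hc"] <- ws; expected["HC", "hC"] <- ws
  expected["HC", "HC"] <- we
  perm <- rownames(expected)
  expect_equal(sl[perm, perm], expected)
})

test_that("enabled-only biomes pass unchanged; reduction mode is global", {
  # parent TWc = (2,2,1): split {T},{W} with reduction to non-affinity
  ev <- enumerate_clado_events(c(2L, 2L, 1L), clado_params(0.3, 0.3))
  split0 <- ev[ev$scenario == "split" & ev$reduction == "to_non_affinity", ]
  lefts <- vapply(split0$left, paste, "", collapse = "")
  rights <- vapply(split0$right, paste, "", collapse = "")
  expect_true(any(lefts == "201" & rights == "021"))
  # no event mixes modes across the two daughters
  split1 <- ev[ev$scenario == "split" & ev$reduction == "to_enabled", ]
  expect_true(all(vapply(seq_len(nrow(split1)), function(k)
    all(c(split1$left[[k]], split1$right[[k]]) != 0L), TRUE)))
})

test_that("tensor normalizes, is daughter-exchange symmetric, stays in-space", {
  set.seed(21)
  for (B in 1:4) {
    sp <- enumerate_states(B)
    te <- build_clado_tensor(sp, random_clado())
    sums <- tapply(te$prob, te$parent, sum)
    expect_lt(max(abs(sums - 1)), 1e-12)
    # symmetry prob(i; j, k) = prob(i; k, j)
    key <- paste(te$parent, te$left, te$right)
    agg <- tapply(te$prob, key, sum)
    mirror <- paste(te$parent, te$right, te$left)
    magg <- tapply(te$prob, mirror, sum)
    expect_equal(agg[sort(names(agg))], magg[sort(names(magg))],
                 tolerance = 1e-12)
    expect_true(all(te$left >= 1 & te$left <= sp$n_states))
    expect_true(all(te$right >= 1 & te$right <= sp$n_states))
  }
})

test_that("pe = 1 collapses the tensor to identity inheritance", {
  te <- build_clado_tensor(space3, clado_params(0, 0))
  expect_true(all(te$prob[te$left == te$parent & te$right == te$parent] == 1))
  expect_true(all(te$prob[te$left != te$parent | te$right != te$parent] == 0))
})

test_that("information-free cladogenesis reduces to a pure anagenetic CTMC", {
  # ps = pb = 0: the combine is an elementwise product, so the tree
  # likelihood equals standard pruning without any cladogenetic step
  set.seed(31)
  Q <- build_q(random_rates(), space2)
  te <- build_clado_tensor(space2, clado_params(0, 0))
  masks <- random_masks(space2, c("A", "B", "C", "D"))
  tree <- tree4_bal
  ll <- prune_loglik(tree, masks, Q, te)
  # independent standard pruning (no cladogenetic transitions)
  partial <- function(node) {
    if (node <= 4) return(masks[, tree$tip.label[node]])
    ce <- which(tree$edge[, 1] == node)
    out <- rep(1, 5)
    for (e in ce) {
      P <- as.matrix(Matrix::expm(Q * tree$edge.length[e]))
      out <- out * as.numeric(P %*% partial(tree$edge[e, 2]))
    }
    out
  }
  ll_ctmc <- log(mean(partial(5L)))
  expect_equal(ll, ll_ctmc, tolerance = 1e-10)
})
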