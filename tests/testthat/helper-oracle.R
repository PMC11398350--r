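# Independent likelihood oracle: exhaustive sum over every assignment of
# internal-node states (pre-cladogenesis) and branch-start corner states,
# with per-branch transition probabilities from Matrix::expm and tip states
# marginalized against the masks. O(S^(nodes + edges)) -- tiny trees only.

brute_force_loglik <- function(tree, masks, q, tensor, root_freq = NULL) {
  S <- nrow(q)
  nt <- length(tree$tip.label)
  edge <- tree$edge
  internal <- (nt + 1L):(2L * nt - 1L)
  if (is.null(root_freq)) root_freq <- rep(1 / S, S)
  n_vars <- length(internal) + nrow(edge)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_vars)))
  node_col <- function(n) grid[, match(n, internal)]
  corner_col <- function(e) grid[, length(internal) + e]

  Pt <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(q * t)))
  Parr <- array(0, c(S, S, S))
  for (k in seq_along(tensor$parent))
    Parr[tensor$parent[k], tensor$left[k], tensor$right[k]] <-
      Parr[tensor$parent[k], tensor$left[k], tensor$right[k]] +
      tensor$prob[k]

  term <- root_freq[node_col(nt + 1L)]
  for (n in internal) {
    ce <- which(edge[, 1] == n)
    term <- term * Parr[cbind(node_col(n), corner_col(ce[1]),
                              corner_col(ce[2]))]
  }
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    if (child <= nt) {
      tip_factor <- as.numeric(Pt[[e]] %*% masks[, tree$tip.label[child]])
      term <- term * tip_factor[corner_col(e)]
    } else {
      term <- term * Pt[[e]][cbind(corner_col(e), node_col(child))]
    }
  }
  log(sum(term))
}

# brute-force conditional marginal of the root (pre-cladogenesis) state
brute_force_root_marginal <- function(tree, masks, q, tensor,
                                      root_freq = NULL) {
  S <- nrow(q)
  nt <- length(tree$tip.label)
  if (is.null(root_freq)) root_freq <- rep(1 / S, S)
  probs <- vapply(seq_len(S), function(i) {
    rf <- rep(0, S); rf[i] <- root_freq[i]
    exp(brute_force_loglik(tree, masks, q, tensor, rf))
  }, 0)
  probs / sum(probs)
}

# brute-force enumeration of cladogenetic outcomes from first principles:
# every (which daughter is reduced / subset / ordered bipartition / global
# reduction mode) combination, without the closed-form counts
brute_force_outcomes <- function(parent, modes = c(1L, 0L)) {
  est <- which(parent == 2L)
  n <- length(est)
  outcomes <- list(list(left = parent, right = parent, scenario = "equal"))
  if (n >= 2L) {
    subsets <- unlist(lapply(seq_len(n - 1L), function(k)
      utils::combn(est, k, simplify = FALSE)), recursive = FALSE)
    reduce <- function(keep, mode) {
      d <- parent; d[setdiff(est, keep)] <- mode; d
    }
    for (A in subsets) for (m in modes) {
      outcomes <- c(outcomes,
                    list(list(left = parent, right = reduce(A, m),
                              scenario = "subset"),
                         list(left = reduce(A, m), right = parent,
                              scenario = "subset"),
                         list(left = reduce(A, m),
                              right = reduce(setdiff(est, A), m),
                              scenario = "split")))
    }
  }
  outcomes
}
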