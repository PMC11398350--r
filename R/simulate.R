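#' Simulate a pure-birth tree rescaled to unit height
#'
#' Yule process started from the root split: with k lineages the waiting
#' time to the next split is Exponential(k), the splitting lineage is chosen
#' uniformly, and after the n-th lineage appears one further Exponential(n)
#' waiting time runs to the present. Branch lengths are rescaled so the root
#' height is 1, matching the convention that rates are measured per unit
#' tree height.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth birth rate (only the shape distribution matters after
#'   rescaling).
#' @return an ultrametric \code{ape::phylo} with tips "t1".."tn".
#' @export
simulate_tree <- function(n_tips, birth = 1) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  # temp records: parent temp-id, birth time, end time (NA while active)
  parent <- c(NA_integer_, 1L, 1L)
  t_birth <- c(0, 0, 0)
  t_end <- c(0, NA, NA)   # temp node 1 is the root, splitting at time 0
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    t <- t + stats::rexp(1, length(active) * birth)
    i <- active[sample.int(length(active), 1L)]
    t_end[i] <- t
    ids <- length(parent) + 1:2
    parent <- c(parent, i, i)
    t_birth <- c(t_birth, t, t)
    t_end <- c(t_end, NA, NA)
    active <- c(setdiff(active, i), ids)
  }
  t_total <- t + stats::rexp(1, n_tips * birth)
  t_end[active] <- t_total

  is_tip <- seq_along(parent) %in% active
  node_id <- integer(length(parent))
  node_id[is_tip] <- seq_len(n_tips)
  node_id[1L] <- n_tips + 1L
  node_id[!is_tip & seq_along(parent) != 1L] <-
    n_tips + 1L + seq_len(sum(!is_tip) - 1L)
  nonroot <- seq_along(parent)[-1L]
  tree <- list(edge = cbind(node_id[parent[nonroot]], node_id[nonroot]),
               edge.length = (t_end[nonroot] - t_birth[nonroot]) / t_total,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_tips - 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a character history along a tree
#'
#' Forward realization of the process: the root state is drawn from
#' \code{root_option}; a cladogenetic outcome is drawn from the tensor slice
#' at the root and at every internal node; along each branch anagenetic
#' events are drawn by competing exponentials over the positive off-diagonal
#' rates of the current state (Gillespie).
#'
#' @param tree rooted binary \code{ape::phylo} with branch lengths.
#' @param q anagenetic generator.
#' @param tensor cladogenetic tensor.
#' @param space the state space.
#' @param root_option "uniform" or a probability vector over states.
#' @return object of classes \code{rfbs_true_history} and
#'   \code{rfbs_history}: \code{node_states} (per node, tips included, the
#'   state just before cladogenesis or at the tip), \code{corner_states}
#'   (per edge, the state at the branch start), \code{tip_states} (named by
#'   tip label), and \code{paths} (per edge, data frame of piecewise-constant
#'   segments with columns time, state).
#' @export
simulate_history <- function(tree, q, tensor, space, root_option = "uniform") {
  enc <- encode_tree(tree)
  edge <- tree$edge
  n_tips <- enc$n_tips
  root <- n_tips + 1L
  pi0 <- .root_freq(root_option, space$n_states)
  node_states <- integer(2L * n_tips - 1L)
  corner_states <- integer(nrow(edge))
  paths <- vector("list", nrow(edge))
  node_states[root] <- sample.int(space$n_states, 1L, prob = pi0)
  children_edges <- split(seq_len(nrow(edge)), edge[, 1])
  stack <- root
  while (length(stack)) {
    node <- stack[1L]; stack <- stack[-1L]
    ce <- children_edges[[as.character(node)]]
    sel <- which(tensor$parent == node_states[node])
    k <- sel[sample.int(length(sel), 1L, prob = tensor$prob[sel])]
    corner_states[ce[1L]] <- tensor$left[k]
    corner_states[ce[2L]] <- tensor$right[k]
    for (e in ce) {
      seg_t <- 0; s <- corner_states[e]
      times <- 0; states <- s
      repeat {
        out_rate <- -q[s, s]
        if (out_rate <= 0) break
        dt <- stats::rexp(1, out_rate)
        if (seg_t + dt > tree$edge.length[e]) break
        seg_t <- seg_t + dt
        w <- q[s, ]; w[s] <- 0
        s <- sample.int(space$n_states, 1L, prob = w)
        times <- c(times, seg_t); states <- c(states, s)
      }
      paths[[e]] <- data.frame(time = times, state = states)
      child <- edge[e, 2L]
      node_states[child] <- s
      if (child > n_tips) stack <- c(stack, child)
    }
  }
  tip_states <- stats::setNames(node_states[seq_len(n_tips)], tree$tip.label)
  structure(list(node_states = stats::setNames(node_states,
                                               seq_along(node_states)),
                 corner_states = stats::setNames(corner_states, edge[, 2L]),
                 tip_states = tip_states, paths = paths),
            class = c("rfbs_true_history", "rfbs_history"))
}

#' Apply an ambiguity-resolution treatment to true tip states
#'
#' The baseline (worst-case) coding scores every established biome as {2}
#' and every unestablished biome as ambiguous {0, 1}, giving each tip a
#' compatible set of 2^k states for k unestablished biomes. For a fraction
#' \code{tip_fraction} of tips (sampled without replacement), a fraction
#' \code{resolve_fraction} of the non-true compatible states is removed
#' (\code{ceiling(resolve_fraction * n_non_true)} states chosen uniformly),
#' so \code{resolve_fraction = 1} confirms the single true state and
#' \code{resolve_fraction = 0} leaves the worst case untouched. The true
#' state is never removed.
#'
#' @param tip_states named integer vector of true state indices (from
#'   [simulate_history()]).
#' @param space the state space.
#' @param resolve_fraction fraction of non-true ambiguous states removed,
#'   in [0, 1] (the study treatments use 0, 1/3, 2/3, 1).
#' @param tip_fraction fraction of tips treated (0.25, 0.75, or 1).
#' @return S x n_tips 0/1 mask matrix, columns named by species.
#' @export
mask_tips <- function(tip_states, space, resolve_fraction = 0,
                      tip_fraction = 1) {
  if (resolve_fraction < 0 || resolve_fraction > 1 ||
      tip_fraction < 0 || tip_fraction > 1)
    stop("fractions must lie in [0, 1]")
  n <- length(tip_states)
  masks <- matrix(0L, space$n_states, n,
                  dimnames = list(NULL, names(tip_states)))
  for (i in seq_len(n)) {
    est <- space$codes[tip_states[i], ] == 2L
    compat <- which(apply(space$codes, 1L, function(cd)
      all((cd == 2L) == est)))
    masks[compat, i] <- 1L
  }
  treated <- sample.int(n, round(tip_fraction * n))
  for (i in treated) {
    non_true <- setdiff(which(masks[, i] == 1L), tip_states[i])
    n_rm <- ceiling(resolve_fraction * length(non_true))
    if (n_rm > 0L)
      masks[non_true[sample.int(length(non_true))][seq_len(n_rm)], i] <- 0L
  }
  masks
}

#' Recode affinity data for the presence/absence baseline
#'
#' Established affinities (code 2) become presence; enabled and
#' non-affinities (codes 0 and 1, including any ambiguity between them)
#' become absence. The recoding collapses all tip ambiguity, since every
#' state in a compatible set shares the established pattern.
#'
#' @param tip_masks S x n_tips mask matrix over the full state space (or a
#'   named vector of true state indices).
#' @param space the full affinity state space.
#' @param dec_space the presence/absence space ([build_dec_space()]) built on
#'   the same biomes.
#' @return S_dec x n_tips 0/1 mask matrix (singleton columns).
#' @export
recode_dec <- function(tip_masks, space, dec_space) {
  if (!is.matrix(tip_masks)) {
    m <- matrix(0L, space$n_states, length(tip_masks),
                dimnames = list(NULL, names(tip_masks)))
    m[cbind(as.integer(tip_masks), seq_along(tip_masks))] <- 1L
    tip_masks <- m
  }
  out <- matrix(0L, dec_space$n_states, ncol(tip_masks),
                dimnames = list(NULL, colnames(tip_masks)))
  for (i in seq_len(ncol(tip_masks))) {
    st <- which(tip_masks[, i] == 1L)
    pres <- space$codes[st, , drop = FALSE] == 2L
    if (nrow(unique(pres)) != 1L)
      stop("mask for ", colnames(tip_masks)[i],
           " mixes established patterns; cannot recode")
    dec_codes <- ifelse(pres[1L, ], 2L, 0L)
    out[state_index(dec_space, dec_codes), i] <- 1L
  }
  out
}
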