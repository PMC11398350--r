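#' Jointly sample an ancestral history
#'
#' Backward filtering / forward sampling conditional on the tip data and the
#' current parameters: the root state is drawn proportional to the root
#' frequencies times the root partials; at each internal node with state i
#' the daughter corner pair (j, k) is drawn proportional to
#' \eqn{P(i;j,k) F_{left}(j) F_{right}(k)}; along each branch the child node
#' state is drawn proportional to \eqn{e^{Qt}_{j j'} D(child)_{j'}}. Node
#' states are the states just before cladogenesis; corner states are the
#' states at the very start of each daughter branch, just after it.
#'
#' @param tree rooted binary \code{ape::phylo} (or an encoded tree from the
#'   MCMC engine).
#' @param tip_masks S x n_tips 0/1 matrix, columns named by species.
#' @param q anagenetic generator.
#' @param tensor cladogenetic tensor.
#' @param root_option root state frequencies.
#' @return list of class \code{rfbs_history}: \code{node_states} (state index
#'   per node, tips included, named by node number) and \code{corner_states}
#'   (state index per edge, named by the edge's child node).
#' @export
sample_history <- function(tree, tip_masks, q, tensor,
                           root_option = "uniform") {
  enc <- if (inherits(tree, "phylo")) encode_tree(tree, colnames(tip_masks))
         else tree
  res <- .prune_call(enc, tip_masks, q, tensor, root_option, TRUE, TRUE)
  if (!is.finite(res$loglik))
    stop("cannot sample a history: data impossible under these parameters",
         if (!is.na(res$impossible_node))
           paste0(" (all-zero partial at node ", res$impossible_node, ")")
         else "")
  edge <- enc$tree$edge
  n_tips <- enc$n_tips
  root <- n_tips + 1L
  n_nodes <- 2L * n_tips - 1L
  D <- res$D; F <- res$F
  pi0 <- .root_freq(root_option, nrow(q))

  draw <- function(w) sample.int(length(w), 1L, prob = w)
  node_states <- integer(n_nodes)
  corner_states <- integer(nrow(edge))
  node_states[root] <- draw(pi0 * D[, root])

  # preorder over internal nodes: parents before children
  children_edges <- split(seq_len(nrow(edge)), edge[, 1])
  stack <- root
  while (length(stack)) {
    node <- stack[1L]; stack <- stack[-1L]
    ce <- children_edges[[as.character(node)]]
    i <- node_states[node]
    sel <- which(tensor$parent == i)
    w <- tensor$prob[sel] * F[tensor$left[sel], ce[1L]] *
      F[tensor$right[sel], ce[2L]]
    k <- sel[draw(w)]
    corner_states[ce[1L]] <- tensor$left[k]
    corner_states[ce[2L]] <- tensor$right[k]
    for (e in ce) {
      child <- edge[e, 2L]
      node_states[child] <- draw(res$Pt[corner_states[e], , e] * D[, child])
      if (child > n_tips) stack <- c(stack, child)
    }
  }
  structure(list(node_states = stats::setNames(node_states, seq_len(n_nodes)),
                 corner_states = stats::setNames(corner_states, edge[, 2L])),
            class = "rfbs_history")
}

# location table shared by summaries and truths: internal nodes then corners
.history_locations <- function(history) {
  internal <- as.integer(names(history$node_states)) >
    (length(history$node_states) + 1L) %/% 2L
  data.frame(
    id = c(names(history$node_states)[internal], names(history$corner_states)),
    kind = rep(c("node", "corner"),
               c(sum(internal), length(history$corner_states))),
    stringsAsFactors = FALSE)
}

.history_state_vec <- function(history) {
  internal <- as.integer(names(history$node_states)) >
    (length(history$node_states) + 1L) %/% 2L
  c(history$node_states[internal], history$corner_states)
}

#' Per-biome affinity-type summaries of sampled histories
#'
#' Marginalizes sampled joint histories into, for every location (internal
#' node or branch-start corner) and biome, the posterior probabilities of
#' the three affinity types (non-affinity, enabled, established), which sum
#' to one per location and biome.
#'
#' @param samples list of [sample_history()] results.
#' @param space the state space the histories were sampled over.
#' @return object of class \code{rfbs_ancestral}: list with \code{locations}
#'   (data frame id/kind) and \code{prob}, an array
#'   (location x biome x affinity code 0..2).
#' @export
summarize_histories <- function(samples, space) {
  if (!length(samples)) stop("need at least one sampled history")
  loc <- .history_locations(samples[[1L]])
  states <- vapply(samples, .history_state_vec,
                   integer(nrow(loc)))  # locations x samples
  if (nrow(loc) == 1L) states <- matrix(states, nrow = 1L)
  prob <- array(0, dim = c(nrow(loc), space$n_biomes, 3L),
                dimnames = list(loc$id, space$labels, c("p0", "p1", "p2")))
  for (b in seq_len(space$n_biomes)) {
    code_of_state <- space$codes[, b]
    codes <- matrix(code_of_state[states], nrow = nrow(loc))
    for (a in 0:2) prob[, b, a + 1L] <- rowMeans(codes == a)
  }
  structure(list(locations = loc, prob = prob, n_samples = length(samples)),
            class = "rfbs_ancestral")
}

#' Ancestral affinity accuracy against a known truth
#'
#' For each affinity type a in {0, 1, 2}: the mean posterior probability
#' assigned to a over all (location, biome) cells whose true code is a.
#' Types with no occurrences in the truth are reported as NA (absent), not
#' zero.
#'
#' @param truth integer matrix (location x biome) of true codes, rows
#'   aligned with \code{summary$locations} (e.g. from [history_truth()]).
#' @param summary an [summarize_histories()] result.
#' @param collapse optional named list mapping new group labels to code sets,
#'   e.g. \code{list(established = 2, unestablished = 0:1)}; posterior mass
#'   and truths are pooled within groups before scoring.
#' @return named numeric vector of per-type accuracies in [0, 1].
#' @export
affinity_accuracy <- function(truth, summary, collapse = NULL) {
  if (!all(dim(truth) == dim(summary$prob)[1:2]))
    stop("truth and summary are misaligned")
  if (is.null(collapse))
    collapse <- list(`0` = 0L, `1` = 1L, `2` = 2L)
  out <- stats::setNames(rep(NA_real_, length(collapse)), names(collapse))
  for (g in seq_along(collapse)) {
    codes <- collapse[[g]]
    is_true <- matrix(truth %in% codes, nrow(truth))
    if (!any(is_true)) next
    mass <- apply(summary$prob[, , codes + 1L, drop = FALSE], c(1, 2), sum)
    out[g] <- mean(mass[is_true])
  }
  out
}

#' True codes at history locations
#'
#' Extracts the (location x biome) matrix of true affinity codes from a
#' simulated history, aligned with [summarize_histories()] locations.
#'
#' @param history a true history ([simulate_history()] or [sample_history()]).
#' @param space the state space.
#' @return integer matrix (location x biome).
#' @export
history_truth <- function(history, space) {
  space$codes[.history_state_vec(history), , drop = FALSE]
}

#' Cell-pooled ancestral accuracy
#'
#' The mean posterior probability assigned to the true affinity over all
#' (location, biome) cells — the type-frequency-weighted average of the
#' per-type accuracies from [affinity_accuracy()].
#'
#' @inheritParams affinity_accuracy
#' @return a single value in [0, 1].
#' @export
pooled_accuracy <- function(truth, summary) {
  if (!all(dim(truth) == dim(summary$prob)[1:2]))
    stop("truth and summary are misaligned")
  idx <- cbind(rep(seq_len(nrow(truth)), ncol(truth)),
               rep(seq_len(ncol(truth)), each = nrow(truth)),
               as.vector(truth) + 1L)
  mean(summary$prob[idx])
}

#' Chance-level (null) baseline for ancestral accuracy
#'
#' The mean posterior probability assigned to each affinity type, pooled
#' over all locations, biomes, and replicate posteriors: the probability of
#' sampling an affinity of that type by chance, against which
#' [affinity_accuracy()] is compared. Uniform posteriors give 1/3 per type
#' under the full model and 1/2 under the binary baseline.
#'
#' @param summaries list of [summarize_histories()] results (>= 1 replicate).
#' @param collapse as in [affinity_accuracy()].
#' @return named numeric vector of per-type chance probabilities.
#' @export
null_baseline <- function(summaries, collapse = NULL) {
  if (is.null(collapse))
    collapse <- list(`0` = 0L, `1` = 1L, `2` = 2L)
  out <- stats::setNames(rep(NA_real_, length(collapse)), names(collapse))
  for (g in seq_along(collapse)) {
    codes <- collapse[[g]]
    out[g] <- mean(vapply(summaries, function(s)
      mean(apply(s$prob[, , codes + 1L, drop = FALSE], c(1, 2), sum)), 0))
  }
  out
}

#' Write an ancestral summary as TSV
#'
#' One row per (location, biome) with the three affinity-type probabilities.
#'
#' @param summary an [summarize_histories()] result.
#' @param space the state space.
#' @param path output file.
#' @export
write_ancestral <- function(summary, space, path) {
  loc <- summary$locations
  rows <- do.call(rbind, lapply(seq_len(space$n_biomes), function(b)
    data.frame(location = loc$id, kind = loc$kind, biome = space$labels[b],
               p0 = summary$prob[, b, 1L], p1 = summary$prob[, b, 2L],
               p2 = summary$prob[, b, 3L])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
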