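#' Validate and encode a phylogeny for pruning
#'
#' @param tree an \code{ape::phylo}; must be rooted, strictly binary, with
#'   finite non-negative branch lengths.
#' @param species tip-data species names; must match the tip labels 1:1.
#' @return list with the tree, its postorder edge ordering, and the tip
#'   permutation mapping data columns onto tip numbers.
#' @keywords internal
encode_tree <- function(tree, species = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tab <- tabulate(tree$edge[, 1])
  if (any(tab > 2)) {
    bad <- which(tab > 2)[1]
    stop("tree is not binary: node ", bad, " has ", tab[bad], " children")
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree is not strictly binary")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  perm <- NULL
  if (!is.null(species)) {
    perm <- match(tree$tip.label, species)
    if (anyNA(perm) || length(species) != length(tree$tip.label))
      stop("tip data species do not match tree tip labels")
  }
  list(tree = tree, postorder = as.integer(po), perm = perm,
       n_tips = length(tree$tip.label))
}

.root_freq <- function(root_option, S) {
  if (is.null(root_option) || identical(root_option, "uniform"))
    return(rep(1 / S, S))
  if (!is.numeric(root_option) || length(root_option) != S ||
      any(root_option < 0) || abs(sum(root_option) - 1) > 1e-8)
    stop("root_option must be \"uniform\" or a probability vector over states")
  as.numeric(root_option)
}

#' Phylogenetic log-likelihood by pruning with cladogenetic transitions
#'
#' Felsenstein pruning generalized with a cladogenetic combine: tip partials
#' are the 0/1 ambiguity masks; along each branch partials are propagated by
#' \eqn{e^{Qt}}; at each internal node (and at the root) the two branch
#' partials are combined through the sparse cladogenetic tensor; the root
#' vector is dotted with the root state frequencies. Works for any
#' (state space, generator, tensor) triple, so the presence/absence baseline
#' reuses it.
#'
#' @param tree an \code{ape::phylo}, rooted and binary with branch lengths.
#' @param tip_masks S x n_tips matrix of 0/1 indicators (see
#'   [mask_matrix()]), columns named by species.
#' @param q rate matrix from [build_q()] / [build_dec_q()].
#' @param tensor tensor from [build_clado_tensor()].
#' @param root_option "uniform" (default) or a probability vector.
#' @param rescale rescale partials at every node (recommended; identical
#'   result up to rounding).
#' @return the log-likelihood (natural log); \code{-Inf} with attribute
#'   \code{"impossible_node"} if the data are impossible under the model.
#' @export
prune_loglik <- function(tree, tip_masks, q, tensor, root_option = "uniform",
                         rescale = TRUE) {
  enc <- encode_tree(tree, colnames(tip_masks))
  res <- .prune_call(enc, tip_masks, q, tensor, root_option, rescale, FALSE)
  ll <- res$loglik
  if (!is.na(res$impossible_node) && is.infinite(ll))
    attr(ll, "impossible_node") <- res$impossible_node
  ll
}

# shared low-level call; enc from encode_tree (perm set when colnames given)
.prune_call <- function(enc, tip_masks, q, tensor, root_option, rescale,
                        return_partials) {
  tm <- if (is.null(enc$perm)) tip_masks else tip_masks[, enc$perm, drop = FALSE]
  storage.mode(tm) <- "double"
  cpp_prune(q, enc$tree$edge, enc$tree$edge.length, enc$postorder, tm,
            tensor$parent, tensor$left, tensor$right, tensor$prob,
            .root_freq(root_option, nrow(q)), enc$n_tips,
            rescale, return_partials)
}
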