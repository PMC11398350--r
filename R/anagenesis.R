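#' Anagenetic event rates
#'
#' The five rates (events per unit tree height) of affinity change along
#' branches: step-wise gains 0->1 (\code{g01}) and 1->2 (\code{g12}), the
#' lock-step double gain 0->2 (\code{g02}), loss of an established affinity
#' down to enabled 2->1 (\code{l21}), and loss of an enabled affinity 1->0
#' (\code{l10}). Double losses 2->0 are forbidden, as is losing the last
#' established affinity (extinction is not modelled).
#'
#' @param g01,g12,g02,l10,l21 non-negative rates.
#' @return named numeric vector of class \code{rfbs_rates}.
#' @export
anagenetic_rates <- function(g01, g12, g02, l10, l21) {
  r <- c(g01 = g01, g12 = g12, g02 = g02, l10 = l10, l21 = l21)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  structure(r, class = "rfbs_rates")
}

# single-biome events: from-code, to-code, rate name
.rfbs_events <- cbind(from = c(0L, 1L, 0L, 1L, 2L),
                      to   = c(1L, 2L, 2L, 0L, 1L))
.rfbs_event_names <- c("g01", "g12", "g02", "l10", "l21")

# index template for fast generator fills: every allowed (i, j) entry with
# the name of the rate that fills it
.q_template <- function(space) {
  ii <- jj <- integer(0); rr <- character(0)
  for (i in seq_len(space$n_states)) {
    for (b in seq_len(space$n_biomes)) {
      cur <- space$codes[i, b]
      for (e in seq_len(nrow(.rfbs_events))) {
        if (.rfbs_events[e, "from"] != cur) next
        codes <- space$codes[i, ]
        codes[b] <- .rfbs_events[e, "to"]
        j <- state_index(space, codes)
        if (is.na(j)) next
        ii <- c(ii, i); jj <- c(jj, j); rr <- c(rr, .rfbs_event_names[e])
      }
    }
  }
  list(i = ii, j = jj, rate = rr, n_states = space$n_states)
}

.fill_q <- function(template, rates, dn = NULL) {
  S <- template$n_states
  Q <- matrix(0, S, S, dimnames = dn)
  Q[cbind(template$i, template$j)] <- unname(rates[template$rate])
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build the anagenetic rate generator Q
#'
#' Fills, for every ordered pair of states differing at exactly one biome by
#' an allowed event, the corresponding rate; transitions whose destination
#' falls outside the state space (loss of the only established affinity) are
#' absent, and the diagonal is the negative row sum.
#'
#' @param rates an [anagenetic_rates()] vector (or any named vector carrying
#'   g01, g12, g02, l10, l21).
#' @param space an [enumerate_states()] state space.
#' @return S x S rate matrix with state labels as dimnames.
#' @export
build_q <- function(rates, space) {
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and >= 0")
  .fill_q(.q_template(space), rates,
          dn = list(space$state_labels, space$state_labels))
}

#' Finite-time transition probabilities
#'
#' Matrix exponential \eqn{e^{Qt}} computed by scaling-and-squaring
#' (Matrix::expm); rows sum to one.
#'
#' @param q rate matrix from [build_q()] (or the presence/absence analogue).
#' @param t branch length, >= 0 and finite, in tree units.
#' @return stochastic matrix of the same dimension.
#' @export
transition_probs <- function(q, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single finite value >= 0")
  if (t == 0) return(diag(nrow(q)))
  p <- as.matrix(Matrix::expm(q * t))
  dimnames(p) <- dimnames(q)
  p
}

#' Rescale a phylogeny to unit root height
#'
#' Rates are interpreted per unit tree height; this helper divides all branch
#' lengths by the root-to-tip height (maximum root-to-tip distance for
#' non-ultrametric trees).
#'
#' @param tree an \code{ape::phylo}.
#' @return the rescaled tree.
#' @export
rescale_tree_height <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}
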