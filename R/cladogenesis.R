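#' Cladogenetic scenario probabilities
#'
#' At speciation, the parental established-affinity set is passed to the two
#' daughters under one of three scenarios: equal inheritance (both daughters
#' keep the full set, probability \code{pe}), subset inheritance (one
#' daughter keeps the full set, the other a proper non-empty subset,
#' probability \code{ps}), or between-biome split inheritance (the set is
#' divided into two non-empty parts, probability \code{pb}), with
#' \code{pe + ps + pb = 1}. Within a scenario every distinct outcome is
#' equally likely.
#'
#' @param ps,pb probabilities of subset- and split-inheritance; \code{pe} is
#'   \code{1 - ps - pb} and must be non-negative.
#' @return named numeric vector \code{c(pe, ps, pb)} of class
#'   \code{rfbs_clado}.
#' @export
clado_params <- function(ps, pb) {
  pe <- 1 - ps - pb
  p <- c(pe = pe, ps = ps, pb = pb)
  if (any(p < -1e-12) || any(!is.finite(p)))
    stop("ps, pb must be >= 0 with ps + pb <= 1")
  structure(pmax(p, 0), class = "rfbs_clado")
}

#' Count distinct cladogenetic outcomes
#'
#' For a parental state with \code{n_est} established affinities and
#' \code{n_modes} reduction modes (2 in the full model: non-inherited
#' established affinities reduce to enabled or to non-affinity; 1 in the
#' presence/absence baseline, where they simply become absent):
#' one equal outcome; \code{2 * (2^n_est - 2) * n_modes} subset outcomes
#' (which daughter keeps the full set x proper non-empty subset x mode; for
#' two modes this is \eqn{2^{n_est+2} - 8}); and
#' \code{(2^n_est - 2) * n_modes} split outcomes (ordered bipartitions x
#' mode; \eqn{2^{n_est+1} - 4} for two modes). A parent with a single
#' established affinity has only the equal outcome.
#'
#' @param n_est number of established affinities in the parent (>= 1).
#' @param n_modes number of reduction modes (2 for the full model).
#' @return list with \code{n_e}, \code{n_s}, \code{n_b}, \code{n_est}.
#' @export
count_outcomes <- function(n_est, n_modes = 2L) {
  if (length(n_est) != 1L || !is.finite(n_est) || n_est < 1)
    stop("n_est must be a single integer >= 1")
  n_est <- as.integer(n_est)
  if (n_est == 1L) return(list(n_e = 1L, n_s = 0L, n_b = 0L, n_est = n_est))
  base <- 2L^n_est - 2L
  list(n_e = 1L, n_s = 2L * base * as.integer(n_modes),
       n_b = base * as.integer(n_modes), n_est = n_est)
}

# all proper non-empty subsets of an index set, as a list
.proper_subsets <- function(set) {
  n <- length(set)
  out <- list()
  for (k in seq_len(n - 1L)) out <- c(out, utils::combn(set, k, simplify = FALSE))
  out
}

#' Enumerate cladogenetic events for one parental state
#'
#' Applies the inheritance rules: in subset and split events, the established
#' biomes a daughter does not inherit all reduce to the same code (2 -> 1,
#' ecological divergence absent, or 2 -> 0, ecological divergence), one
#' global reduction mode per event; parental enabled-only biomes (code 1)
#' pass unchanged to both daughters. Mirrored left/right outcomes are listed
#' separately. A parent with one established affinity yields the single
#' identical-inheritance event with probability 1 regardless of the
#' scenario probabilities.
#'
#' @param parent integer code vector (a row of \code{space$codes}).
#' @param params a [clado_params()] vector.
#' @param modes codes that non-inherited established biomes may reduce to
#'   (\code{c(1, 0)} for the full model, \code{0} for the binary baseline).
#' @return data frame with list-columns \code{left}, \code{right} (code
#'   vectors) and columns \code{scenario} ("equal", "subset", "split"),
#'   \code{reduction} ("to_enabled", "to_non_affinity", "not_applicable"),
#'   \code{probability}.
#' @export
enumerate_clado_events <- function(parent, params, modes = c(1L, 0L)) {
  est <- which(parent == 2L)
  n <- length(est)
  if (n < 1L) stop("parental state must have at least one established affinity")
  cnt <- count_outcomes(n, length(modes))
  red_name <- function(m) if (m == 1L) "to_enabled" else "to_non_affinity"
  ev <- list(list(left = parent, right = parent, scenario = "equal",
                  reduction = "not_applicable",
                  probability = if (n == 1L) 1 else unname(params["pe"]) / cnt$n_e))
  if (n >= 2L) {
    reduce <- function(keep, mode) {
      d <- parent
      d[setdiff(est, keep)] <- mode
      d
    }
    for (sub in .proper_subsets(est)) {
      for (m in modes) {
        d <- reduce(sub, m)
        w <- unname(params["ps"]) / cnt$n_s
        ev <- c(ev,
                list(list(left = parent, right = d, scenario = "subset",
                          reduction = red_name(m), probability = w),
                     list(left = d, right = parent, scenario = "subset",
                          reduction = red_name(m), probability = w)))
      }
    }
    for (sub in .proper_subsets(est)) {  # ordered bipartitions (A, est \ A)
      for (m in modes) {
        ev <- c(ev, list(list(left = reduce(sub, m),
                              right = reduce(setdiff(est, sub), m),
                              scenario = "split", reduction = red_name(m),
                              probability = unname(params["pb"]) / cnt$n_b)))
      }
    }
  }
  data.frame(left = I(lapply(ev, `[[`, "left")),
             right = I(lapply(ev, `[[`, "right")),
             scenario = vapply(ev, `[[`, "", "scenario"),
             reduction = vapply(ev, `[[`, "", "reduction"),
             probability = vapply(ev, `[[`, 0, "probability"))
}

#' Cladogenetic outcome structure of a state space
#'
#' The parameter-free part of the cladogenetic tensor: every
#' (parent, left, right) triple with its scenario and within-scenario
#' divisor. Probabilities for given scenario weights are filled in by
#' [clado_tensor_probs()]; [build_clado_tensor()] does both.
#'
#' @param space a state space ([enumerate_states()] or [build_dec_space()]).
#' @param modes reduction modes, see [enumerate_clado_events()].
#' @return list of class \code{rfbs_clado_struct} with integer vectors
#'   \code{parent}, \code{left}, \code{right}, \code{scenario} (1 = equal,
#'   2 = subset, 3 = split), \code{denom}, and \code{forced} (logical:
#'   single-established parent, probability fixed at 1).
#' @export
clado_structure <- function(space, modes = c(1L, 0L)) {
  dummy <- clado_params(1 / 3, 1 / 3)
  parent <- left <- right <- scen <- denom <- integer(0)
  forced <- logical(0)
  scen_id <- c(equal = 1L, subset = 2L, split = 3L)
  for (i in seq_len(space$n_states)) {
    n <- sum(space$codes[i, ] == 2L)
    cnt <- count_outcomes(n, length(modes))
    evs <- enumerate_clado_events(space$codes[i, ], dummy, modes)
    l <- vapply(evs$left, function(c) state_index(space, c), 0L)
    r <- vapply(evs$right, function(c) state_index(space, c), 0L)
    if (anyNA(l) || anyNA(r))
      stop("cladogenetic daughter outside the state space (parent ",
           space$state_labels[i], ")")
    s <- scen_id[evs$scenario]
    parent <- c(parent, rep(i, nrow(evs)))
    left <- c(left, l); right <- c(right, r); scen <- c(scen, s)
    denom <- c(denom, c(cnt$n_e, cnt$n_s, cnt$n_b)[s])
    forced <- c(forced, rep(n == 1L, nrow(evs)))
  }
  structure(list(parent = parent, left = left, right = right,
                 scenario = unname(scen), denom = denom, forced = forced,
                 n_states = space$n_states),
            class = "rfbs_clado_struct")
}

#' Fill cladogenetic probabilities for given scenario weights
#'
#' @param struct a [clado_structure()].
#' @param params a [clado_params()] vector.
#' @return numeric vector of probabilities aligned with the structure rows.
#' @export
clado_tensor_probs <- function(struct, params) {
  w <- unname(c(params["pe"], params["ps"], params["pb"]))[struct$scenario] /
    struct$denom
  w[struct$forced] <- 1
  w
}

#' Build the cladogenetic probability tensor
#'
#' Sparse representation of the three-dimensional matrix P: for each parental
#' state, the (left daughter, right daughter, probability) triples. Per
#' parent the probabilities sum to one and the tensor is symmetric under
#' daughter exchange.
#'
#' @inheritParams clado_structure
#' @param params a [clado_params()] vector.
#' @return list of class \code{rfbs_clado_tensor}: the structure fields plus
#'   \code{prob}.
#' @export
build_clado_tensor <- function(space, params, modes = c(1L, 0L)) {
  struct <- clado_structure(space, modes)
  tensor <- c(struct, list(prob = clado_tensor_probs(struct, params)))
  class(tensor) <- "rfbs_clado_tensor"
  sums <- tapply(tensor$prob, tensor$parent, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("internal error: cladogenetic probabilities do not normalize")
  tensor
}

#' Tensor slice for one parent as a dense matrix
#'
#' @param tensor a [build_clado_tensor()] result.
#' @param parent parent state index.
#' @param space the state space (for dimnames).
#' @return S x S matrix of daughter-pair probabilities (rows = left).
#' @export
clado_slice <- function(tensor, parent, space) {
  S <- space$n_states
  m <- matrix(0, S, S, dimnames = list(space$state_labels, space$state_labels))
  sel <- tensor$parent == parent
  for (k in which(sel)) m[tensor$left[k], tensor$right[k]] <-
      m[tensor$left[k], tensor$right[k]] + tensor$prob[k]
  m
}
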