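#' Multiplier proposal
#'
#' The standard univariate multiplier move: \eqn{x' = x e^{\lambda u}} with
#' \eqn{u \sim} Uniform(-0.5, 0.5) and tuning parameter \eqn{\lambda}. The
#' log Hastings correction is \eqn{\log(x'/x) = \lambda u}.
#'
#' @param x current value, > 0.
#' @param lambda tuning parameter controlling the proposal magnitude.
#' @return list with \code{x} (the proposed value) and \code{log_hastings}.
#' @export
multiplier_propose <- function(x, lambda) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop("multiplier proposal requires x > 0")
  u <- stats::runif(1, -0.5, 0.5)
  list(x = x * exp(lambda * u), log_hastings = lambda * u)
}

#' MCMC run configuration
#'
#' @param iterations number of MCMC iterations (one full sweep over all free
#'   parameters per iteration).
#' @param thin record every \code{thin}-th iteration.
#' @param burn_in fraction of iterations discarded before summaries, in
#'   [0, 1).
#' @param lambda_rates multiplier tuning for the anagenetic rates
#'   (default 1.5).
#' @param lambda_clado multiplier tuning for the cladogenetic probabilities
#'   (default 0.2).
#' @param seed integer RNG seed.
#' @param ancestral_every sample a joint ancestral history every this many
#'   post-burn-in iterations (0 disables sampling).
#' @return list of class \code{rfbs_mcmc_config}.
#' @export
mcmc_config <- function(iterations, thin = 1L, burn_in = 0.1,
                        lambda_rates = 1.5, lambda_clado = 0.2,
                        seed = 1L, ancestral_every = 0L) {
  iterations <- as.integer(iterations); thin <- as.integer(thin)
  if (iterations < thin || thin < 1L) stop("need iterations >= thin >= 1")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must lie in [0, 1)")
  if (lambda_rates <= 0 || lambda_clado <= 0) stop("tunings must be > 0")
  structure(list(iterations = iterations, thin = thin, burn_in = burn_in,
                 lambda_rates = lambda_rates, lambda_clado = lambda_clado,
                 seed = as.integer(seed),
                 ancestral_every = as.integer(ancestral_every)),
            class = "rfbs_mcmc_config")
}

.log_prior <- function(rates, ps, pb, beta) {
  if (ps <= 0 || ps >= 1 || pb <= 0 || pb >= 1 || ps + pb > 1) return(-Inf)
  sum(stats::dexp(rates, rate = 1 / beta, log = TRUE))
}

#' Bayesian MCMC over rates and cladogenetic probabilities
#'
#' Metropolis-Hastings with single-parameter multiplier proposals, swept in a
#' fixed order each iteration: the anagenetic rates (exponential prior with
#' scale \code{prior_beta}), then \code{ps} and \code{pb} (uniform on (0,1)
#' with \code{pe = 1 - ps - pb}; proposals leaving the simplex are rejected
#' through the zero prior). The generator and tensor are rebuilt on accepted
#' moves only.
#'
#' @param tree rooted binary \code{ape::phylo} with branch lengths.
#' @param tip_masks S x n_tips 0/1 matrix, columns named by species
#'   ([mask_matrix()]).
#' @param model an [rfbs_model()] or [dec_model()].
#' @param prior_beta scale of the exponential rate prior, in events per unit
#'   tree height.
#' @param config an [mcmc_config()].
#' @param root_option root state frequencies ("uniform" or a vector).
#' @return object of class \code{rfbs_mcmc}: \code{trace} (matrix with
#'   columns iteration, the rates, ps, pb, pe, loglik, logprior),
#'   \code{acceptance} (per-parameter acceptance rates), \code{histories}
#'   (list of sampled ancestral histories, if requested), plus the
#'   configuration, prior, and model metadata.
#' @export
run_mcmc <- function(tree, tip_masks, model, prior_beta = 1, config,
                     root_option = "uniform") {
  set.seed(config$seed)
  enc <- encode_tree(tree, colnames(tip_masks))
  if (!is.null(enc$perm)) {  # permute once; avoids per-call subsetting
    tip_masks <- tip_masks[, enc$perm, drop = FALSE]
    enc$perm <- NULL
  }
  storage.mode(tip_masks) <- "double"
  nr <- length(model$rate_names)
  rates <- stats::rexp(nr, rate = 1 / prior_beta)
  names(rates) <- model$rate_names
  tmpl <- model$q_template
  struct <- model$struct
  burn_iter <- floor(config$burn_in * config$iterations)
  rate_id <- match(tmpl$rate, model$rate_names)
  root_freq <- .root_freq(root_option, model$space$n_states)

  res <- cpp_mcmc(tmpl$i, tmpl$j, rate_id, unname(rates), 1 / 3, 1 / 3,
                  struct$parent, struct$left, struct$right, struct$scenario,
                  as.numeric(struct$denom), struct$forced,
                  enc$tree$edge, enc$tree$edge.length, enc$postorder,
                  tip_masks, root_freq, enc$n_tips, prior_beta,
                  config$iterations, config$thin, config$lambda_rates,
                  config$lambda_clado, burn_iter, config$ancestral_every)
  if (!is.null(res$error))
    stop(res$error, "; check that tip masks are non-empty and match the tree")
  par_names <- c(model$rate_names, "ps", "pb")
  colnames(res$trace) <- c("iteration", par_names, "pe", "loglik", "logprior")

  # histories are drawn after the sweep, conditional on the parameter values
  # the chain held at the sampling iterations (joint posterior samples)
  histories <- list()
  if (config$ancestral_every > 0L && nrow(res$snapshots)) {
    for (s in seq_len(nrow(res$snapshots))) {
      th <- res$snapshots[s, ]
      q <- model$build_q(stats::setNames(th[seq_len(nr)], model$rate_names))
      tensor <- c(struct, list(prob = clado_tensor_probs(
        struct, clado_params(th[nr + 1L], th[nr + 2L]))))
      histories[[s]] <- sample_history(enc, tip_masks, q, tensor, root_option)
    }
  }

  structure(list(trace = res$trace,
                 acceptance = stats::setNames(
                   as.numeric(res$accept) / config$iterations, par_names),
                 histories = histories, config = config,
                 prior_beta = prior_beta, model_kind = model$kind,
                 rate_names = model$rate_names, burn_iter = burn_iter,
                 n_tips = enc$n_tips),
            class = "rfbs_mcmc")
}

#' Post-burn-in samples from a fitted chain
#'
#' @param fit an [run_mcmc()] result.
#' @return the trace matrix restricted to iterations after burn-in.
#' @export
trace_samples <- function(fit) {
  fit$trace[fit$trace[, "iteration"] > fit$burn_iter, , drop = FALSE]
}

#' @export
print.rfbs_mcmc <- function(x, ...) {
  cat(sprintf("%s MCMC: %d iterations (thin %d, burn-in %d), %d tips\n",
              toupper(x$model_kind), x$config$iterations, x$config$thin,
              x$burn_iter, x$n_tips))
  s <- trace_samples(x)
  pars <- c(x$rate_names, "ps", "pb", "pe")
  cat("posterior means:\n")
  print(round(colMeans(s[, pars, drop = FALSE]), 4))
  cat("acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted samples containing
#' \code{ceiling(mass * n)} samples; ties broken by the lowest start.
#'
#' @param samples numeric vector of posterior samples (>= 2).
#' @param mass interval mass in (0, 1].
#' @return numeric vector \code{c(lower, upper)}.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1L], s[n]))
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1L])
}

#' Effective sample size of an MCMC trace
#'
#' \eqn{n / (1 + 2 \sum_k \rho_k)} with the autocorrelation sum truncated by
#' the initial-positive-sequence rule: lags are added in consecutive pairs
#' \eqn{(\rho_{2t-1} + \rho_{2t})} until the first pair with a non-positive
#' sum. The estimate is capped at \code{n} (and floored at 1).
#'
#' @param samples numeric vector, length >= 10, non-constant.
#' @return the effective sample size.
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::var(samples) == 0) stop("degenerate input: constant series")
  lag_max <- min(n - 1L, 1000L)
  rho <- as.numeric(stats::acf(samples, lag.max = lag_max,
                               plot = FALSE)$acf)[-1L]
  acsum <- 0
  t <- 1L
  while (2L * t <= length(rho)) {
    pair <- rho[2L * t - 1L] + rho[2L * t]
    if (pair <= 0) break
    acsum <- acsum + pair
    t <- t + 1L
  }
  min(max(n / (1 + 2 * acsum), 1), n)
}
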