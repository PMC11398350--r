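#' Draw model parameters from the prior
#'
#' Rates are Exponential(\code{beta}); \code{ps} and \code{pb} are
#' Uniform(0, 1) with \code{pe = 1 - ps - pb}, redrawn until the simplex
#' constraint holds.
#'
#' @param model an [rfbs_model()] / [dec_model()].
#' @param beta exponential prior scale.
#' @return list with \code{rates} (named) and \code{clado}
#'   ([clado_params()]).
#' @export
draw_prior_params <- function(model, beta) {
  rates <- stats::setNames(
    stats::rexp(length(model$rate_names), rate = 1 / beta),
    model$rate_names)
  repeat {
    ps <- stats::runif(1); pb <- stats::runif(1)
    if (ps + pb <= 1) break
  }
  list(rates = rates, clado = clado_params(ps, pb))
}

#' Simulate one replicate dataset under the model
#'
#' Draws generating parameters from the prior, simulates a unit-height
#' pure-birth tree and a character history on it.
#'
#' @param model an [rfbs_model()].
#' @param n_tips tree size.
#' @param beta prior scale for the generating rates.
#' @return list with \code{tree}, \code{truth} (the true history),
#'   \code{params}, \code{q}, \code{tensor}.
#' @export
simulate_replicate <- function(model, n_tips, beta) {
  params <- draw_prior_params(model, beta)
  q <- model$build_q(params$rates)
  tensor <- c(model$struct,
              list(prob = clado_tensor_probs(model$struct, params$clado)))
  tree <- simulate_tree(n_tips)
  truth <- simulate_history(tree, q, tensor, model$space)
  list(tree = tree, truth = truth, params = params, q = q, tensor = tensor)
}

.free_params <- function(fit) c(fit$rate_names, "ps", "pb")

# per-parameter HPD coverage / ESS / error table for one fitted chain
.param_table <- function(fit, truth_vec, mass = 0.95) {
  s <- trace_samples(fit)
  do.call(rbind, lapply(.free_params(fit), function(p) {
    x <- s[, p]
    h <- hpd_interval(x, mass)
    data.frame(param = p, truth = unname(truth_vec[p]),
               post_mean = mean(x), post_median = stats::median(x),
               hpd_lo = h[1], hpd_hi = h[2],
               covered = truth_vec[p] >= h[1] & truth_vec[p] <= h[2],
               ess = effective_sample_size(x),
               abs_error = abs(stats::median(x) - truth_vec[p]),
               row.names = NULL)
  }))
}

.truth_vec <- function(params)
  c(params$rates, ps = unname(params$clado["ps"]),
    pb = unname(params$clado["pb"]))

#' HPD coverage experiment
#'
#' Simulates replicate datasets with generating parameters drawn from the
#' prior, fits the model by MCMC to entirely confirmed tip data, and records
#' for every free parameter whether the generating value falls inside the
#' 95\% HPD, together with the chain's effective sample size. Under a
#' correctly calibrated sampler the per-parameter coverage is binomial with
#' the nominal mass.
#'
#' @param n_reps number of replicates.
#' @param n_tips tips per simulated tree.
#' @param n_biomes number of biomes.
#' @param beta exponential prior scale (used both to generate and to fit).
#' @param iterations,thin MCMC length and thinning.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param mass HPD mass.
#' @return data frame with one row per (replicate, parameter).
#' @export
run_coverage_experiment <- function(n_reps, n_tips, n_biomes = 2, beta = 0.5,
                                    iterations = 4000, thin = 2, seed = 1,
                                    mass = 0.95) {
  model <- rfbs_model(enumerate_states(n_biomes))
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    set.seed(seed + r)
    rep_data <- simulate_replicate(model, n_tips, beta)
    masks <- mask_tips(rep_data$truth$tip_states, model$space,
                       resolve_fraction = 1, tip_fraction = 1)
    fit <- run_mcmc(rep_data$tree, masks, model, prior_beta = beta,
                    mcmc_config(iterations, thin, seed = seed + r))
    cbind(rep = r, .param_table(fit, .truth_vec(rep_data$params), mass))
  }))
}

#' Ambiguity / ancestral-accuracy / baseline-comparison battery
#'
#' One set of simulated replicates shared across tip-coding treatments, so
#' treatment contrasts are paired. For each replicate (generating parameters
#' from the prior, a fresh tree and history), the full model is fitted under
#' each treatment; ancestral histories are sampled during the MCMC and
#' scored against the true history per affinity type. The presence/absence
#' baseline is fitted once per replicate to the recoded (established-only)
#' data and scored on the collapsed established/unestablished truth.
#'
#' @param n_reps number of replicates.
#' @param n_tips tips per tree.
#' @param n_biomes number of biomes.
#' @param beta prior scale (the ambiguity experiment uses 1.0).
#' @param treatments named list of c(resolve_fraction, tip_fraction) pairs.
#' @param iterations,thin MCMC length and thinning.
#' @param ancestral_every history-sampling cadence (post-burn-in iterations);
#'   0 disables ancestral sampling and scoring (rate-error-only designs).
#' @param with_dec also fit the presence/absence baseline to recoded data.
#' @param seed base seed.
#' @return list with \code{params} (per replicate x treatment x parameter:
#'   coverage, error, ESS), \code{accuracy} (per replicate x model/treatment
#'   x affinity type), and \code{null} (chance baselines pooled across
#'   replicates, per model/treatment and type).
#' @export
run_accuracy_experiment <- function(n_reps, n_tips, n_biomes = 2, beta = 1.0,
                                    treatments = list(
                                      confirmed = c(1, 1),
                                      partial = c(2 / 3, 0.75),
                                      ambiguous = c(0, 1)),
                                    iterations = 2000, thin = 2,
                                    ancestral_every = 25, with_dec = TRUE,
                                    seed = 1) {
  model <- rfbs_model(enumerate_states(n_biomes))
  dspace <- build_dec_space(n_biomes)
  dmodel <- dec_model(dspace)
  est_collapse <- list(established = 2L, unestablished = 0:1)
  param_rows <- acc_rows <- list()
  summaries <- list()  # keyed by scoring label, list of per-rep summaries
  truths <- list()

  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    rep_data <- simulate_replicate(model, n_tips, beta)
    truth_vec <- .truth_vec(rep_data$params)
    truth_codes <- history_truth(rep_data$truth, model$space)
    for (tr in names(treatments)) {
      masks <- mask_tips(rep_data$truth$tip_states, model$space,
                         resolve_fraction = treatments[[tr]][1],
                         tip_fraction = treatments[[tr]][2])
      fit <- run_mcmc(rep_data$tree, masks, model, prior_beta = beta,
                      mcmc_config(iterations, thin, seed = seed + r,
                                  ancestral_every = ancestral_every))
      param_rows[[length(param_rows) + 1L]] <-
        cbind(rep = r, treatment = tr, .param_table(fit, truth_vec))
      if (ancestral_every > 0) {
        summ <- summarize_histories(fit$histories, model$space)
        key <- paste0("rfbs_", tr)
        summaries[[key]] <- c(summaries[[key]], list(summ))
        truths[[key]] <- c(truths[[key]], list(truth_codes))
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          rep = r, model = key,
          type = c("0", "1", "2", "established", "unestablished", "overall"),
          accuracy = c(affinity_accuracy(truth_codes, summ),
                       affinity_accuracy(truth_codes, summ, est_collapse),
                       pooled_accuracy(truth_codes, summ)),
          row.names = NULL)
      }
    }
    if (with_dec && ancestral_every > 0) {
      dec_masks <- recode_dec(rep_data$truth$tip_states, model$space, dspace)
      dec_fit <- run_mcmc(rep_data$tree, dec_masks, dmodel, prior_beta = beta,
                          mcmc_config(iterations, thin, seed = seed + r,
                                      ancestral_every = ancestral_every))
      dec_summ <- summarize_histories(dec_fit$histories, dspace)
      dec_truth <- matrix(ifelse(truth_codes == 2L, 2L, 0L),
                          nrow(truth_codes))
      summaries[["dec"]] <- c(summaries[["dec"]], list(dec_summ))
      truths[["dec"]] <- c(truths[["dec"]], list(dec_truth))
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        rep = r, model = "dec",
        type = c("established", "unestablished", "overall"),
        accuracy = c(unname(affinity_accuracy(dec_truth, dec_summ,
                                              est_collapse)),
                     pooled_accuracy(dec_truth, dec_summ)),
        row.names = NULL)
    }
  }

  null_rows <- do.call(rbind, lapply(names(summaries), function(key) {
    coll <- if (key == "dec") est_collapse
            else c(list(`0` = 0L, `1` = 1L, `2` = 2L), est_collapse)
    nb <- null_baseline(summaries[[key]], coll)
    data.frame(model = key, type = names(nb), null = unname(nb),
               row.names = NULL)
  }))
  list(params = do.call(rbind, param_rows),
       accuracy = do.call(rbind, acc_rows),
       null = null_rows)
}

#' Run a named validation experiment
#'
#' Dispatcher over the package's validation designs: \code{"coverage"}
#' (HPD calibration, [run_coverage_experiment()]), \code{"ambiguity"} and
#' \code{"accuracy"} (both served by the shared battery
#' [run_accuracy_experiment()], which records per-treatment parameter error
#' and ancestral accuracy with null baselines).
#'
#' @param kind one of "coverage", "ambiguity", "accuracy".
#' @param ... passed to the underlying driver.
#' @return the driver's result.
#' @export
run_experiment <- function(kind = c("coverage", "ambiguity", "accuracy"),
                           ...) {
  kind <- match.arg(kind)
  if (kind == "coverage") run_coverage_experiment(...)
  else run_accuracy_experiment(...)
}
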