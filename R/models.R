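#' Model objects tying together state space, generator, and tensor
#'
#' A model bundles the state space, the names of its free anagenetic rates,
#' a generator builder, and the parameter-free cladogenetic outcome
#' structure. The MCMC engine and the ancestral sampler are generic over
#' this bundle, so the full affinity model and the presence/absence baseline
#' share all machinery.
#'
#' @param space a state space from [enumerate_states()].
#' @return list of class \code{rfbs_model} with elements \code{kind},
#'   \code{space}, \code{rate_names}, \code{build_q} (function from a named
#'   rate vector to a generator), and \code{struct}
#'   (a [clado_structure()]).
#' @export
rfbs_model <- function(space) {
  if (!identical(space$kind, "rfbs"))
    stop("rfbs_model() needs a space from enumerate_states()")
  tmpl <- .q_template(space)
  structure(list(kind = "rfbs", space = space,
                 rate_names = c("g01", "g12", "g02", "l10", "l21"),
                 build_q = function(rates) .fill_q(tmpl, rates),
                 q_template = tmpl,
                 struct = clado_structure(space, modes = c(1L, 0L))),
            class = "rfbs_model")
}

#' @rdname rfbs_model
#' @param dec_space a space from [build_dec_space()].
#' @export
dec_model <- function(dec_space) {
  if (!identical(dec_space$kind, "dec"))
    stop("dec_model() needs a space from build_dec_space()")
  tmpl <- .dec_template(dec_space)
  structure(list(kind = "dec", space = dec_space,
                 rate_names = c("gain", "loss"),
                 build_q = function(rates) .fill_q(tmpl, rates),
                 q_template = tmpl,
                 struct = clado_structure(dec_space, modes = 0L)),
            class = "rfbs_model")
}
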