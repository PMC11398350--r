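# shared fixtures: small spaces, random parameters, tiny trees

space2 <- enumerate_states(2, c("H", "C"))
space3 <- enumerate_states(3, c("T", "W", "C"))

random_rates <- function() {
  anagenetic_rates(stats::runif(1, 0.1, 2), stats::runif(1, 0.1, 2),
                   stats::runif(1, 0.1, 2), stats::runif(1, 0.1, 2),
                   stats::runif(1, 0.1, 2))
}

random_clado <- function() {
  repeat {
    ps <- stats::runif(1, 0.05, 0.9)
    pb <- stats::runif(1, 0.05, 0.9)
    if (ps + pb < 0.98) return(clado_params(ps, pb))
  }
}

tree3 <- ape::read.tree(text = "((A:0.4,B:0.6):0.5,C:1.1);")
tree4_bal <- ape::read.tree(text = "((A:0.3,B:0.5):0.7,(C:0.6,D:0.2):0.4);")
tree4_cat <- ape::read.tree(text = "(((A:0.2,B:0.4):0.3,C:0.8):0.5,D:1.2);")

random_masks <- function(space, tips) {
  m <- matrix(0L, space$n_states, length(tips), dimnames = list(NULL, tips))
  for (i in seq_along(tips)) {
    k <- sample.int(space$n_states, sample(1:3, 1))
    m[k, i] <- 1L
  }
  m
}

# mean and autocorrelation-aware Monte Carlo standard error of a chain
mc_se <- function(x) stats::sd(x) / sqrt(effective_sample_size(x))
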