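#' Presence/absence (DEC-like) baseline state space
#'
#' Binary biome occupancy over non-empty biome subsets: 2^B - 1 states. For
#' uniformity with the full model, presence is stored as code 2 and absence
#' as code 0, so labels, summaries and accuracy machinery apply unchanged
#' (state labels are the uppercase initials of the occupied biomes).
#'
#' @param n_biomes number of biomes (>= 1).
#' @param labels optional biome names with distinct first letters.
#' @return an \code{rfbs_space} with \code{kind = "dec"}.
#' @export
build_dec_space <- function(n_biomes, labels = NULL) {
  space <- enumerate_states(n_biomes, labels)
  keep <- rowSums(space$codes == 1L) == 0L
  space$codes <- space$codes[keep, , drop = FALSE]
  space$digits <- space$digits[keep]
  space$state_labels <- space$state_labels[keep]
  space$n_states <- sum(keep)
  space$kind <- "dec"
  space
}

#' Anagenetic generator for the presence/absence baseline
#'
#' Single-biome gains at rate \code{gain} and losses at rate \code{loss};
#' losing the last occupied biome is forbidden (the destination lies outside
#' the state space).
#'
#' @param rates named vector with elements \code{gain} and \code{loss}.
#' @param dec_space a [build_dec_space()] space.
#' @return S x S rate matrix.
#' @export
build_dec_q <- function(rates, dec_space) {
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and >= 0")
  .fill_q(.dec_template(dec_space), rates,
          dn = list(dec_space$state_labels, dec_space$state_labels))
}

.dec_template <- function(dec_space) {
  ii <- jj <- integer(0); rr <- character(0)
  for (i in seq_len(dec_space$n_states)) {
    for (b in seq_len(dec_space$n_biomes)) {
      codes <- dec_space$codes[i, ]
      codes[b] <- if (codes[b] == 0L) 2L else 0L
      j <- state_index(dec_space, codes)
      if (is.na(j)) next
      ii <- c(ii, i); jj <- c(jj, j)
      rr <- c(rr, if (dec_space$codes[i, b] == 0L) "gain" else "loss")
    }
  }
  list(i = ii, j = jj, rate = rr, n_states = dec_space$n_states)
}

#' Cladogenetic tensor for the presence/absence baseline
#'
#' Mirrors the three inheritance scenarios on occupancy sets: equal
#' (probability \code{pe}), subset (one daughter keeps the full set, the
#' other a proper non-empty subset; \code{2 (2^n - 2)} outcomes sharing
#' \code{ps}), and split (ordered bipartitions into non-empty parts;
#' \code{2^n - 2} outcomes sharing \code{pb}). Biomes a daughter does not
#' inherit simply become absent (a single reduction mode). Singleton parents
#' inherit identically with probability 1.
#'
#' @param dec_space a [build_dec_space()] space.
#' @param params a [clado_params()] vector.
#' @return an \code{rfbs_clado_tensor}.
#' @export
build_dec_clado <- function(dec_space, params) {
  build_clado_tensor(dec_space, params, modes = 0L)
}
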