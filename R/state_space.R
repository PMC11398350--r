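#' Enumerate the biome-affinity state space
#'
#' A species carries, for each of \code{n_biomes} biomes, one of three
#' affinity codes: 0 (non-affinity), 1 (enabled affinity: the biome lies in
#' the species' fundamental niche but is unoccupied), or 2 (established
#' affinity: the biome is occupied). Every extant species must hold at least
#' one established affinity, so the valid state space holds
#' \eqn{3^B - 2^B} states (5 for two biomes, 19 for three).
#'
#' States are ordered lexicographically by their digit strings (for two
#' biomes: 02, 12, 20, 21, 22). The ordering is an internal convention; all
#' results are reported through labels and index maps.
#'
#' @param n_biomes number of biomes (>= 1).
#' @param labels optional character vector of biome names; their first
#'   letters must be distinct (they form the state labels). Defaults to
#'   \code{LETTERS[1:n_biomes]}.
#' @return an object of class \code{rfbs_space}: a list with elements
#'   \code{n_biomes}, \code{labels}, \code{codes} (an S x B integer matrix of
#'   affinity codes), \code{digits} (digit strings, e.g. "210"),
#'   \code{state_labels} (letter labels, e.g. "Tw"), and \code{n_states}.
#' @examples
#' sp <- enumerate_states(2, c("H", "C"))
#' sp$state_labels  # "C" "hC" "H" "Hc" "HC"
#' @export
enumerate_states <- function(n_biomes, labels = NULL) {
  if (length(n_biomes) != 1L || !is.finite(n_biomes) || n_biomes < 1)
    stop("n_biomes must be a single integer >= 1")
  n_biomes <- as.integer(n_biomes)
  if (is.null(labels)) labels <- LETTERS[seq_len(n_biomes)]
  if (length(labels) != n_biomes)
    stop("labels must have length n_biomes")
  if (anyDuplicated(toupper(substr(labels, 1, 1))))
    stop("biome labels must have distinct first letters")
  codes <- as.matrix(expand.grid(rep(list(0:2), n_biomes))[, n_biomes:1, drop = FALSE])
  dimnames(codes) <- NULL
  codes <- codes[rowSums(codes == 2L) >= 1L, , drop = FALSE]
  digits <- apply(codes, 1L, paste, collapse = "")
  ord <- order(digits)
  codes <- codes[ord, , drop = FALSE]
  digits <- digits[ord]
  storage.mode(codes) <- "integer"
  sl <- vapply(seq_len(nrow(codes)), function(i) state_label(codes[i, ], labels), "")
  structure(list(n_biomes = n_biomes, labels = labels, codes = codes,
                 digits = digits, state_labels = sl, n_states = nrow(codes),
                 kind = "rfbs"),
            class = "rfbs_space")
}

#' @export
print.rfbs_space <- function(x, ...) {
  cat(sprintf("%s state space: %d biomes (%s), %d states\n",
              if (identical(x$kind, "dec")) "Presence/absence" else "Affinity-set",
              x$n_biomes, paste(x$labels, collapse = ", "), x$n_states))
  cat(" ", paste(x$state_labels, collapse = " "), "\n")
  invisible(x)
}

#' Label an affinity state
#'
#' Concatenates, in biome order, the uppercase biome initial for an
#' established affinity (code 2), the lowercase initial for an enabled
#' affinity (code 1), and nothing for a non-affinity (code 0). For biomes
#' tropical/warm/cold (T, W, C), the codes (2, 1, 0) give "Tw".
#'
#' @param codes integer vector of affinity codes in {0, 1, 2}.
#' @param labels biome names (first letters used), same length as codes.
#' @return a single character string.
#' @seealso [parse_state_label()] for the inverse.
#' @export
state_label <- function(codes, labels) {
  if (length(codes) != length(labels))
    stop("codes and labels must have the same length")
  init <- substr(labels, 1, 1)
  paste(ifelse(codes == 2L, toupper(init), ifelse(codes == 1L, tolower(init), "")),
        collapse = "")
}

#' Parse an affinity-state label back to codes
#'
#' @param label a state label produced by [state_label()].
#' @param labels biome names in order.
#' @return integer vector of codes in {0, 1, 2}.
#' @export
parse_state_label <- function(label, labels) {
  init <- substr(labels, 1, 1)
  chars <- strsplit(label, "")[[1]]
  codes <- integer(length(labels))
  pos <- 1L
  for (b in seq_along(labels)) {
    if (pos <= length(chars) && chars[pos] == toupper(init[b])) {
      codes[b] <- 2L; pos <- pos + 1L
    } else if (pos <= length(chars) && chars[pos] == tolower(init[b])) {
      codes[b] <- 1L; pos <- pos + 1L
    }
  }
  if (pos != length(chars) + 1L || sum(codes == 2L) < 1L)
    stop("label '", label, "' is not a valid state label for these biomes")
  codes
}

#' Look up state indices
#'
#' @param space an `rfbs_space`.
#' @param x digit strings ("210"), state labels ("Tw"), or an integer code
#'   vector / matrix of code rows.
#' @return integer indices into the state space.
#' @export
state_index <- function(space, x) {
  if (is.character(x)) {
    i <- match(x, space$digits)
    j <- match(x, space$state_labels)
    out <- ifelse(is.na(i), j, i)
    if (anyNA(out)) stop("unknown state(s): ", paste(x[is.na(out)], collapse = ", "))
    return(out)
  }
  if (is.matrix(x)) return(match(apply(x, 1, paste, collapse = ""), space$digits))
  match(paste(x, collapse = ""), space$digits)
}

#' A per-species tip observation
#'
#' Records, for each biome, the non-empty subset of affinity codes compatible
#' with what was observed. An established affinity is the singleton {2}; an
#' unestablished biome scored with complete ignorance (the worst case) is
#' {0, 1}, i.e. ambiguous between enabled and non-affinity.
#'
#' @param species species identifier.
#' @param allowed a list of length B; each element an integer vector, a
#'   non-empty subset of 0:2. Alternatively a character vector of cell codes
#'   in {"0","1","2","01","?"} where "?" means {0, 1}.
#' @return an object of class \code{rfbs_tip_obs}.
#' @export
tip_observation <- function(species, allowed) {
  if (is.character(allowed)) {
    allowed <- lapply(allowed, function(cell) {
      switch(cell,
             "0" = 0L, "1" = 1L, "2" = 2L,
             "01" = c(0L, 1L), "?" = c(0L, 1L),
             stop("unknown tip-data cell value '", cell, "'"))
    })
  }
  if (!length(allowed) || any(!lengths(allowed)))
    stop("each biome needs a non-empty allowed set")
  allowed <- lapply(allowed, function(a) sort(unique(as.integer(a))))
  if (any(unlist(allowed) < 0L) || any(unlist(allowed) > 2L))
    stop("allowed codes must lie in {0, 1, 2}")
  structure(list(species = as.character(species), allowed = allowed),
            class = "rfbs_tip_obs")
}

#' Include/exclude/adjacency constraints on tip ambiguity
#'
#' Includes force an unestablished biome to be at minimum enabled (code 1):
#' the evidence (e.g. survival in a non-native arboretum) demonstrates
#' suitability, not occupancy. Excludes force a non-affinity (code 0), e.g.
#' failed germination without prolonged cold. The adjacency rule encodes a
#' climatic gradient: a state in which the two biomes flanking an
#' intermediate biome are both established while the intermediate biome is a
#' non-affinity is dropped from the ambiguity set.
#'
#' @param includes data frame with columns \code{species}, \code{biome}
#'   (biome label or index), or NULL.
#' @param excludes same layout as \code{includes}.
#' @param adjacency integer or character vector giving the ordered biome
#'   gradient (length >= 3), or NULL to disable.
#' @param adjacency_mode "established" (rule fires when both flanking biomes
#'   have code 2, the documented usage) or "affinity" (fires when both have
#'   code >= 1).
#' @return an object of class \code{rfbs_constraints}.
#' @export
constraint_set <- function(includes = NULL, excludes = NULL, adjacency = NULL,
                           adjacency_mode = c("established", "affinity")) {
  adjacency_mode <- match.arg(adjacency_mode)
  norm <- function(x) {
    if (is.null(x) || !nrow(x)) return(NULL)
    data.frame(species = as.character(x$species), biome = x$biome,
               stringsAsFactors = FALSE)
  }
  structure(list(includes = norm(includes), excludes = norm(excludes),
                 adjacency = adjacency, adjacency_mode = adjacency_mode),
            class = "rfbs_constraints")
}

.biome_idx <- function(biome, space) {
  if (is.numeric(biome)) return(as.integer(biome))
  i <- match(biome, space$labels)
  if (anyNA(i)) stop("unknown biome(s): ", paste(biome[is.na(i)], collapse = ", "))
  i
}

#' Tip ambiguity set compatible with an observation and constraints
#'
#' Builds the 0/1 indicator over the state space admitting exactly the
#' states whose per-biome codes fall in the observation's allowed sets after
#' applying include constraints (unestablished biome forced to code 1),
#' exclude constraints (forced to code 0), and the climatic adjacency rule.
#' Every admitted state reproduces the observed established pattern, and all
#' admitted states receive equal observation likelihood.
#'
#' @param obs an [tip_observation()].
#' @param constraints an [constraint_set()], or NULL.
#' @param space an [enumerate_states()] state space.
#' @return an object of class \code{rfbs_tip_mask}: list with \code{species}
#'   and \code{mask}, an integer 0/1 vector over states.
#' @examples
#' sp <- enumerate_states(3, c("T", "W", "C"))
#' obs <- tip_observation("sp1", c("2", "?", "?"))
#' m <- compatible_states(obs, NULL, sp)
#' sp$digits[m$mask == 1]  # "200" "201" "210" "211"
#' @export
compatible_states <- function(obs, constraints = NULL, space) {
  if (length(obs$allowed) != space$n_biomes)
    stop("observation has ", length(obs$allowed), " biomes; space has ",
         space$n_biomes)
  allowed <- obs$allowed
  if (!is.null(constraints)) {
    pick <- function(df) {
      if (is.null(df)) return(integer(0))
      .biome_idx(df$biome[df$species == obs$species], space)
    }
    for (b in pick(constraints$includes)) {
      a <- intersect(allowed[[b]], c(1L, 2L))
      if (!(2L %in% obs$allowed[[b]]) || length(obs$allowed[[b]]) > 1L)
        a <- setdiff(a, 2L)  # unestablished: include confirms enabled only
      allowed[[b]] <- a
    }
    for (b in pick(constraints$excludes)) {
      if (identical(obs$allowed[[b]], 2L))
        stop("species ", obs$species, ": cannot exclude established biome ",
             space$labels[b])
      allowed[[b]] <- intersect(allowed[[b]], 0L)
    }
  }
  if (any(!lengths(allowed)))
    stop("contradictory constraints empty the ambiguity set for species ",
         obs$species)
  mask <- rep(1L, space$n_states)
  for (b in seq_len(space$n_biomes))
    mask <- mask & (space$codes[, b] %in% allowed[[b]])
  if (!is.null(constraints) && !is.null(constraints$adjacency)) {
    grad <- .biome_idx(constraints$adjacency, space)
    thr <- if (identical(constraints$adjacency_mode, "affinity")) 1L else 2L
    for (m in seq_along(grad)[-c(1L, length(grad))]) {
      lo <- space$codes[, grad[seq_len(m - 1L)], drop = FALSE]
      hi <- space$codes[, grad[(m + 1L):length(grad)], drop = FALSE]
      bracketed <- apply(lo >= thr, 1, any) & apply(hi >= thr, 1, any)
      mask <- mask & !(bracketed & space$codes[, grad[m]] == 0L)
    }
  }
  mask <- as.integer(mask)
  if (!sum(mask))
    stop("contradictory constraints empty the ambiguity set for species ",
         obs$species)
  structure(list(species = obs$species, mask = mask), class = "rfbs_tip_mask")
}

#' Assemble a tip-mask matrix from a list of tip masks
#'
#' @param masks list of \code{rfbs_tip_mask} objects.
#' @param space the state space.
#' @return S x n_tips integer matrix, columns named by species.
#' @export
mask_matrix <- function(masks, space) {
  m <- vapply(masks, function(x) x$mask, integer(space$n_states))
  colnames(m) <- vapply(masks, function(x) x$species, "")
  m
}
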