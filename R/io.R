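#' Read a rooted binary tree from a newick file
#'
#' @param path newick file.
#' @return an \code{ape::phylo}; polytomies, missing branch lengths, and
#'   unrooted trees are rejected with informative errors.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  encode_tree(tree)$tree
}

#' Write a tree to newick
#'
#' @param tree an \code{ape::phylo}.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read tip affinity data (and optional constraints) into ambiguity masks
#'
#' The tip-data file is delimited text with a \code{species} column and one
#' column per biome; cells take values 0, 1, 2, 01, or ? (? is shorthand for
#' 01, ambiguous between non-affinity and enabled). The constraint file has
#' columns \code{species}, \code{biome}, \code{action} (include/exclude).
#'
#' @param path tip-data file (TSV/CSV; separator sniffed from the header).
#' @param space the state space; its biome labels must match the header.
#' @param constraints_path optional constraint file.
#' @param adjacency optional ordered biome gradient (labels or indices)
#'   activating the climatic adjacency rule.
#' @param adjacency_mode see [constraint_set()].
#' @return S x n_tips 0/1 mask matrix, columns named by species.
#' @export
read_tip_data <- function(path, space, constraints_path = NULL,
                          adjacency = NULL,
                          adjacency_mode = c("established", "affinity")) {
  adjacency_mode <- match.arg(adjacency_mode)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (!"species" %in% names(df)) stop("tip data needs a 'species' column")
  if (anyDuplicated(df$species))
    stop("duplicated species in tip data: ",
         df$species[duplicated(df$species)][1])
  missing_b <- setdiff(space$labels, names(df))
  if (length(missing_b))
    stop("tip data lacks biome column(s): ", paste(missing_b, collapse = ", "))
  cs <- NULL
  if (!is.null(constraints_path)) {
    cdf <- utils::read.table(constraints_path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE)
    if (!all(c("species", "biome", "action") %in% names(cdf)))
      stop("constraint file needs columns species, biome, action")
    unknown <- setdiff(cdf$species, df$species)
    if (length(unknown))
      stop("constraints name unknown species: ",
           paste(unknown, collapse = ", "))
    both <- intersect(paste(cdf$species, cdf$biome)[cdf$action == "include"],
                      paste(cdf$species, cdf$biome)[cdf$action == "exclude"])
    if (length(both))
      stop("species/biome pair both included and excluded: ", both[1])
    cs <- constraint_set(includes = cdf[cdf$action == "include", ],
                         excludes = cdf[cdf$action == "exclude", ],
                         adjacency = adjacency,
                         adjacency_mode = adjacency_mode)
  } else if (!is.null(adjacency)) {
    cs <- constraint_set(adjacency = adjacency,
                         adjacency_mode = adjacency_mode)
  }
  masks <- lapply(seq_len(nrow(df)), function(i)
    compatible_states(tip_observation(df$species[i],
                                      as.character(df[i, space$labels])),
                      cs, space))
  mask_matrix(masks, space)
}

#' Dump a state space as a TSV report
#'
#' Columns: index, digit string, state label.
#'
#' @param space a state space.
#' @param path output file.
#' @export
write_state_space <- function(space, path) {
  utils::write.table(
    data.frame(index = seq_len(space$n_states), digits = space$digits,
               label = space$state_labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an MCMC trace as TSV with a commented header
#'
#' Header comments record the configuration, seed, prior, and per-parameter
#' acceptance rates, so a run is reproducible from its output alone.
#'
#' @param fit an [run_mcmc()] result.
#' @param path output file.
#' @export
write_trace <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- fit$config
  writeLines(c(
    sprintf("# model=%s iterations=%d thin=%d burn_in=%g seed=%d",
            fit$model_kind, cfg$iterations, cfg$thin, cfg$burn_in, cfg$seed),
    sprintf("# lambda_rates=%g lambda_clado=%g prior_beta=%g",
            cfg$lambda_rates, cfg$lambda_clado, fit$prior_beta),
    sprintf("# acceptance: %s",
            paste(names(fit$acceptance), round(fit$acceptance, 4),
                  sep = "=", collapse = " "))), con)
  utils::write.table(fit$trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write tip masks in the tip-data dialect where possible
#'
#' Masks that factor into per-biome allowed sets (as all masks produced by
#' observation coding do) are written with cells 0/1/2/01; other masks are
#' written in an extra \code{states} column listing admitted digit strings.
#'
#' @param tip_masks S x n_tips mask matrix.
#' @param space the state space.
#' @param path output file.
#' @export
write_tip_data <- function(tip_masks, space, path) {
  cell <- function(codes) paste(sort(unique(codes)), collapse = "")
  rows <- lapply(seq_len(ncol(tip_masks)), function(i) {
    st <- which(tip_masks[, i] == 1L)
    allowed <- lapply(seq_len(space$n_biomes),
                      function(b) sort(unique(space$codes[st, b])))
    factorizes <- prod(lengths(allowed)) == length(st)
    c(species = colnames(tip_masks)[i],
      stats::setNames(vapply(allowed, cell, ""), space$labels),
      states = if (factorizes) "" else paste(space$digits[st], collapse = ","))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (all(df$states == "")) df$states <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
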