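#' Euclidean distance between two WHALES descriptors
#'
#' The similarity measure of the screen: smaller distance means higher
#' 3D-pharmacophoric similarity. Both vectors must have the full 33-value
#' layout.
#'
#' @param x,y Numeric vectors of length 33 (see [whales_descriptor()]).
#' @return Nonnegative scalar distance.
#' @export
similarity_distance <- function(x, y) {
  if (length(x) != 33 || length(y) != 33) {
    stop_ws("descriptor length mismatch: expected 33-value vectors, got %d and %d",
            length(x), length(y), class = "whalescreen_contract_error")
  }
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' Rank a descriptor library against query templates
#'
#' Scores every library molecule against every template by Euclidean
#' descriptor distance, aggregates the per-template distances (default:
#' minimum over templates, i.e. the nearest-template rule, so a molecule
#' similar to ANY query is ranked highly; `"mean"` is available), and
#' returns the `top_k` hits sorted by ascending aggregate distance. Ties
#' are broken by molecule id (lexicographic), making the ranking
#' deterministic and independent of library input order.
#'
#' @param templates Descriptor matrix of the query templates (rownames =
#'   template ids), from [whales_descriptors()].
#' @param library Descriptor matrix of the screening library.
#' @param top_k Number of hits to return (default 27); clamped to the
#'   library size.
#' @param aggregate `"min"` (default) or `"mean"`.
#' @return A data frame of class `screening_hits`: `molecule_id`, one
#'   `dist_<template>` column per template, `aggregate_distance`, `rank`
#'   (1..k, ascending distance).
#' @export
rank_library <- function(templates, library, top_k = 27L,
                         aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  templates <- as_descriptor_matrix(templates, "templates")
  library <- as_descriptor_matrix(library, "library")
  if (top_k < 1) {
    stop_ws("top_k must be >= 1", class = "whalescreen_contract_error")
  }
  clash <- intersect(rownames(templates), rownames(library))
  if (length(clash)) {
    message(sprintf("template id(s) also present in the library (scored normally): %s",
                    paste(clash, collapse = ", ")))
  }
  # library x templates distance matrix
  D <- vapply(seq_len(nrow(templates)), function(t) {
    sqrt(rowSums(sweep(library, 2, templates[t, ])^2))
  }, numeric(nrow(library)))
  D <- matrix(D, nrow = nrow(library))
  agg <- switch(aggregate,
                min = apply(D, 1, min),
                mean = rowMeans(D))
  ord <- order(agg, rownames(library), method = "radix")
  k <- min(as.integer(top_k), nrow(library))
  sel <- ord[seq_len(k)]
  hits <- data.frame(molecule_id = rownames(library)[sel],
                     stringsAsFactors = FALSE)
  for (t in seq_len(nrow(templates))) {
    hits[[paste0("dist_", rownames(templates)[t])]] <- D[sel, t]
  }
  hits$aggregate_distance <- agg[sel]
  hits$rank <- seq_len(k)
  class(hits) <- c("screening_hits", "data.frame")
  hits
}

as_descriptor_matrix <- function(x, what) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    x <- whales_descriptors(x)
  }
  x <- as.matrix(x)
  if (!nrow(x)) {
    stop_ws("%s descriptor matrix is empty", what,
            class = "whalescreen_contract_error")
  }
  if (ncol(x) != 33) {
    stop_ws("%s descriptor matrix must have 33 columns, has %d", what,
            ncol(x), class = "whalescreen_contract_error")
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("%s%04d", what, seq_len(nrow(x)))
  x
}

#' Write a screening hit list to CSV
#'
#' @param hits A `screening_hits` data frame from [rank_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
screening_report <- function(hits, path) {
  if (!nrow(hits)) {
    stop_ws("refusing to write an empty hit list",
            class = "whalescreen_contract_error")
  }
  utils::write.csv(hits, path, row.names = FALSE)
  invisible(path)
}

#' Read a screening report written by [screening_report()]
#'
#' @param path CSV path.
#' @return A `screening_hits` data frame.
#' @export
read_screening_report <- function(path) {
  hits <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(molecule_id = "character"))
  class(hits) <- c("screening_hits", "data.frame")
  hits
}
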