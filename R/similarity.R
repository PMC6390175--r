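#' Similarity matrix container
#'
#' A symmetric S x S matrix of pairwise stimulus similarity with stimulus
#' metadata. `kind` tags where the values came from: "categorical" (binary
#' same/different category), "physical" (configural form or motion pattern),
#' "perceptual" (judgments) or "response" (pattern correlations).
#'
#' @param values symmetric numeric S x S matrix.
#' @param stimulus_ids character vector of length S.
#' @param identity,expression per-stimulus category labels.
#' @param kind one of "categorical", "physical", "perceptual", "response".
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, stimulus_ids,
                              identity = NULL, expression = NULL,
                              kind = c("categorical", "physical",
                                       "perceptual", "response")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  S <- nrow(values)
  if (S < 2L || ncol(values) != S)
    stop("values must be a square matrix with S >= 2")
  if (max(abs(values - t(values))) > 1e-12)
    stop("similarity matrix is asymmetric beyond tolerance 1e-12")
  stimulus_ids <- as.character(stimulus_ids)
  stopifnot(length(stimulus_ids) == S)
  if (kind == "categorical") {
    off <- values[lower.tri(values)]
    if (!all(off %in% c(0, 1)))
      stop("categorical similarity matrices must be 0/1 off the diagonal")
  }
  dimnames(values) <- list(stimulus_ids, stimulus_ids)
  structure(list(values = values, stimulus_ids = stimulus_ids,
                 identity = if (is.null(identity)) rep(NA_character_, S)
                            else as.character(identity),
                 expression = if (is.null(expression)) rep(NA_character_, S)
                              else as.character(expression),
                 kind = kind),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, kind=%s (%d unique pairs)\n",
              nrow(x$values), nrow(x$values), x$kind,
              choose(nrow(x$values), 2L)))
  invisible(x)
}

#' Binary categorical model similarity matrix
#'
#' Assigns 1 (maximal similarity) to stimulus pairs sharing a category label
#' and 0 to pairs that differ. With labels = identity over a crossed
#' identity x expression design this tests for expression-invariant identity
#' structure, and vice versa.
#'
#' @param labels per-stimulus category labels.
#' @param stimulus_ids optional stimulus ids (default `names(labels)` or
#'   indices).
#' @param identity,expression optional metadata passed through.
#' @return A `similarity_matrix` of kind "categorical". If all stimuli share
#'   one label (constant off-diagonal) the matrix is built but flagged with
#'   attribute `degenerate = TRUE`: it cannot be used in a correlation.
#' @export
category_model_matrix <- function(labels, stimulus_ids = NULL,
                                  identity = NULL, expression = NULL) {
  labels <- as.character(labels)
  S <- length(labels)
  if (S < 2L) stop("need at least 2 stimuli")
  if (is.null(stimulus_ids))
    stimulus_ids <- if (!is.null(names(labels))) names(labels)
                    else as.character(seq_len(S))
  vals <- outer(labels, labels, `==`) * 1
  diag(vals) <- 1
  out <- similarity_matrix(vals, stimulus_ids, identity, expression,
                           kind = "categorical")
  if (length(unique(labels)) == 1L || length(unique(labels)) == S) {
    if (length(unique(labels)) == 1L)
      attr(out, "degenerate") <- TRUE
  }
  out
}

#' Perceptual similarity matrix from a pair-judgment table
#'
#' Averages per-pair similarity ratings over participants, as in a behavioral
#' pairwise-judgment experiment where every unordered pair of stimuli is
#' rated on a continuous scale.
#'
#' @param pair_table data.frame with columns `participant`, `stim_a`,
#'   `stim_b`, `rating` (and optionally `task`).
#' @param stimulus_ids character vector defining the stimulus set and order.
#' @param identity,expression optional per-stimulus metadata.
#' @return A `similarity_matrix` of kind "perceptual"; diagonal set to 1
#'   (self-similarity is maximal by convention and excluded from RSA anyway).
#' @export
judgment_matrix <- function(pair_table, stimulus_ids,
                            identity = NULL, expression = NULL) {
  need <- c("stim_a", "stim_b", "rating")
  if (!all(need %in% names(pair_table)))
    stop("pair_table needs columns: ", paste(need, collapse = ", "))
  stimulus_ids <- as.character(stimulus_ids)
  S <- length(stimulus_ids)
  ia <- match(as.character(pair_table$stim_a), stimulus_ids)
  ib <- match(as.character(pair_table$stim_b), stimulus_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("pair table references unknown stimuli")
  if (any(ia == ib)) stop("pair table contains self-pairs")
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  means <- tapply(pair_table$rating, key, mean)
  lo <- which(lower.tri(matrix(0, S, S)), arr.ind = TRUE)
  all_keys <- paste(lo[, 2L], lo[, 1L])
  missing <- setdiff(all_keys, names(means))
  if (length(missing)) {
    mi <- do.call(rbind, strsplit(missing, " "))
    stop("unrated pair(s): ",
         paste(paste0(stimulus_ids[as.integer(mi[, 1L])], "~",
                      stimulus_ids[as.integer(mi[, 2L])]),
               collapse = ", "))
  }
  vals <- matrix(0, S, S)
  vals[lower.tri(vals)] <- as.vector(means[all_keys])
  vals <- vals + t(vals)
  diag(vals) <- 1
  similarity_matrix(vals, stimulus_ids, identity, expression,
                    kind = "perceptual")
}

#' Response-pattern similarity matrix
#'
#' Pearson correlation between per-stimulus multichannel response patterns,
#' the sensor-level pattern-similarity measure used for RSA against model
#' matrices.
#'
#' @param patterns numeric channels x S matrix, one column per stimulus.
#' @param stimulus_ids optional (default column names or indices).
#' @param identity,expression optional metadata.
#' @param scale_channels if TRUE, z-score each channel across stimuli first.
#' @param context optional string naming the time/frequency bin for error
#'   messages.
#' @return A `similarity_matrix` of kind "response".
#' @export
pattern_similarity_matrix <- function(patterns, stimulus_ids = NULL,
                                      identity = NULL, expression = NULL,
                                      scale_channels = FALSE,
                                      context = NULL) {
  patterns <- as.matrix(patterns)
  if (is.null(stimulus_ids))
    stimulus_ids <- if (!is.null(colnames(patterns))) colnames(patterns)
                    else as.character(seq_len(ncol(patterns)))
  sds <- apply(patterns, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance response pattern for stimulus ",
         paste(stimulus_ids[sds == 0], collapse = ", "),
         if (!is.null(context)) paste0(" at ", context) else "")
  if (scale_channels)
    patterns <- t(scale(t(patterns)))
  vals <- stats::cor(patterns)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  similarity_matrix(vals, stimulus_ids, identity, expression,
                    kind = "response")
}

#' Vectorize a similarity matrix for RSA
#'
#' Extracts the lower triangle (diagonal excluded) in the package's canonical
#' cell order — column-major lower triangle, the order `stats::dist` uses.
#' Any two matrices over the same stimulus set vectorize to positionally
#' aligned cells, which is what matrix-to-matrix correlation requires.
#'
#' @param m a `similarity_matrix` or plain symmetric matrix.
#' @return Numeric vector of length S(S-1)/2.
#' @export
vectorize <- function(m) {
  vals <- if (inherits(m, "similarity_matrix")) m$values else as.matrix(m)
  if (max(abs(vals - t(vals))) > 1e-12)
    stop("matrix is asymmetric beyond tolerance; cannot vectorize")
  vals[lower.tri(vals)]
}

#' Rebuild a symmetric matrix from its canonical cell vector
#'
#' Inverse of [vectorize()] up to the (discarded) diagonal, which is set to
#' `diag_value`.
#'
#' @param cells vector of length S(S-1)/2.
#' @param diag_value value for the restored diagonal (default 1).
#' @export
devectorize <- function(cells, diag_value = 1) {
  S <- (1 + sqrt(1 + 8 * length(cells))) / 2
  if (S != round(S))
    stop("cell vector length is not S(S-1)/2 for integer S")
  S <- as.integer(S)
  m <- matrix(0, S, S)
  m[lower.tri(m)] <- cells
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Reorder a similarity matrix to a given stimulus order
#'
#' Response-pattern pipelines key stimuli in sorted order; model matrices
#' built from a stimulus list keep list order. Vectorized cells only align
#' if both use the same order, so reorder before correlating.
#'
#' @param m a `similarity_matrix`.
#' @param stimulus_ids target order (a permutation of `m$stimulus_ids`).
#' @export
reorder_similarity <- function(m, stimulus_ids) {
  stimulus_ids <- as.character(stimulus_ids)
  idx <- match(stimulus_ids, m$stimulus_ids)
  if (anyNA(idx) || length(idx) != length(m$stimulus_ids))
    stop("stimulus_ids is not a permutation of the matrix's stimulus set")
  similarity_matrix(m$values[idx, idx], stimulus_ids,
                    m$identity[idx], m$expression[idx], m$kind)
}
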