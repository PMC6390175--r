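#' Threshold-free cluster enhancement
#'
#' Integrates suprathreshold cluster extent and height over thresholds,
#' enhancing contiguous effects without committing to a cluster-forming
#' threshold: for each map coordinate p,
#' TFCE(p) = sum over h in (0, map(p)\] (step dh) of extent(h, p)^E * h^H * dh,
#' where extent is the size of the suprathreshold (>= h) connected component
#' containing p (contiguous run in 1-D; 4-connectivity in 2-D). One-sided:
#' negative values are not enhanced.
#'
#' @param map numeric vector (1-D map) or matrix (2-D, frequencies x time).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; NULL (default) uses max(map)/100.
#' @return Enhanced map, same shape as the input.
#' @export
tfce <- function(map, E = 0.5, H = 2, dh = NULL) {
  dims <- if (is.matrix(map)) dim(map) else c(length(map), 1L)
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  out <- .tfce_cpp(as.numeric(map), dims[1L], dims[2L], E, H,
                   if (is.null(dh)) -1 else dh)
  if (is.matrix(map)) matrix(out, dims[1L], dims[2L], dimnames = dimnames(map))
  else out
}

#' Permutation scheme for group-level RSA inference
#'
#' @param n_permutations number of sign-flip permutations (default 10000).
#' @param seed RNG seed making the null reproducible.
#' @export
permutation_scheme <- function(n_permutations = 10000L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), scheme = "participant sign-flip"),
            class = "permutation_scheme")
}

#' TFCE permutation correction of group RSA maps
#'
#' One-sample group inference over participants' Fisher-z maps: the observed
#' right-sided t map is TFCE-enhanced; the null is built by randomly negating
#' each participant's map (the exchangeable null for a one-sample test),
#' recomputing t and TFCE, and taking the map-wise maximum. Corrected
#' p(coordinate) = (1 + #\{null maxima >= observed TFCE\}) / (1 + n_perm).
#'
#' @param zmaps participants x coordinates matrix (coordinates column-major
#'   if the map is 2-D).
#' @param dims map shape, e.g. c(n_freq, n_time) or c(n_time, 1).
#' @param scheme a [permutation_scheme()].
#' @param alpha familywise significance level (default 0.05).
#' @param E,H,dh TFCE parameters (see [tfce()]).
#' @return Object of class `rsa_stat_map`: list with `t` (observed t map),
#'   `tfce` (enhanced map), `p` (corrected p map), `mask` (p <= alpha),
#'   `null_max` (the permutation distribution), `dims`, `alpha`, and
#'   `params` echoing every decided constant.
#' @export
permutation_correct <- function(zmaps, dims = c(ncol(zmaps), 1L),
                                scheme = permutation_scheme(),
                                alpha = 0.05, E = 0.5, H = 2, dh = NULL) {
  stopifnot(is.matrix(zmaps), nrow(zmaps) >= 2L,
            prod(dims) == ncol(zmaps))
  n <- nrow(zmaps)
  n_perm <- scheme$n_permutations
  exhaustive <- FALSE
  if (n <= 30 && n_perm >= 2^n) {
    warning("n_permutations >= 2^n_participants: enumerating all ", 2^n,
            " sign patterns exhaustively")
    signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
    n_perm <- nrow(signs)
    exhaustive <- TRUE
  } else {
    set.seed(scheme$seed)
    signs <- matrix(sample(c(-1L, 1L), n_perm * n, replace = TRUE),
                    n_perm, n)
  }
  dh_arg <- if (is.null(dh)) -1 else dh
  tobs <- group_t_map(zmaps)
  obs_enh <- .tfce_cpp(tobs, dims[1L], dims[2L], E, H, dh_arg)
  null_max <- .perm_null_max_cpp(zmaps, signs, dims[1L], dims[2L],
                                 E, H, dh_arg)
  p <- vapply(obs_enh, function(o) (1 + sum(null_max >= o)) / (1 + n_perm),
              numeric(1))
  shape <- function(v) if (dims[2L] > 1L) matrix(v, dims[1L], dims[2L]) else v
  structure(list(t = shape(tobs), tfce = shape(obs_enh), p = shape(p),
                 mask = shape(p <= alpha), null_max = null_max,
                 dims = dims, alpha = alpha,
                 params = list(E = E, H = H,
                               dh = if (is.null(dh)) "max/100" else dh,
                               n_permutations = n_perm,
                               exhaustive = exhaustive,
                               seed = scheme$seed,
                               scheme = scheme$scheme)),
            class = "rsa_stat_map")
}

#' @export
print.rsa_stat_map <- function(x, ...) {
  nsig <- sum(x$mask)
  cat(sprintf(
    "<rsa_stat_map> %s map: %d/%d coordinates significant at alpha=%g (%d perms)\n",
    if (x$dims[2L] > 1L) paste(x$dims, collapse = " x ") else "1-D",
    nsig, prod(x$dims), x$alpha, x$params$n_permutations))
  invisible(x)
}

#' Per-participant RSA map over map coordinates
#'
#' Correlates (partial) Spearman the model cell vector against response cell
#' vectors at every map coordinate and Fisher-transforms the result.
#'
#' @param response_cells n_pairs x n_coords matrix: column j holds the
#'   vectorized response-pattern similarity matrix at coordinate j.
#' @param model_cells vectorized model similarity matrix.
#' @param control_cells optional list of vectorized control matrices for
#'   partial correlation.
#' @return Numeric vector of Fisher-z values, one per coordinate.
#' @export
rsa_map <- function(response_cells, model_cells, control_cells = NULL) {
  stopifnot(is.matrix(response_cells),
            nrow(response_cells) == length(model_cells))
  apply(response_cells, 2L, function(cells) {
    rho <- partial_spearman(cells, model_cells, control_cells)
    # clamp: rho == +/-1 can only arise in noise-free toy data
    fisher_z(max(-1 + 1e-12, min(1 - 1e-12, rho)))
  })
}

#' Full group RSA scan
#'
#' Runs the complete inference chain on per-participant response-similarity
#' stacks: (partial) Spearman against the model per coordinate -> Fisher z ->
#' smoothing (Butterworth over time for 1-D maps, separable Gaussian for
#' time-frequency maps) -> group t -> TFCE -> sign-flip permutation
#' correction.
#'
#' @param response_cells_list one element per participant; each an
#'   n_pairs x n_coords matrix (see [rsa_map()]).
#' @param model a `similarity_matrix` (or cell vector) to test.
#' @param controls optional list of `similarity_matrix` / cell vectors to
#'   partial out.
#' @param dims map shape c(n_freq, n_time) for 2-D scans, or NULL for 1-D.
#' @param smoothing NULL, or for 1-D maps list(sampling_rate=, cutoff=10,
#'   order=5), or for 2-D maps list(freq_step=, time_step=, fwhm_freq=4,
#'   fwhm_time=20).
#' @param scheme a [permutation_scheme()].
#' @param alpha familywise level.
#' @param ... TFCE parameters passed to [permutation_correct()].
#' @return An `rsa_stat_map`; element `z` carries the smoothed
#'   per-participant maps, `rho_mean` the unsmoothed group-mean rho map.
#' @export
rsa_scan <- function(response_cells_list, model, controls = NULL,
                     dims = NULL, smoothing = NULL,
                     scheme = permutation_scheme(), alpha = 0.05, ...) {
  model_cells <- if (inherits(model, "similarity_matrix")) vectorize(model)
                 else model
  control_cells <- if (is.null(controls)) NULL
                   else lapply(controls, function(m)
                     if (inherits(m, "similarity_matrix")) vectorize(m) else m)
  zl <- lapply(response_cells_list, rsa_map, model_cells = model_cells,
               control_cells = control_cells)
  n_coord <- length(zl[[1L]])
  if (is.null(dims)) dims <- c(n_coord, 1L)
  zmaps <- do.call(rbind, zl)
  if (!is.null(smoothing)) {
    if (dims[2L] > 1L) {
      zmaps <- t(apply(zmaps, 1L, function(z)
        as.vector(smooth_tf_map(matrix(z, dims[1L], dims[2L]),
                                freq_step = smoothing$freq_step,
                                time_step = smoothing$time_step,
                                fwhm_freq = smoothing$fwhm_freq %||% 4,
                                fwhm_time = smoothing$fwhm_time %||% 20))))
    } else {
      zmaps <- smooth_timecourse(zmaps, smoothing$sampling_rate,
                                 cutoff = smoothing$cutoff %||% 10,
                                 order = smoothing$order %||% 5L)
    }
  }
  out <- permutation_correct(zmaps, dims = dims, scheme = scheme,
                             alpha = alpha, ...)
  out$z <- zmaps
  out$rho_mean <- {
    rho <- colMeans(do.call(rbind, lapply(zl, tanh)))
    if (dims[2L] > 1L) matrix(rho, dims[1L], dims[2L]) else rho
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
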