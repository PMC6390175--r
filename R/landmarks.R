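#' Construct a landmark frame
#'
#' A single video frame annotated with labelled 2-D landmark coordinates
#' (pixel units).
#'
#' @param coords numeric matrix, L x 2, one row per landmark (x, y).
#' @param landmark_ids character or integer vector of length L; unique labels.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(coords, landmark_ids = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be an L x 2 matrix of (x, y) positions")
  if (nrow(coords) < 3L)
    stop("a landmark frame needs at least 3 landmarks")
  landmark_ids <- as.character(landmark_ids)
  if (length(landmark_ids) != nrow(coords))
    stop("landmark_ids length must match the number of coordinate rows")
  dup <- landmark_ids[duplicated(landmark_ids)]
  if (length(dup))
    stop("duplicate landmark ids: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(coords[, 1L]) | !is.finite(coords[, 2L]))
  if (length(bad))
    stop("non-finite coordinates at landmark(s): ",
         paste(landmark_ids[bad], collapse = ", "))
  dimnames(coords) <- list(landmark_ids, c("x", "y"))
  structure(list(coords = coords, landmark_ids = landmark_ids),
            class = "landmark_frame")
}

#' Construct a landmark video
#'
#' An ordered sequence of landmark frames sharing one landmark scheme, plus
#' stimulus metadata (identity and expression labels).
#'
#' @param frames list of `landmark_frame`, all with identical id order.
#' @param frame_rate frames per second.
#' @param stimulus_id stimulus identifier.
#' @param identity_label,expression_label category labels for the stimulus.
#' @return An object of class `landmark_video`.
#' @export
landmark_video <- function(frames, frame_rate, stimulus_id,
                           identity_label = NA_character_,
                           expression_label = NA_character_) {
  if (length(frames) < 2L)
    stop("a landmark video needs at least 2 frames")
  if (!all(vapply(frames, inherits, logical(1), "landmark_frame")))
    stop("frames must all be landmark_frame objects")
  ids <- frames[[1L]]$landmark_ids
  same <- vapply(frames, function(f) identical(f$landmark_ids, ids), logical(1))
  if (!all(same))
    stop("landmark id order differs at frame(s) ",
         paste(which(!same), collapse = ", "), " (1-based)")
  structure(list(frames = frames, frame_rate = frame_rate,
                 stimulus_id = as.character(stimulus_id),
                 identity_label = as.character(identity_label),
                 expression_label = as.character(expression_label)),
            class = "landmark_video")
}

#' @export
print.landmark_video <- function(x, ...) {
  cat(sprintf(
    "<landmark_video> %s [id=%s, expr=%s]: %d frames x %d landmarks @ %g fps\n",
    x$stimulus_id, x$identity_label, x$expression_label,
    length(x$frames), length(x$frames[[1L]]$landmark_ids), x$frame_rate))
  invisible(x)
}

n_landmarks <- function(video) length(video$frames[[1L]]$landmark_ids)
n_frames <- function(video) length(video$frames)

#' Configural-form configuration vector of a frame
#'
#' The configuration of a landmark frame is the vector of Euclidean distances
#' between every unordered pair of its L landmarks, of length L(L-1)/2, in
#' canonical lexicographic (i < j) pair order. Distances between corresponding
#' labelled points are invariant under global translation and rotation, making
#' this a rigid-invariant face-form descriptor.
#'
#' @param frame a `landmark_frame`.
#' @return Numeric vector of length `choose(L, 2)` with attribute
#'   `pair_index`, a 2-column matrix of the landmark indices of each pair.
#' @examples
#' f <- landmark_frame(rbind(c(0, 0), c(3, 4), c(6, 8)))
#' compute_configuration(f)  # 5, 10, 5
#' @export
compute_configuration <- function(frame) {
  if (!inherits(frame, "landmark_frame"))
    frame <- landmark_frame(frame)
  d <- as.vector(stats::dist(frame$coords))
  L <- nrow(frame$coords)
  # dist() emits pairs (i, j), i < j, ordered by i then j: the canonical order
  idx <- which(lower.tri(matrix(0, L, L)), arr.ind = TRUE)
  pair_index <- cbind(i = idx[, 2L], j = idx[, 1L])
  attr(d, "pair_index") <- pair_index
  d
}

first_frame_configuration <- function(video) {
  compute_configuration(video$frames[[1L]])
}

# relative threshold: equilateral configurations differ only in rounding
config_sd_degenerate <- function(cfg) {
  stats::sd(cfg) < 1e-12 * mean(abs(cfg))
}

#' Configural form similarity of two videos
#'
#' Pearson correlation between the first-frame configuration vectors of the
#' two videos (the first frame carries the neutral expression, so this is a
#' pure form measure).
#'
#' @param video_a,video_b `landmark_video` objects with identical landmark
#'   schemes.
#' @return Pearson correlation in \[-1, 1\].
#' @export
configural_form_similarity <- function(video_a, video_b) {
  if (!identical(video_a$frames[[1L]]$landmark_ids,
                 video_b$frames[[1L]]$landmark_ids))
    stop("videos have different landmark schemes")
  ca <- first_frame_configuration(video_a)
  cb <- first_frame_configuration(video_b)
  if (config_sd_degenerate(ca))
    stop("zero-variance configuration vector for stimulus ",
         video_a$stimulus_id)
  if (config_sd_degenerate(cb))
    stop("zero-variance configuration vector for stimulus ",
         video_b$stimulus_id)
  stats::cor(ca, cb)
}

#' Configural-form similarity matrix for a stimulus set
#'
#' @param videos list of `landmark_video` with a shared landmark scheme.
#' @return A `similarity_matrix` (kind "physical") of pairwise Pearson
#'   correlations between first-frame configuration vectors.
#' @export
build_form_similarity_matrix <- function(videos) {
  stopifnot(length(videos) >= 2L)
  cfgs <- vapply(videos, first_frame_configuration,
                 numeric(choose(n_landmarks(videos[[1L]]), 2L)))
  bad <- apply(cfgs, 2L, config_sd_degenerate)
  if (any(bad))
    stop("zero-variance configuration vector for stimulus ",
         paste(vapply(videos[bad], `[[`, "", "stimulus_id"),
               collapse = ", "))
  vals <- stats::cor(cfgs)
  diag(vals) <- 1
  similarity_matrix(vals,
                    stimulus_ids = vapply(videos, `[[`, "", "stimulus_id"),
                    identity = vapply(videos, `[[`, "", "identity_label"),
                    expression = vapply(videos, `[[`, "", "expression_label"),
                    kind = "physical")
}
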