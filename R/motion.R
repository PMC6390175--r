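#' Feature map: facial-anatomy groupings of landmarks
#'
#' Maps feature names (brow, eye, mouth corner, ...) to disjoint sets of
#' landmark ids. Flow values are averaged within each feature before the
#' motion-pattern computation.
#'
#' @param features named list; each element a character vector of landmark ids.
#' @return Object of class `feature_map`.
#' @export
feature_map <- function(features) {
  stopifnot(is.list(features), length(features) >= 1L,
            !is.null(names(features)))
  features <- lapply(features, as.character)
  if (any(lengths(features) == 0L))
    stop("empty feature(s): ",
         paste(names(features)[lengths(features) == 0L], collapse = ", "))
  all_ids <- unlist(features, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("features must be disjoint; duplicated landmark id(s): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(features = features, n_features = length(features)),
            class = "feature_map")
}

#' Fiducial triangle for rigid head-motion correction
#'
#' Three landmarks on a structure that can only move with the whole head
#' (the nose). The frame-1 positions of the triangle are the registration
#' reference.
#'
#' @param ids character vector of exactly 3 landmark ids.
#' @param reference 3 x 2 matrix of their frame-1 coordinates (optional until
#'   [rigid_correct()] fills it from the video).
#' @export
fiducial_triangle <- function(ids, reference = NULL) {
  ids <- as.character(ids)
  if (length(ids) != 3L || anyDuplicated(ids))
    stop("a fiducial triangle needs exactly 3 distinct landmark ids")
  if (!is.null(reference)) {
    reference <- as.matrix(reference)
    stopifnot(nrow(reference) == 3L, ncol(reference) == 2L)
    check_noncollinear(reference, "fiducial reference triangle")
  }
  structure(list(ids = ids, reference = reference),
            class = "fiducial_triangle")
}

triangle_det <- function(p) {
  (p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
    (p[3L, 1L] - p[1L, 1L]) * (p[2L, 2L] - p[1L, 2L])
}

check_noncollinear <- function(p, what) {
  d <- triangle_det(p)
  scale <- max(stats::dist(p))^2
  if (scale == 0 || abs(d) < 1e-10 * scale)
    stop("degenerate (collinear) ", what,
         sprintf(": twice-signed-area = %.3g relative to scale %.3g",
                 d, scale))
  invisible(TRUE)
}

#' Exact 2-D affine transform mapping one triangle onto another
#'
#' Solves the six linear equations fixing the affine map that carries the
#' three source points exactly onto the three destination points.
#'
#' @param src,dst 3 x 2 matrices of point coordinates.
#' @return 3 x 2 matrix `A`; a point row vector p maps to `c(p, 1) %*% A`.
#' @export
fit_affine_from_triangle <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == 3L, ncol(src) == 2L,
            nrow(dst) == 3L, ncol(dst) == 2L)
  check_noncollinear(src, "source triangle")
  solve(cbind(src, 1), dst)
}

apply_affine <- function(points, A) {
  cbind(as.matrix(points), 1) %*% A
}

#' Remove rigid whole-head motion from a landmark video
#'
#' For every frame, fits the affine transform carrying that frame's fiducial
#' triangle onto the frame-1 triangle and applies it to all landmarks: the
#' inverse of the head movement. After correction the fiducials of every
#' frame coincide with frame 1, so residual landmark motion is non-rigid
#' (expression) motion.
#'
#' @param video a `landmark_video`.
#' @param triangle a `fiducial_triangle` whose ids occur in the video.
#' @return The corrected `landmark_video` (attribute `rigid_corrected` set).
#' @export
rigid_correct <- function(video, triangle) {
  ids <- video$frames[[1L]]$landmark_ids
  tri_idx <- match(triangle$ids, ids)
  if (anyNA(tri_idx))
    stop("fiducial id(s) not in video: ",
         paste(triangle$ids[is.na(tri_idx)], collapse = ", "))
  ref <- video$frames[[1L]]$coords[tri_idx, , drop = FALSE]
  check_noncollinear(ref, "frame-1 fiducial triangle")
  frames <- vector("list", length(video$frames))
  frames[[1L]] <- video$frames[[1L]]
  for (f in seq_along(video$frames)[-1L]) {
    cur <- video$frames[[f]]$coords[tri_idx, , drop = FALSE]
    A <- tryCatch(fit_affine_from_triangle(cur, ref),
                  error = function(e)
                    stop("frame ", f, ": ", conditionMessage(e)))
    frames[[f]] <- landmark_frame(apply_affine(video$frames[[f]]$coords, A),
                                  ids)
  }
  out <- landmark_video(frames, video$frame_rate, video$stimulus_id,
                        video$identity_label, video$expression_label)
  attr(out, "rigid_corrected") <- TRUE
  out
}

#' Per-landmark flow magnitudes between consecutive frames
#'
#' Flow is taken as the Euclidean displacement (pixels) of each landmark from
#' one frame to the next, on the rigid-corrected video. A pixel-based optic
#' flow estimator sampled at the landmark positions could be substituted; the
#' units and spatial support are identical.
#'
#' @param video a (rigid-corrected) `landmark_video`.
#' @param landmark_ids optional subset of ids (e.g. the interior landmarks);
#'   default: all.
#' @return L_sel x (F-1) matrix of nonnegative flow magnitudes; rows named by
#'   landmark id.
#' @export
landmark_flow <- function(video, landmark_ids = NULL) {
  ids <- video$frames[[1L]]$landmark_ids
  sel <- if (is.null(landmark_ids)) seq_along(ids)
         else {
           m <- match(as.character(landmark_ids), ids)
           if (anyNA(m))
             stop("unknown landmark id(s): ",
                  paste(landmark_ids[is.na(m)], collapse = ", "))
           m
         }
  F <- length(video$frames)
  out <- matrix(0, length(sel), F - 1L,
                dimnames = list(ids[sel], NULL))
  prev <- video$frames[[1L]]$coords[sel, , drop = FALSE]
  for (f in 2:F) {
    cur <- video$frames[[f]]$coords[sel, , drop = FALSE]
    out[, f - 1L] <- sqrt(rowSums((cur - prev)^2))
    prev <- cur
  }
  out
}

#' Average flow magnitudes within anatomical features
#'
#' @param raw L x (F-1) flow matrix from [landmark_flow()], rows named by id.
#' @param fmap a `feature_map`.
#' @return n_features x (F-1) matrix of mean flows, rows named by feature.
#' @export
average_flow_by_feature <- function(raw, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  out <- matrix(NA_real_, fmap$n_features, ncol(raw),
                dimnames = list(names(fmap$features), NULL))
  for (nm in names(fmap$features)) {
    m <- match(fmap$features[[nm]], rownames(raw))
    if (anyNA(m))
      stop("feature '", nm, "' references landmark id(s) absent from flow: ",
           paste(fmap$features[[nm]][is.na(m)], collapse = ", "))
    out[nm, ] <- colMeans(raw[m, , drop = FALSE])
  }
  out
}

#' Spatiotemporal motion pattern of a video
#'
#' The motion pattern is the vector of absolute differences between every
#' unordered pair of the n_features x (F-1) feature-averaged flow values —
#' for 12 features and 56 frames, choose(12 * 55, 2) = 217,470 elements.
#' Like the configural form measure it is a pattern between corresponding
#' reference values, here spread over space and time.
#'
#' @param flow n_features x (F-1) feature-averaged flow matrix.
#' @return Numeric vector of length `choose(length(flow), 2)` in canonical
#'   pair order (column-major flattening of the flow matrix, then dist order).
#' @export
motion_pattern <- function(flow) {
  v <- as.vector(flow)
  as.vector(stats::dist(v))
}

video_motion_pattern <- function(video, fmap, triangle) {
  corrected <- if (isTRUE(attr(video, "rigid_corrected"))) video
               else rigid_correct(video, triangle)
  raw <- landmark_flow(corrected,
                       unlist(fmap$features, use.names = FALSE))
  motion_pattern(average_flow_by_feature(raw, fmap))
}

#' Motion-pattern similarity matrix for a stimulus set
#'
#' Rigid-corrects each video, computes feature-averaged landmark flow and the
#' motion-pattern vector, and correlates motion patterns between all pairs.
#'
#' @param videos list of `landmark_video`.
#' @param fmap a `feature_map` over interior landmarks.
#' @param triangle the `fiducial_triangle` used for rigid correction.
#' @return A `similarity_matrix` (kind "physical").
#' @export
build_motion_similarity_matrix <- function(videos, fmap, triangle) {
  stopifnot(length(videos) >= 2L)
  pats <- vapply(videos, video_motion_pattern,
                 numeric(choose(fmap$n_features *
                                  (n_frames(videos[[1L]]) - 1L), 2L)),
                 fmap = fmap, triangle = triangle)
  sds <- apply(pats, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance motion pattern for stimulus ",
         paste(vapply(videos[sds == 0], `[[`, "", "stimulus_id"),
               collapse = ", "))
  vals <- stats::cor(pats)
  diag(vals) <- 1
  similarity_matrix(vals,
                    stimulus_ids = vapply(videos, `[[`, "", "stimulus_id"),
                    identity = vapply(videos, `[[`, "", "identity_label"),
                    expression = vapply(videos, `[[`, "", "expression_label"),
                    kind = "physical")
}
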