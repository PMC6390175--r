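#' Specification of a synthetic dynamic-face stimulus set
#'
#' Describes the crossed identity x expression design and the generative
#' scales. Defaults mirror the design the pipeline targets: 6 identities x 6
#' expressions, 179 landmarks (141 interior), 12 anatomical features, 56
#' frames of a 2 s clip (28 fps).
#'
#' @param n_identities,n_expressions design factors (default 6 x 6).
#' @param n_landmarks total landmarks per frame (default 179).
#' @param n_interior interior-face landmarks eligible for non-rigid motion
#'   (default 141).
#' @param n_features anatomical feature groups (default 12).
#' @param n_frames frames per clip (default 56).
#' @param frame_rate frames per second (default 28 = 56 frames / 2 s).
#' @param identity_form_scale SD (pixels) of identity-specific neutral
#'   configuration offsets (default 8).
#' @param expression_motion_scale apex displacement scale (pixels) of
#'   expression-specific feature motion (default 15; the neutral-to-apex
#'   ramp completes by mid-clip, putting peak flows near 1 px/frame).
#' @param rigid_motion_amplitude scale (pixels) of global rigid head motion
#'   (default 2).
#' @param landmark_noise_sd per-frame landmark annotation jitter, pixels
#'   (default 0.1, sub-pixel jitter of temporally-tracked landmarks).
#'   Drawn independently every frame, so it also sets the flow noise
#'   floor; flow magnitudes rectify this noise, and the inverse-affine
#'   head correction amplifies fiducial jitter by the face-to-triangle
#'   distance ratio, so small values already produce a realistic floor.
#' @param seed RNG seed.
#' @export
face_set_spec <- function(n_identities = 6L, n_expressions = 6L,
                          n_landmarks = 179L, n_interior = 141L,
                          n_features = 12L, n_frames = 56L, frame_rate = 28,
                          identity_form_scale = 8,
                          expression_motion_scale = 15,
                          rigid_motion_amplitude = 2,
                          landmark_noise_sd = 0.1, seed = 1L) {
  stopifnot(n_identities >= 1L, n_expressions >= 1L, n_landmarks >= 6L,
            n_interior <= n_landmarks, n_frames >= 2L,
            n_features >= 1L, n_features <= n_interior - 3L)
  structure(as.list(environment()), class = "face_set_spec")
}

smooth_random_walk <- function(n, scale, span = 9L) {
  # cumulative noise, moving-average smoothed, anchored at 0 at frame 1
  x <- cumsum(stats::rnorm(n, 0, 1))
  k <- rep(1 / span, span)
  pad <- (span - 1L) %/% 2L
  xs <- stats::filter(c(rep(x[1L], pad), x, rep(x[n], span - 1L - pad)),
                      k, sides = 2L)
  xs <- as.vector(xs)[pad + seq_len(n)]
  xs <- xs - xs[1L]
  if (max(abs(xs)) > 0) xs / max(abs(xs)) * scale else xs
}

#' Generate a synthetic landmark-annotated dynamic-face stimulus set
#'
#' Emulates the structure of a crossed identity x expression set of dynamic
#' face clips: frame 1 is an identity-specific neutral landmark
#' configuration (shared face template + identity offset + per-video
#' annotation noise); later frames add a smooth, feature-localized
#' expression displacement trajectory (shared across identities, with a
#' per-video timing warp) composed with global rigid head motion (rotation +
#' translation). Three nose landmarks are reserved as rigid fiducials and
#' never receive expression motion.
#'
#' @param spec a [face_set_spec()].
#' @return List with `videos` (list of `landmark_video`), `fmap`
#'   (a `feature_map` over interior landmarks), `triangle` (the nose
#'   `fiducial_triangle`), and `truth` (planted identity offsets, expression
#'   displacement fields and temporal profiles).
#' @export
generate_face_set <- function(spec = face_set_spec()) {
  set.seed(spec$seed)
  L <- spec$n_landmarks
  ids <- sprintf("lm%03d", seq_len(L))
  # face template in a ~200 px box; nose fiducials fixed and well-separated
  template <- cbind(stats::runif(L, 28, 228), stats::runif(L, 28, 228))
  # a well-conditioned nose triangle: annotation jitter on the fiducials
  # must not amplify across the face when the affine is inverted
  template[1:3, ] <- matrix(c(128, 112, 144, 104, 144, 144), 3L, 2L)
  fid_ids <- ids[1:3]
  interior_idx <- seq_len(spec$n_interior)
  assignable <- setdiff(interior_idx, 1:3)
  groups <- split(assignable,
                  rep_len(seq_len(spec$n_features), length(assignable)))
  if (any(lengths(groups) == 0L))
    stop("cannot partition ", length(assignable),
         " interior landmarks into ", spec$n_features, " nonempty features")
  fmap <- feature_map(stats::setNames(lapply(groups, function(i) ids[i]),
                                      paste0("feature", seq_along(groups))))
  id_offsets <- lapply(seq_len(spec$n_identities), function(i)
    matrix(stats::rnorm(2L * L, 0, spec$identity_form_scale), L, 2L))
  # expression displacement fields: localized to a subset of features
  expr_disp <- lapply(seq_len(spec$n_expressions), function(e) {
    D <- matrix(0, L, 2L)
    active <- sample(seq_len(spec$n_features),
                     max(1L, spec$n_features %/% 3L))
    for (g in active) {
      gi <- groups[[g]]
      dir <- stats::rnorm(2L)
      dir <- dir / sqrt(sum(dir^2))
      mag <- spec$expression_motion_scale * stats::runif(length(gi), 0.5, 1.5)
      D[gi, ] <- outer(mag, dir) +
        matrix(stats::rnorm(2L * length(gi), 0,
                            0.2 * spec$expression_motion_scale),
               length(gi), 2L)
    }
    D
  })
  # neutral-to-apex ramp completing by mid-clip, then held at apex
  apex_frame <- max(2, (spec$n_frames - 1L) / 2)
  base_profile <- (1 - cos(pi * pmin((seq_len(spec$n_frames) - 1L) /
                                       apex_frame, 1))) / 2
  centre <- colMeans(template)
  videos <- vector("list", spec$n_identities * spec$n_expressions)
  truth_profiles <- list()
  v <- 0L
  for (i in seq_len(spec$n_identities)) {
    for (e in seq_len(spec$n_expressions)) {
      v <- v + 1L
      neutral <- template + id_offsets[[i]]
      gamma <- exp(stats::rnorm(1L, 0, 0.2))   # per-video timing warp
      profile <- base_profile^gamma
      theta <- smooth_random_walk(spec$n_frames,
                                  spec$rigid_motion_amplitude * 0.01)
      tx <- smooth_random_walk(spec$n_frames, spec$rigid_motion_amplitude)
      ty <- smooth_random_walk(spec$n_frames, spec$rigid_motion_amplitude)
      frames <- vector("list", spec$n_frames)
      for (f in seq_len(spec$n_frames)) {
        pts <- neutral + profile[f] * expr_disp[[e]]
        R <- matrix(c(cos(theta[f]), sin(theta[f]),
                      -sin(theta[f]), cos(theta[f])), 2L, 2L)
        pts <- sweep(pts, 2L, centre) %*% R
        pts <- sweep(pts, 2L, centre + c(tx[f], ty[f]), `+`)
        # annotation jitter happens on the image, after head motion
        pts <- pts + matrix(stats::rnorm(2L * L, 0, spec$landmark_noise_sd),
                            L, 2L)
        frames[[f]] <- landmark_frame(pts, ids)
      }
      videos[[v]] <- landmark_video(frames, spec$frame_rate,
                                    stimulus_id = sprintf("id%de%d", i, e),
                                    identity_label = sprintf("id%d", i),
                                    expression_label = sprintf("expr%d", e))
      truth_profiles[[v]] <- profile
    }
  }
  list(videos = videos, fmap = fmap,
       triangle = fiducial_triangle(fid_ids, template[1:3, ]),
       truth = list(template = template, identity_offsets = id_offsets,
                    expression_displacements = expr_disp,
                    profiles = truth_profiles))
}

#' Specification of synthetic pairwise similarity judgments
#'
#' @param weight_form,weight_motion weights linking the (min-max normalised)
#'   physical form and motion similarity of a pair to its rating.
#' @param noise_sd rating noise SD on the 0-1 scale (default 0.15).
#' @param n_participants raters (default 10).
#' @param seed RNG seed.
#' @export
judgment_sim_spec <- function(weight_form = 1, weight_motion = 0,
                              noise_sd = 0.15, n_participants = 10L,
                              seed = 1L) {
  stopifnot(is.finite(weight_form), is.finite(weight_motion), noise_sd >= 0)
  structure(as.list(environment()), class = "judgment_sim_spec")
}

rescale01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1L]) / diff(r)
}

#' Generate synthetic pairwise similarity-judgment tables
#'
#' Ratings are noisy monotone (linear, clipped) functions of the physical
#' form/motion similarity of each pair: every participant rates all
#' S(S-1)/2 unordered pairs on a 0-1 scale for both a form task and a motion
#' task.
#'
#' @param form_sim,motion_sim `similarity_matrix` objects (physical
#'   measures) over the same stimulus set.
#' @param form_spec,motion_spec [judgment_sim_spec()] for the two tasks;
#'   defaults: the form task weights form only, the motion task motion only.
#' @return data.frame with columns participant, stim_a, stim_b, rating, task.
#' @export
generate_judgments <- function(form_sim, motion_sim,
                               form_spec = judgment_sim_spec(1, 0, seed = 11L),
                               motion_spec = judgment_sim_spec(0, 1,
                                                               seed = 12L)) {
  stopifnot(identical(form_sim$stimulus_ids, motion_sim$stimulus_ids))
  S <- length(form_sim$stimulus_ids)
  lo <- which(lower.tri(matrix(0, S, S)), arr.ind = TRUE)
  pair_a <- form_sim$stimulus_ids[lo[, 2L]]
  pair_b <- form_sim$stimulus_ids[lo[, 1L]]
  f01 <- rescale01(vectorize(form_sim))
  m01 <- rescale01(vectorize(motion_sim))
  one_task <- function(spec, task) {
    set.seed(spec$seed)
    base <- spec$weight_form * f01 + spec$weight_motion * m01
    do.call(rbind, lapply(seq_len(spec$n_participants), function(p) {
      rating <- pmin(1, pmax(0, base + stats::rnorm(length(base), 0,
                                                    spec$noise_sd)))
      data.frame(participant = p, stim_a = pair_a, stim_b = pair_b,
                 rating = rating, task = task)
    }))
  }
  rbind(one_task(form_spec, "form"), one_task(motion_spec, "motion"))
}

#' Specification of a synthetic multichannel epoch simulation
#'
#' Defaults follow the emulated recording design: 16 participants, 32
#' presentations of each of the 36 videos (1152 trials), epochs -500 to
#' 2500 ms at 100 Hz. The channel count defaults to 64 for desk-scale
#' runtime (a 306-channel layout is supported, not default). `effect_size`
#' is the planted oscillation amplitude in units of the sensor noise SD;
#' the default 1.5 is the documented recovery effect size.
#'
#' @param planted_model a `similarity_matrix`: the representational geometry
#'   the channel patterns realise inside the planted window.
#' @param n_participants,n_channels,n_trials_per_video design sizes.
#' @param planted_window_ms,planted_freq_hz time and frequency extents of
#'   the planted effect (defaults 600-1500 ms, 4-20 Hz).
#' @param effect_size planted amplitude / noise SD (default 1.5; 0 = null).
#' @param noise_sd additive white sensor-noise SD (default 1).
#' @param response_type "induced" (phase random across trials: invisible to
#'   evoked averaging, visible in power) or "evoked" (phase-locked).
#' @param sampling_rate Hz (default 100).
#' @param times epoch time axis in ms.
#' @param pattern_gain modulation depth of the planted pattern (default 0.5).
#' @param seed RNG seed.
#' @export
meg_sim_spec <- function(planted_model, n_participants = 16L,
                         n_channels = 64L, n_trials_per_video = 32L,
                         planted_window_ms = c(600, 1500),
                         planted_freq_hz = c(4, 20),
                         effect_size = 1.5, noise_sd = 1,
                         response_type = c("induced", "evoked"),
                         sampling_rate = 100,
                         times = seq(-500, 2500, by = 10),
                         pattern_gain = 0.5, seed = 1L) {
  response_type <- match.arg(response_type)
  stopifnot(inherits(planted_model, "similarity_matrix"),
            effect_size >= 0, noise_sd >= 0,
            n_channels >= length(planted_model$stimulus_ids) + 1L)
  if (planted_window_ms[1L] < min(times) ||
      planted_window_ms[2L] > max(times))
    stop("planted window outside the epoch time axis")
  if (planted_freq_hz[2L] >= sampling_rate / 2)
    stop("planted frequencies outside the resolvable range")
  structure(as.list(environment()), class = "meg_sim_spec")
}

nearest_psd_corr <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  M2 <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  stats::cov2cor(M2)
}

planted_patterns <- function(spec) {
  # channels x stimuli patterns whose Pearson correlations across channels
  # equal the planted model exactly: orthonormal columns orthogonal to the
  # constant vector, mixed through the model's Cholesky factor
  S <- length(spec$planted_model$stimulus_ids)
  M <- nearest_psd_corr(spec$planted_model$values)
  A <- chol(M)
  G <- matrix(stats::rnorm(spec$n_channels * S), spec$n_channels, S)
  G <- sweep(G, 2L, colMeans(G))           # orthogonal to constant vector
  Q <- qr.Q(qr(G))
  X <- Q %*% A
  sweep(X, 2L, apply(X, 2L, stats::sd), `/`)   # unit-SD channel patterns
}

raised_cosine_envelope <- function(times, window, ramp_ms = 100) {
  env <- numeric(length(times))
  inside <- times >= window[1L] & times <= window[2L]
  env[inside] <- 1
  up <- inside & times < window[1L] + ramp_ms
  dn <- inside & times > window[2L] - ramp_ms
  env[up] <- (1 - cos(pi * (times[up] - window[1L]) / ramp_ms)) / 2
  env[dn] <- (1 - cos(pi * (window[2L] - times[dn]) / ramp_ms)) / 2
  env
}

#' Generate synthetic multichannel epochs with planted geometry
#'
#' Per participant, builds channel patterns whose between-stimulus Pearson
#' correlations equal the planted model matrix, then embeds them as
#' amplitude modulations of band-limited oscillations inside the planted
#' time window, on top of white sensor noise. For induced effects the
#' oscillation phase is randomised across trials (cancels in evoked
#' averages, survives in Morlet power); for evoked effects it is
#' phase-locked. Power (induced) or signed amplitude (evoked) is linear in
#' the planted pattern, so the realised pattern geometry matches the model.
#'
#' @param spec a [meg_sim_spec()].
#' @param participants which participants to generate (default all); each
#'   participant has an independent seed derived from `spec$seed`, so any
#'   subset is reproducible in isolation.
#' @return List of `epoch_set`, one per requested participant.
#' @export
generate_epochs <- function(spec, participants = seq_len(spec$n_participants)) {
  stims <- spec$planted_model$stimulus_ids
  S <- length(stims)
  n_trials <- S * spec$n_trials_per_video
  tsec <- spec$times / 1000
  env <- raised_cosine_envelope(spec$times, spec$planted_window_ms)
  n_carrier <- 3L
  carriers <- seq(spec$planted_freq_hz[1L], spec$planted_freq_hz[2L],
                  length.out = n_carrier)
  # amplitude in units of the noise SD; unit scale when noise is disabled
  base_amp <- spec$effect_size * (if (spec$noise_sd > 0) spec$noise_sd else 1)
  lapply(participants, function(p) {
    set.seed((spec$seed * 1009L + p * 7919L) %% .Machine$integer.max)
    X <- planted_patterns(spec)
    amp <- if (spec$response_type == "induced")
      base_amp * sqrt(pmax(1 + spec$pattern_gain * X, 0.04))
    else
      base_amp * (1 + spec$pattern_gain * X)
    stim_seq <- rep(stims, spec$n_trials_per_video)
    data <- array(stats::rnorm(n_trials * spec$n_channels * length(tsec),
                               0, spec$noise_sd),
                  c(n_trials, spec$n_channels, length(tsec)))
    if (spec$effect_size > 0) {
      for (tr in seq_len(n_trials)) {
        si <- match(stim_seq[tr], stims)
        phases <- if (spec$response_type == "induced")
          stats::runif(n_carrier, 0, 2 * pi) else rep(0, n_carrier)
        osc <- numeric(length(tsec))
        for (k in seq_len(n_carrier))
          osc <- osc + sin(2 * pi * carriers[k] * tsec + phases[k])
        osc <- osc / sqrt(n_carrier)
        data[tr, , ] <- data[tr, , ] +
          amp[, si] %o% (env * osc)
      }
    }
    epoch_set(data, spec$sampling_rate, spec$times, stim_seq,
              channel_names = sprintf("ch%03d", seq_len(spec$n_channels)),
              channel_types = rep("axial", spec$n_channels))
  })
}
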