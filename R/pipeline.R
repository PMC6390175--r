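# End-to-end orchestration: build the six test matrices, the behavioral
# planned-comparison table, and the sensor-level evoked / time-frequency
# RSA scans.

#' Build response cell stacks from an evoked set
#'
#' For each selected time point, the per-stimulus channel patterns are
#' correlated into a pattern-similarity matrix and vectorized.
#'
#' @param evoked an `evoked_set` from [evoked_average()].
#' @param time_idx indices into the time axis to scan (default: all
#'   post-stimulus samples).
#' @return n_pairs x n_time matrix of similarity cells; attribute `times`
#'   gives the scanned time axis (ms).
#' @export
evoked_response_cells <- function(evoked, time_idx = NULL) {
  if (is.null(time_idx)) time_idx <- which(evoked$times > 0)
  S <- length(evoked$stimulus_ids)
  out <- matrix(NA_real_, choose(S, 2L), length(time_idx))
  for (k in seq_along(time_idx)) {
    pat <- t(evoked$data[, , time_idx[k]])
    out[, k] <- vectorize(pattern_similarity_matrix(
      pat, evoked$stimulus_ids,
      context = sprintf("t=%g ms", evoked$times[time_idx[k]])))
  }
  attr(out, "times") <- evoked$times[time_idx]
  out
}

#' Build response cell stacks from baseline-corrected TF power
#'
#' One coordinate per (frequency, time) bin, frequency fastest (column-major
#' over a `c(n_freq, n_time)` map).
#'
#' @param power a baseline-corrected `tf_power`.
#' @param time_idx indices into the time axis (default: post-stimulus
#'   samples clear of wavelet edge contamination at every frequency).
#' @param freq_idx indices into the frequency axis (default: all).
#' @return n_pairs x (n_freq * n_time) matrix; attributes `times`, `freqs`,
#'   `dims`.
#' @export
tf_response_cells <- function(power, time_idx = NULL, freq_idx = NULL) {
  if (!isTRUE(power$baseline_corrected))
    warning("tf power is not baseline-corrected")
  if (is.null(freq_idx)) freq_idx <- seq_along(power$freqs)
  if (is.null(time_idx)) {
    clean <- !apply(power$edges[freq_idx, , drop = FALSE], 2L, any)
    time_idx <- which(power$times > 0 & clean)
  }
  S <- length(power$stimulus_ids)
  nf <- length(freq_idx); nt <- length(time_idx)
  out <- matrix(NA_real_, choose(S, 2L), nf * nt)
  for (ti in seq_len(nt)) {
    for (fi in seq_len(nf)) {
      pat <- t(power$data[, , freq_idx[fi], time_idx[ti]])
      out[, (ti - 1L) * nf + fi] <- vectorize(pattern_similarity_matrix(
        pat, power$stimulus_ids,
        context = sprintf("f=%s Hz, t=%g ms", power$freqs[freq_idx[fi]],
                          power$times[time_idx[ti]])))
    }
  }
  attr(out, "times") <- power$times[time_idx]
  attr(out, "freqs") <- power$freqs[freq_idx]
  attr(out, "dims") <- c(nf, nt)
  out
}

#' Build the six test similarity matrices for a stimulus set
#'
#' Identity and expression categorical models, configural form and motion
#' pattern physical measures, and form/motion perceptual judgment matrices.
#'
#' @param videos list of `landmark_video`.
#' @param fmap,triangle feature map and fiducial triangle for the motion
#'   measure.
#' @param judgments judgment pair table with a `task` column ("form",
#'   "motion"); NULL drops the two perceptual matrices.
#' @return Named list of `similarity_matrix`: identity, expression, form,
#'   motion, and (if judgments given) form_judgment, motion_judgment.
#' @export
build_test_matrices <- function(videos, fmap, triangle, judgments = NULL) {
  ids <- vapply(videos, `[[`, "", "stimulus_id")
  idl <- vapply(videos, `[[`, "", "identity_label")
  exl <- vapply(videos, `[[`, "", "expression_label")
  out <- list(
    identity = category_model_matrix(idl, ids, idl, exl),
    expression = category_model_matrix(exl, ids, idl, exl),
    form = build_form_similarity_matrix(videos),
    motion = build_motion_similarity_matrix(videos, fmap, triangle))
  if (!is.null(judgments)) {
    out$form_judgment <- judgment_matrix(
      judgments[judgments$task == "form", ], ids, idl, exl)
    out$motion_judgment <- judgment_matrix(
      judgments[judgments$task == "motion", ], ids, idl, exl)
  }
  out
}

planned_comparison_pairs <- function() {
  # the 13 planned comparisons among the six test matrices
  rbind(
    c("form_judgment", "motion_judgment"),
    c("form_judgment", "identity"), c("form_judgment", "expression"),
    c("motion_judgment", "identity"), c("motion_judgment", "expression"),
    c("form", "identity"), c("form", "expression"),
    c("motion", "identity"), c("motion", "expression"),
    c("form", "form_judgment"), c("form", "motion_judgment"),
    c("motion", "form_judgment"), c("motion", "motion_judgment"))
}

#' Behavioral RSA: planned comparisons among the six test matrices
#'
#' Spearman correlations over the S(S-1)/2 off-diagonal cells for the 13
#' planned pairs (judgments vs each other; judgments vs category models;
#' physical measures vs category models; physical vs corresponding
#' perceptual measures), with right-sided asymptotic p-values (positive
#' relationships are the only interpretable direction for similarities) and
#' Bonferroni flags.
#'
#' @param matrices named list from [build_test_matrices()] including the
#'   judgment matrices.
#' @param alpha nominal level for the Bonferroni flag (default 0.05).
#' @return data.frame: matrix_a, matrix_b, n_cells, rho, p, significant,
#'   significant_bonferroni.
#' @export
run_behavioral_rsa <- function(matrices, alpha = 0.05) {
  pairs <- planned_comparison_pairs()
  missing <- setdiff(unique(as.vector(pairs)), names(matrices))
  if (length(missing))
    stop("missing test matrix(es): ", paste(missing, collapse = ", "))
  cells <- lapply(matrices, vectorize)
  n <- length(cells[[1L]])
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    rho <- spearman_rsa(cells[[pairs[i, 1L]]], cells[[pairs[i, 2L]]])
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    data.frame(matrix_a = pairs[i, 1L], matrix_b = pairs[i, 2L],
               n_cells = n, rho = rho, p = p)
  })
  res <- do.call(rbind, res)
  res$significant <- res$p < alpha
  res$significant_bonferroni <- res$p < alpha / nrow(res)
  res
}

#' Sensor-level MEG RSA scan over a participant group
#'
#' Runs the full chain for each requested model matrix: artifact rejection,
#' then either evoked averaging (per-time-point scan, Butterworth-smoothed)
#' or Morlet power with log-ratio baseline (time-frequency scan,
#' Gaussian-smoothed), pattern-similarity cells, (partial) Spearman RSA,
#' Fisher z, group t, TFCE and sign-flip permutation correction.
#'
#' @param epochs_list list of `epoch_set`, one per participant.
#' @param models named list of `similarity_matrix` model matrices to test.
#' @param controls optional named list of `similarity_matrix` to partial out
#'   of every model test.
#' @param analysis "evoked" or "time-frequency".
#' @param freqs frequency grid for the time-frequency analysis.
#' @param time_step_ms RSA time-grid spacing for the time-frequency scan;
#'   the scan runs on every `time_step_ms` milliseconds of the post-stimulus
#'   axis (default 10). The evoked scan always uses the native sample grid:
#'   its Butterworth smoothing needs the full bandwidth.
#' @param scheme a [permutation_scheme()].
#' @param alpha familywise level.
#' @param artifact_limits c(axial, planar) rejection thresholds.
#' @param verbose log one line per stage.
#' @return Named list of `rsa_stat_map`, one per model; each carries the
#'   scan axes in `$times` (and `$freqs`).
#' @export
run_meg_rsa <- function(epochs_list, models, controls = NULL,
                        analysis = c("time-frequency", "evoked"),
                        freqs = seq(4, 50, by = 2), time_step_ms = 10,
                        scheme = permutation_scheme(), alpha = 0.05,
                        artifact_limits = c(axial = 2000, planar = 50),
                        verbose = FALSE) {
  analysis <- match.arg(analysis)
  say <- function(...) if (verbose) message(sprintf(...))
  stacks <- vector("list", length(epochs_list))
  axes <- NULL
  # response stacks key stimuli in sorted order; align the model matrices
  stim_order <- sort(unique(epochs_list[[1L]]$stimulus_id))
  models <- lapply(models, reorder_similarity, stimulus_ids = stim_order)
  if (!is.null(controls))
    controls <- lapply(controls, reorder_similarity,
                       stimulus_ids = stim_order)
  for (p in seq_along(epochs_list)) {
    t0 <- proc.time()[3L]
    ep <- reject_artifacts(epochs_list[[p]], artifact_limits[[1L]],
                           artifact_limits[[2L]])
    if (analysis == "evoked") {
      ev <- evoked_average(ep)
      keep <- which(ev$times > 0)
      cells <- evoked_response_cells(ev, keep)
      axes <- list(times = attr(cells, "times"), dims = NULL,
                   sampling_rate = epochs_list[[1L]]$sampling_rate)
    } else {
      pw <- log_ratio_baseline(morlet_power(ep, freqs))
      clean <- !apply(pw$edges, 2L, any)
      keep <- which(pw$times > 0 & clean &
                      (pw$times %% time_step_ms == 0))
      cells <- tf_response_cells(pw, time_idx = keep)
      axes <- list(times = attr(cells, "times"),
                   freqs = attr(cells, "freqs"),
                   dims = attr(cells, "dims"))
    }
    stacks[[p]] <- cells
    say("participant %d: %d trials -> %d coords [%.1f s]", p,
        dim(ep$data)[1L], ncol(cells), proc.time()[3L] - t0)
  }
  smoothing <- if (analysis == "evoked")
    list(sampling_rate = axes$sampling_rate, cutoff = 10, order = 5L)
  else
    list(freq_step = diff(axes$freqs[1:2]),
         time_step = diff(axes$times[1:2]), fwhm_freq = 4, fwhm_time = 20)
  out <- lapply(names(models), function(nm) {
    t0 <- proc.time()[3L]
    map <- rsa_scan(stacks, models[[nm]], controls = controls,
                    dims = axes$dims, smoothing = smoothing,
                    scheme = scheme, alpha = alpha)
    map$times <- axes$times
    map$freqs <- axes$freqs
    say("model %s: %d significant coords [%.1f s]", nm, sum(map$mask),
        proc.time()[3L] - t0)
    map
  })
  stats::setNames(out, names(models))
}

#' Run manifest
#'
#' Records everything needed to reproduce a run: the configuration, the
#' seed, every decided parameter and package version; two runs with equal
#' manifests produce equal outputs.
#'
#' @param config named list of run parameters.
#' @param file path for the JSON manifest.
#' @export
write_manifest <- function(config, file) {
  cfg_file <- tempfile()
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = config[order(names(config))],
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("facersa")),
    r_version = R.version.string)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
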