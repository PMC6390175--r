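# Plain-text interchange formats: delimited tables for landmarks, feature
# maps, judgments and similarity matrices; flat numeric dump + JSON sidecar
# for epoch arrays. All round-trip tested.

#' Write / read a landmark video as delimited text
#'
#' Columns: frame (1-based), landmark_id, x, y. One file per stimulus;
#' identity/expression labels travel in a separate stimulus table (see
#' [write_stimulus_table()]).
#'
#' @param video a `landmark_video`.
#' @param file path.
#' @export
write_landmark_video <- function(video, file) {
  rows <- do.call(rbind, lapply(seq_along(video$frames), function(f) {
    co <- video$frames[[f]]$coords
    data.frame(frame = f, landmark_id = rownames(co),
               x = co[, 1L], y = co[, 2L])
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_landmark_video
#' @param frame_rate,stimulus_id,identity_label,expression_label metadata
#'   not stored in the landmark file itself.
#' @export
read_landmark_video <- function(file, frame_rate, stimulus_id,
                                identity_label = NA, expression_label = NA) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character",
                                          "numeric", "numeric"))
  frames <- lapply(split(tab, tab$frame), function(fr)
    landmark_frame(cbind(fr$x, fr$y), fr$landmark_id))
  landmark_video(frames[order(as.integer(names(frames)))], frame_rate,
                 stimulus_id, identity_label, expression_label)
}

#' Write / read the stimulus metadata table
#' @param videos list of `landmark_video`.
#' @param file path.
#' @export
write_stimulus_table <- function(videos, file) {
  tab <- data.frame(
    stimulus_id = vapply(videos, `[[`, "", "stimulus_id"),
    identity = vapply(videos, `[[`, "", "identity_label"),
    expression = vapply(videos, `[[`, "", "expression_label"))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_stimulus_table
#' @export
read_stimulus_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    colClasses = "character")
}

#' Write / read a similarity matrix as square delimited text
#'
#' First row and column hold stimulus ids; `#key=value` comment lines carry
#' the kind tag and per-stimulus labels.
#'
#' @param m a `similarity_matrix`.
#' @param file path.
#' @export
write_similarity_matrix <- function(m, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", m$kind), con)
  writeLines(paste0("#identity=", paste(m$identity, collapse = ",")), con)
  writeLines(paste0("#expression=", paste(m$expression, collapse = ",")), con)
  utils::write.table(format(m$values, digits = 17), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(file)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", row.names = 1L, check.names = FALSE)
  vals <- as.matrix(tab)
  similarity_matrix(vals, rownames(vals),
                    identity = strsplit(meta$identity %||% "", ",")[[1L]],
                    expression = strsplit(meta$expression %||% "", ",")[[1L]],
                    kind = meta$kind %||% "physical")
}

#' Write / read a feature map (feature_name, landmark_id rows)
#' @param fmap a `feature_map`.
#' @param file path.
#' @export
write_feature_map <- function(fmap, file) {
  tab <- data.frame(
    feature_name = rep(names(fmap$features), lengths(fmap$features)),
    landmark_id = unlist(fmap$features, use.names = FALSE))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           colClasses = "character")
  feature_map(split(tab$landmark_id, tab$feature_name))
}

#' Write / read a judgment pair table
#' @param table data.frame participant, stim_a, stim_b, rating, task.
#' @param file path.
#' @export
write_judgment_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_judgment_table
#' @export
read_judgment_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "numeric", "character"))
}

#' Write / read an epoch set (flat numeric dump + JSON metadata sidecar)
#'
#' `file` holds one line per trial (channels x time values, time fastest,
#' space-separated); `paste0(file, ".json")` holds the metadata. An import
#' adapter for a standard MEG reader can produce the same `epoch_set`
#' in memory and skip these files entirely.
#'
#' @param epochs an `epoch_set`.
#' @param file path for the numeric dump.
#' @export
write_epoch_set <- function(epochs, file) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = d[1L],
                 byrow = TRUE)
  utils::write.table(flat, file, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(dims = d, sampling_rate = epochs$sampling_rate,
               times = epochs$times, stimulus_id = epochs$stimulus_id,
               channel_names = epochs$channel_names,
               channel_types = epochs$channel_types)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file, header = FALSE, sep = " "))
  d <- meta$dims
  data <- aperm(array(t(flat), c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  epoch_set(data, meta$sampling_rate, meta$times, meta$stimulus_id,
            meta$channel_names, meta$channel_types)
}

#' Write an RSA stat map as delimited text plus run metadata
#'
#' Emits `<file>` with one row per map coordinate (coordinate indices, mean
#' rho, t, TFCE, corrected p, significance flag) and `<file>.meta.json`
#' capturing every decided parameter.
#'
#' @param map an `rsa_stat_map` from [rsa_scan()].
#' @param file path.
#' @param coord_labels optional data.frame of per-coordinate labels (e.g.
#'   time_ms, freq_hz) cbound in front of the statistics.
#' @export
write_rsa_results <- function(map, file, coord_labels = NULL) {
  tab <- data.frame(coord = seq_len(prod(map$dims)),
                    rho_mean = as.vector(map$rho_mean),
                    t = as.vector(map$t),
                    tfce = as.vector(map$tfce),
                    p = as.vector(map$p),
                    significant = as.vector(map$mask))
  if (!is.null(coord_labels)) tab <- cbind(coord_labels, tab)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(map$params, list(alpha = map$alpha,
                                          dims = map$dims)),
                       paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
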