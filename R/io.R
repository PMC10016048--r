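# Plain-text readers/writers for the pipeline's interchange formats and an
# optional HDF5 epoch export (rhdf5, if installed).

#' Write / read a behavioral events table
#'
#' Columns: `block_id`, `trial_idx`, `onset_ms`, `trial_type`, `response_ms`
#' (empty = no response), `motor_condition` and, when present,
#' `participant_id`.
#'
#' @param trials trial data.frame
#' @param path CSV file path
#' @return `write_events_csv`: the path, invisibly; `read_events_csv`: the
#'   trial data.frame
#' @export
write_events_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$response_ms <- as.numeric(tr$response_ms)
  tr
}

#' Write / read a gait trace
#'
#' Columns: `t` (s), `X`, `Y`, `Z` (m); foot and sample rate are carried in
#' a header comment line.
#'
#' @param trace a `gait_trace`
#' @param path CSV file path
#' @export
write_gait_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# foot=%s sample_rate_hz=%g", trace$foot,
                     trace$sample_rate_hz), con)
  write.csv(data.frame(t = trace$t, trace$xyz), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_csv
#' @export
read_gait_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  foot <- sub(".*foot=(\\S+).*", "\\1", hdr)
  fs <- as.numeric(sub(".*sample_rate_hz=([0-9.]+).*", "\\1", hdr))
  df <- read.csv(path, skip = 1)
  structure(list(foot = foot, sample_rate_hz = fs, t = df$t,
                 xyz = as.matrix(df[, c("X", "Y", "Z")])),
            class = "gait_trace")
}

#' Export an epoch set to HDF5 (requires the rhdf5 package)
#'
#' Datasets: `data` (epoch x channel x time), `channels`, `positions`,
#' `time_ms`, plus scalar attributes `sample_rate_hz`, `lock`, `condition`.
#'
#' @param epochs an [epoch_set()]
#' @param path output .h5 file
#' @export
write_epochs_h5 <- function(epochs, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop_mobidt("missing_dep", "rhdf5 is required for HDF5 export")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$montage$label, path, "channels")
  rhdf5::h5write(as.matrix(epochs$montage[, c("x", "y", "z")]), path, "positions")
  rhdf5::h5write(epochs$time_ms, path, "time_ms")
  rhdf5::h5write(epochs$sample_rate_hz, path, "sample_rate_hz")
  rhdf5::h5write(epochs$lock, path, "lock")
  rhdf5::h5write(epochs$condition, path, "condition")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Serialize a cluster result to JSON
#'
#' @param result a `cluster_result`
#' @param path output .json file
#' @export
write_cluster_json <- function(result, path) {
  out <- list(
    t_thresh = result$t_thresh,
    n_permutations = result$n_permutations,
    alpha = result$alpha,
    wcm_weight = result$wcm_weight,
    clusters = lapply(result$clusters, function(cl)
      list(sign = cl$sign, mass = cl$mass, p_perm = cl$p_perm,
           members = apply(cl$members, 1, as.list))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
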