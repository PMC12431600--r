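# Plain-text interchange: displacement traces and feature tables as CSV.

#' Write a displacement trace to CSV
#'
#' Columns `time_s`, `displacement_px`.
#'
#' @param trace A [displacement_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "displacement_trace"))
  write.csv(data.frame(time_s = trace$time,
                       displacement_px = trace$value),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a displacement trace from CSV
#'
#' Expects columns `time_s` and `displacement_px`; the sampling rate is
#' inferred from the median time step.
#'
#' @param path CSV file.
#' @return A [displacement_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "displacement_px") %in% names(d))) {
    stop("expected columns time_s and displacement_px")
  }
  dt <- median(diff(d$time_s))
  displacement_trace(d$time_s, d$displacement_px, sampling_rate = 1 / dt)
}

#' Write a feature table to CSV
#'
#' @param features Data frame with columns `fruit_id`, `stage`,
#'   `damping_ratio`, `natural_frequency_hz`, `firmness_mpa` (extra columns
#'   are preserved).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV file with at least `damping_ratio` and
#'   `natural_frequency_hz` columns.
#' @return A data frame.
#' @export
read_features_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("damping_ratio", "natural_frequency_hz")
  if (!all(need %in% names(d))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  d
}
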