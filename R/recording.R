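#' Construct an aEEG recording
#'
#' A recording holds a rectified aEEG amplitude series in microvolts with a
#' constant sample interval and an optional class label. Amplitudes must be
#' finite and non-negative (aEEG is rectified before display), and a series
#' must contain at least two samples.
#'
#' @param samples numeric vector of amplitudes in microvolts.
#' @param sample_interval seconds per sample (> 0). Default 1 s: the CFM's
#'   time-compressed aEEG trend trace is slow, so 1 Hz is a natural canonical
#'   rate for the amplitude envelope.
#' @param id identifier string.
#' @param label optional `"normal"` or `"abnormal"`.
#' @return an object of class `aeeg_recording`.
#' @examples
#' rec <- aeeg_recording(c(12.5, 13, 11.8))
#' duration_s(rec)
#' @export
aeeg_recording <- function(samples, sample_interval = 1.0, id = "recording",
                           label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a recording needs at least 2 samples, got ", length(samples))
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("recording amplitudes must be finite")
  }
  if (any(samples < 0)) {
    stop("recording amplitudes must be >= 0 microvolts (aEEG is rectified); ",
         "first offending index: ", which(samples < 0)[1L])
  }
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop("sample_interval must be a single positive number of seconds")
  }
  if (!is.null(label)) {
    label <- match.arg(label, AEEG_CLASSES)
  }
  structure(
    list(id = as.character(id)[1L], samples = samples,
         sample_interval = as.numeric(sample_interval), label = label),
    class = "aeeg_recording"
  )
}

#' @export
print.aeeg_recording <- function(x, ...) {
  cat(sprintf(
    "<aeeg_recording '%s'> %d samples @ %.4g s (%.1f s total)%s\n",
    x$id, length(x$samples), x$sample_interval, duration_s(x),
    if (is.null(x$label)) "" else paste0(", label: ", x$label)
  ))
  invisible(x)
}

#' Recording duration in seconds
#'
#' Duration is the time span covered by the samples,
#' `n * sample_interval`, i.e. each sample represents one interval.
#'
#' @param rec an [aeeg_recording()].
#' @return duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "aeeg_recording"))
  length(rec$samples) * rec$sample_interval
}

is_recording <- function(x) inherits(x, "aeeg_recording")
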