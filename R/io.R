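#' Read an aEEG recording from disk
#'
#' CSV is the canonical storage format: a header `time_s,amplitude_uV`
#' followed by one row per sample, UTF-8, `.` decimal. The sample interval is
#' inferred as the median difference of the time column. EDF/EDF+ files are
#' read through a minimal single-channel reader ([read_edf_channel()]) with
#' digital-to-physical scaling applied, so values arrive in microvolts.
#'
#' Recordings shorter than `warn_below_s` trigger a warning, not an error:
#' clinical traces are nominally 3 hours, but short recordings are legitimate
#' for testing and exploration.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`.
#' @param id recording id; defaults to the file name without extension.
#' @param warn_below_s warn when the recording is shorter than this many
#'   seconds (default 10800 = 3 h).
#' @return an [aeeg_recording()]; the label slot is always empty (labels
#'   travel in manifests, not in signal files).
#' @export
read_recording <- function(path, format = c("csv", "edf"), id = NULL,
                           warn_below_s = 10800) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  rec <- switch(format,
    csv = read_recording_csv(path, id),
    edf = read_edf_channel(path, id = id)
  )
  if (duration_s(rec) < warn_below_s) {
    warning(sprintf("recording '%s' is %.0f s, shorter than %.0f s",
                    rec$id, duration_s(rec), warn_below_s))
  }
  rec
}

read_recording_csv <- function(path, id) {
  df <- tryCatch(
    read.csv(path, header = TRUE, colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("expected columns time_s,amplitude_uV in ", path)
  time <- df[[1L]]
  amp <- df[[2L]]
  bad <- which(!is.finite(time) | !is.finite(amp))
  if (length(bad)) {
    stop("malformed row in ", path, " at data line ", bad[1L])
  }
  if (length(time) >= 2L && any(diff(time) <= 0)) {
    stop("time column must be strictly increasing in ", path,
         " (violation near data line ", which(diff(time) <= 0)[1L] + 1L, ")")
  }
  interval <- if (length(time) >= 2L) median(diff(time)) else 1.0
  aeeg_recording(amp, sample_interval = interval, id = id)
}

#' Write an aEEG recording as CSV
#'
#' Writes the canonical `time_s,amplitude_uV` layout readable by
#' [read_recording()]. Round-tripping preserves amplitudes at the stored
#' precision (15 significant digits).
#'
#' @param rec an [aeeg_recording()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(is_recording(rec))
  time <- seq(0, by = rec$sample_interval, length.out = length(rec$samples))
  lines <- c("time_s,amplitude_uV",
             paste(format(time, digits = 15, trim = TRUE, scientific = FALSE),
                   format(rec$samples, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = ","))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Minimal EDF/EDF+ single-channel reader
#'
#' Parses the fixed-layout ASCII EDF header and the 16-bit little-endian
#' sample records of one signal, applying the digital-to-physical calibration
#' so amplitudes come back in the physical unit of the channel (microvolts
#' for aEEG exports). Annotation channels ("EDF Annotations") are skipped
#' when picking a default channel.
#'
#' @param path EDF file path.
#' @param channel 1-based signal index; default picks the first non-annotation
#'   signal.
#' @param id recording id.
#' @return an [aeeg_recording()].
#' @export
read_edf_channel <- function(path, channel = NULL, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr_txt <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  hdr_txt(8)                               # version
  hdr_txt(80); hdr_txt(80)                 # patient, recording ids
  hdr_txt(8); hdr_txt(8)                   # start date, time
  header_bytes <- as.integer(hdr_txt(8))
  hdr_txt(44)                              # reserved
  n_records <- as.integer(hdr_txt(8))
  record_duration <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1L) stop("not an EDF file (bad signal count): ", path)
  field <- function(width) vapply(seq_len(ns), function(i) hdr_txt(width), "")
  labels <- field(16)
  field(80); field(8)                      # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                # prefiltering
  samples_per_rec <- as.integer(field(8))
  field(32)                                # reserved
  if (is.null(channel)) {
    channel <- which(!grepl("annotation", labels, ignore.case = TRUE))[1L]
    if (is.na(channel)) stop("no data signal in EDF file: ", path)
  }
  if (channel < 1L || channel > ns) stop("EDF channel out of range: ", channel)
  seek(con, header_bytes)
  gain <- (phys_max[channel] - phys_min[channel]) /
    (dig_max[channel] - dig_min[channel])
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = samples_per_rec[s], size = 2L,
                      signed = TRUE, endian = "little")
      if (s == channel) {
        out[[r]] <- phys_min[channel] + gain * (vals - dig_min[channel])
      }
    }
  }
  amp <- unlist(out, use.names = FALSE)
  interval <- record_duration / samples_per_rec[channel]
  aeeg_recording(amp, sample_interval = interval, id = id)
}

#' Write a combined-feature matrix as CSV
#'
#' One row per recording: the 119 named feature columns in the fixed order
#' basic(4), histogram(55), segment(60), plus a final `label` column. Column
#' names come from [combined_feature_names()] and are stable across calls.
#'
#' @param vectors a list of 119-long named numeric vectors (or a matrix with
#'   119 columns).
#' @param labels character vector of class labels, one per vector.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(vectors, labels, path) {
  if (is.matrix(vectors)) {
    vectors <- lapply(seq_len(nrow(vectors)), function(i) vectors[i, ])
  }
  if (length(vectors) != length(labels)) {
    stop("vectors and labels differ in length (", length(vectors), " vs ",
         length(labels), ")")
  }
  nm <- combined_feature_names()
  lens <- lengths(vectors)
  if (any(lens != length(nm))) {
    stop("every feature vector must have ", length(nm), " entries; found ",
         "lengths ", paste(unique(lens[lens != length(nm)]), collapse = ", "))
  }
  mat <- do.call(rbind, vectors)
  colnames(mat) <- nm
  df <- data.frame(mat, check.names = FALSE)
  df$label <- as.character(labels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a combined-feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return list with `x` (numeric matrix, 119 named columns) and `labels`
#'   (character vector; `NA` where the label column is empty).
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no label column in ", path)
  lab <- as.character(df$label)
  x <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(x) <- "double"
  list(x = x, labels = lab)
}
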