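# Shared fixtures built in code. Expensive synthetic feature matrices are
# cached per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# Labeled feature matrix from a synthetic cohort (full-length recordings).
cached_features <- function(n_normal, n_abnormal, seed, duration_s = 10800) {
  key <- paste(n_normal, n_abnormal, seed, duration_s, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthesis_config(duration_s = duration_s, seed = seed)
    recs <- make_dataset(n_normal, n_abnormal, cfg)
    .fixture_cache[[key]] <- extract_dataset(recs)
  }
  .fixture_cache[[key]]
}

# Small two-class Gaussian feature matrix (no recordings involved) for
# forest mechanics tests where only the bootstrap/split machinery matters.
toy_matrix <- function(n_per_class = 30, p = 5, shift = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = shift), n_per_class))
  colnames(x) <- paste0("f", seq_len(p))
  labels <- rep(c("abnormal", "normal"), each = n_per_class)
  list(x = x, labels = labels)
}

# Minimal single-signal EDF writer for reader tests: one channel, int16
# little-endian, physical scaling chosen by the caller.
write_tiny_edf <- function(path, samples_physical, phys_min = 0,
                           phys_max = 100, dig_min = -32768L,
                           dig_max = 32767L, record_duration = 10,
                           samples_per_record = 10) {
  stopifnot(length(samples_physical) %% samples_per_record == 0)
  n_records <- length(samples_physical) / samples_per_record
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  header <- paste0(
    pad("0", 8), pad("patient", 80), pad("recording", 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(256 + 256, 8), pad("", 44), pad(n_records, 8),
    pad(record_duration, 8), pad(1, 4),
    pad("aEEG", 16), pad("CFM", 80), pad("uV", 8),
    pad(phys_min, 8), pad(phys_max, 8), pad(dig_min, 8), pad(dig_max, 8),
    pad("none", 80), pad(samples_per_record, 8), pad("", 32))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- as.integer(round((samples_physical - phys_min) / gain + dig_min))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
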