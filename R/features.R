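#' Segment a recording with an overlapping window
#'
#' Overlapping windows catch transient structure (bursts, suppressions) that
#' whole-recording statistics wash out. Defaults: 3-minute windows advanced
#' by 1.5 minutes, i.e. 50% overlap. A recording of duration `L` seconds
#' yields `floor((L - window_s) / step_s) + 1` segments; a nominal 3-hour
#' trace gives 119.
#'
#' @param rec an [aeeg_recording()].
#' @param window_s window length in seconds (default 180).
#' @param step_s step between window starts in seconds (default 90).
#' @return list of segments, each a list with `index` (0-based), `start_s`,
#'   and `samples`.
#' @export
segment_recording <- function(rec, window_s = 180, step_s = 90) {
  stopifnot(is_recording(rec), step_s > 0, window_s > 0)
  L <- duration_s(rec)
  if (L < window_s) {
    stop(sprintf("recording (%.0f s) shorter than window (%.0f s)",
                 L, window_s))
  }
  win_n <- as.integer(round(window_s / rec$sample_interval))
  step_n <- as.integer(round(step_s / rec$sample_interval))
  if (step_n < 1L) stop("step_s smaller than one sample interval")
  n_seg <- as.integer(floor((L - window_s) / step_s)) + 1L
  lapply(seq_len(n_seg) - 1L, function(k) {
    from <- k * step_n + 1L
    list(index = k, start_s = k * step_s,
         samples = rec$samples[from:(from + win_n - 1L)])
  })
}

# Local-extremum linear interpolation: one envelope pass. Endpoints are
# always treated as extrema so the interpolant covers the full support.
envelope_pass <- function(x, upper = TRUE) {
  n <- length(x)
  if (n < 3L) stop("envelope needs at least 3 samples")
  mid <- 2:(n - 1L)
  is_ext <- if (upper) {
    x[mid] >= x[mid - 1L] & x[mid] >= x[mid + 1L]
  } else {
    x[mid] <= x[mid - 1L] & x[mid] <= x[mid + 1L]
  }
  idx <- c(1L, mid[is_ext], n)
  approx(idx, x[idx], xout = seq_len(n), method = "linear")$y
}

#' Second-order envelope of an amplitude series
#'
#' Two iterated passes of local-extremum linear interpolation: the first
#' pass connects the local maxima (minima) of the signal, the second pass
#' connects the local maxima (minima) of that envelope, yielding a smoother
#' outer hull. Endpoints count as extrema in both passes. For a constant
#' series both envelopes equal the series.
#'
#' @param samples numeric amplitude vector, length >= 3.
#' @return list with `upper` and `lower`, both the same length as `samples`.
#' @export
second_order_envelope <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) stop("need at least 3 samples for an envelope")
  upper <- envelope_pass(envelope_pass(samples, TRUE), TRUE)
  lower <- envelope_pass(envelope_pass(samples, FALSE), FALSE)
  list(upper = upper, lower = lower)
}

#' Approximate entropy parameters
#'
#' Standard Pincus conventions: embedding length `m = 2`, tolerance
#' `r = r_frac * SD` of the analyzed segment, Chebyshev (max-coordinate)
#' distance, self-matches included. With self-matches every count is >= 1,
#' so the statistic is finite and non-negative.
#'
#' @param m embedding (comparison window) length, integer >= 1.
#' @param r_frac tolerance as a fraction of the segment standard deviation
#'   (used when `r` is `NULL`).
#' @param r absolute tolerance in signal units; overrides `r_frac`.
#' @return a list of class `apen_params`.
#' @export
apen_params <- function(m = 2L, r_frac = 0.2, r = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (!is.null(r) && r <= 0) stop("r must be > 0")
  if (is.null(r) && (!is.numeric(r_frac) || r_frac <= 0)) {
    stop("r_frac must be > 0")
  }
  structure(list(m = m, r_frac = r_frac, r = r), class = "apen_params")
}

resolve_r <- function(params, samples) {
  if (!is.null(params$r)) return(params$r)
  s <- sd(samples)
  # A constant (zero-variance) segment has no scale; any positive tolerance
  # gives ApEn = 0 there, so fall back to an arbitrary unit tolerance.
  if (!is.finite(s) || s == 0) 1.0 else params$r_frac * s
}

#' Approximate entropy of an amplitude series
#'
#' ApEn(m, r, N) = Phi_m(r) - Phi_{m+1}(r), where Phi_m(r) is the average
#' natural log of the fraction of m-length template vectors lying within
#' Chebyshev distance r of each template (self-match included). Low values
#' mean the series is regular (patterns repeat); higher values mean
#' irregularity. A constant series scores exactly 0.
#'
#' @param samples numeric vector, length >= m + 2.
#' @param params an [apen_params()].
#' @return a single non-negative number.
#' @export
apen <- function(samples, params = apen_params()) {
  stopifnot(inherits(params, "apen_params"))
  samples <- as.numeric(samples)
  N <- length(samples)
  if (N < params$m + 2L) {
    stop("need at least m + 2 = ", params$m + 2L, " samples, got ", N)
  }
  r <- resolve_r(params, samples)
  if (r <= 0) stop("tolerance r must be > 0")
  apen_cpp(samples, params$m, r)
}

#' Basic whole-recording features
#'
#' Four clinically interpretable summaries of the full trace: minimum,
#' maximum and mean amplitude, and the percentage of the recording-level
#' second-order lower envelope lying strictly below 5 microvolts (a
#' persistently depressed lower margin is the classical sign of abnormal
#' background).
#'
#' @param rec an [aeeg_recording()].
#' @return named numeric vector of length 4:
#'   `basic_min`, `basic_max`, `basic_mean`, `basic_pct_low_margin`.
#' @export
basic_features <- function(rec) {
  stopifnot(is_recording(rec))
  env <- second_order_envelope(rec$samples)
  c(basic_min = min(rec$samples),
    basic_max = max(rec$samples),
    basic_mean = mean(rec$samples),
    basic_pct_low_margin = 100 * mean(env$lower < 5))
}

#' Amplitude-histogram features
#'
#' The amplitude distribution is summarized with finer resolution where the
#' clinical signal lives: 1 microvolt bins over [0, 50) — fifty bins — and
#' 10 microvolt bins above, [50,60), [60,70), [70,80), [80,90), with the
#' last bin open-ended [90, Inf) so no sample is dropped. Counts are
#' normalized to proportions so recordings of different lengths are
#' comparable; the 55 proportions sum to 1.
#'
#' @param rec an [aeeg_recording()].
#' @return named numeric vector of 55 proportions (`hist_000` .. `hist_054`).
#' @export
histogram_features <- function(rec) {
  stopifnot(is_recording(rec))
  breaks <- c(0:50, seq(60, 90, by = 10), Inf)
  counts <- tabulate(findInterval(rec$samples, breaks), nbins = 55L)
  p <- counts / length(rec$samples)
  names(p) <- sprintf("hist_%03d", 0:54)
  p
}

#' Per-segment features
#'
#' For each segment: the upper and lower boundary (mean of the second-order
#' upper/lower envelope over the segment), the mean amplitude, and the
#' approximate entropy.
#'
#' @param segments output of [segment_recording()].
#' @param params an [apen_params()].
#' @return data.frame with columns `index`, `start_s`, `upper_boundary`,
#'   `lower_boundary`, `mean_value`, `apen`.
#' @export
segment_feature_table <- function(segments, params = apen_params()) {
  if (length(segments) == 0L) stop("empty segment list")
  rows <- lapply(segments, function(seg) {
    res <- tryCatch({
      env <- second_order_envelope(seg$samples)
      data.frame(index = seg$index, start_s = seg$start_s,
                 upper_boundary = mean(env$upper),
                 lower_boundary = mean(env$lower),
                 mean_value = mean(seg$samples),
                 apen = apen(seg$samples, params))
    }, error = function(e) {
      stop("segment ", seg$index, ": ", conditionMessage(e), call. = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Select segment features by approximate-entropy rank
#'
#' Extreme ApEn — unusually high irregularity or unusually high regularity —
#' flags likely-abnormal stretches, so only the segments with the ten
#' highest and five lowest ApEn values are kept. Rows are sorted ascending
#' by ApEn (ties broken by segment index); output order is top ranks 1..10
#' (rank 1 = highest ApEn) then bottom ranks 1..5 (rank 1 = lowest ApEn),
#' each contributing (upper, lower, mean, apen): 60 values.
#'
#' @param table output of [segment_feature_table()].
#' @param n_top,n_bottom how many highest/lowest-ApEn segments to keep.
#' @return named numeric vector of length `4 * (n_top + n_bottom)`.
#' @export
select_segments_by_apen <- function(table, n_top = 10L, n_bottom = 5L) {
  need <- n_top + n_bottom
  if (nrow(table) < need) {
    stop("need at least ", need, " segments, got ", nrow(table))
  }
  ord <- order(table$apen, table$index)   # ascending, stable in index
  sorted <- table[ord, ]
  top <- sorted[nrow(sorted):(nrow(sorted) - n_top + 1L), ]  # rank 1 = max
  bottom <- sorted[seq_len(n_bottom), ]                      # rank 1 = min
  sel <- rbind(top, bottom)
  ranks <- c(sprintf("top%02d", seq_len(n_top)),
             sprintf("bot%02d", seq_len(n_bottom)))
  out <- numeric(0)
  for (i in seq_len(nrow(sel))) {
    v <- c(sel$upper_boundary[i], sel$lower_boundary[i],
           sel$mean_value[i], sel$apen[i])
    names(v) <- paste0("seg_", ranks[i], "_",
                       c("upper", "lower", "mean", "apen"))
    out <- c(out, v)
  }
  out
}

#' Extraction configuration
#'
#' @param window_s,step_s segmentation window and step in seconds.
#' @param apen embedding/tolerance settings, an [apen_params()].
#' @param n_top,n_bottom ApEn selection counts.
#' @return list of class `aeeg_extract_config`.
#' @export
extract_config <- function(window_s = 180, step_s = 90,
                           apen = apen_params(), n_top = 10L, n_bottom = 5L) {
  structure(list(window_s = window_s, step_s = step_s, apen = apen,
                 n_top = as.integer(n_top), n_bottom = as.integer(n_bottom)),
            class = "aeeg_extract_config")
}

#' Names of the combined feature vector, in canonical order
#'
#' basic(4), histogram(55), segment(60) — 119 names, stable across calls.
#'
#' @param cfg an [extract_config()].
#' @return character vector of feature names.
#' @export
combined_feature_names <- function(cfg = extract_config()) {
  ranks <- c(sprintf("top%02d", seq_len(cfg$n_top)),
             sprintf("bot%02d", seq_len(cfg$n_bottom)))
  seg <- as.vector(t(outer(paste0("seg_", ranks, "_"),
                           c("upper", "lower", "mean", "apen"), paste0)))
  c("basic_min", "basic_max", "basic_mean", "basic_pct_low_margin",
    sprintf("hist_%03d", 0:54), seg)
}

#' Extract the combined 119-feature vector
#'
#' Concatenates the basic (4), amplitude-histogram (55) and ApEn-selected
#' segment (60) blocks into one named vector of 119 features. Deterministic
#' and side-effect free.
#'
#' @param rec an [aeeg_recording()] long enough for at least
#'   `n_top + n_bottom` segments.
#' @param cfg an [extract_config()].
#' @return named numeric vector of length 119.
#' @export
extract_combined <- function(rec, cfg = extract_config()) {
  stopifnot(inherits(cfg, "aeeg_extract_config"))
  segs <- segment_recording(rec, cfg$window_s, cfg$step_s)
  tab <- segment_feature_table(segs, cfg$apen)
  out <- c(basic_features(rec), histogram_features(rec),
           select_segments_by_apen(tab, cfg$n_top, cfg$n_bottom))
  stopifnot(identical(names(out), combined_feature_names(cfg)))
  out
}

#' Extract features for a list of recordings
#'
#' @param recs list of [aeeg_recording()]s.
#' @param cfg an [extract_config()].
#' @return list with `x` (n x 119 matrix, named columns) and `labels`
#'   (character, `NA` where a recording is unlabeled).
#' @export
extract_dataset <- function(recs, cfg = extract_config()) {
  p <- length(combined_feature_names(cfg))
  x <- t(vapply(recs, extract_combined, numeric(p), cfg = cfg))
  labels <- vapply(recs, function(r) {
    if (is.null(r$label)) NA_character_ else r$label
  }, "")
  rownames(x) <- vapply(recs, function(r) r$id, "")
  list(x = x, labels = labels)
}
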