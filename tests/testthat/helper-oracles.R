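# Independent brute-force oracles, deliberately written with explicit
# nested loops so they share no code with the package implementation.

# Approximate entropy: Phi_m(r) - Phi_{m+1}(r) with Chebyshev distance and
# self-matches, evaluated by direct enumeration of all template pairs.
oracle_apen <- function(u, m, r) {
  N <- length(u)
  phi <- function(mm) {
    M <- N - mm + 1L
    total <- 0
    for (i in seq_len(M)) {
      cnt <- 0L
      for (j in seq_len(M)) {
        d <- max(abs(u[i:(i + mm - 1L)] - u[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      total <- total + log(cnt / M)
    }
    total / M
  }
  phi(m) - phi(m + 1L)
}

# Exhaustive weighted-Gini split search over every feature and every
# midpoint threshold. w is c(abnormal_weight, normal_weight); y01 codes
# abnormal as 0, normal as 1 (matching the package's internal coding).
# Ties: first (lowest feature, then lowest threshold) strictly-better-by-
# 1e-12 candidate wins, mirroring the implementation's acceptance rule.
oracle_best_split <- function(x, y01, w, min_leaf = 1L) {
  gini <- function(n0, n1) {
    W <- w[1] * n0 + w[2] * n1
    if (W == 0) return(0)
    p <- c(w[1] * n0, w[2] * n1) / W
    1 - sum(p^2)
  }
  n0 <- sum(y01 == 0L); n1 <- sum(y01 == 1L)
  parent <- gini(n0, n1)
  W <- w[1] * n0 + w[2] * n1
  best <- list(feature = NA_integer_, threshold = NA_real_, gain = 0)
  for (f in seq_len(ncol(x))) {
    vals <- sort(unique(x[, f]))
    if (length(vals) < 2L) next
    for (k in seq_len(length(vals) - 1L)) {
      thr <- (vals[k] + vals[k + 1L]) / 2
      left <- x[, f] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      l0 <- sum(y01[left] == 0L); l1 <- sum(y01[left] == 1L)
      WL <- w[1] * l0 + w[2] * l1
      WR <- W - WL
      gain <- parent - (WL / W) * gini(l0, l1) -
        (WR / W) * gini(n0 - l0, n1 - l1)
      if (gain > best$gain + 1e-12) {
        best <- list(feature = f, threshold = thr, gain = gain)
      }
    }
  }
  if (is.na(best$feature)) NULL else best
}

# Fixture suite of short series for the ApEn oracle comparison.
apen_fixture_series <- function() {
  set.seed(4242)
  out <- list(
    constant = rep(5, 20),
    period2 = rep(c(1, 2), 10),
    period3 = rep(c(0, 1, 3), each = 1, times = 8),
    ramp = seq(0, 1, length.out = 25),
    sine = 10 + 5 * sin(2 * pi * (0:40) / 8)
  )
  for (k in 1:5) {
    out[[paste0("unif", k)]] <- runif(30 + 4 * k)
    out[[paste0("walk", k)]] <- cumsum(rnorm(25 + 5 * k))
  }
  out
}
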