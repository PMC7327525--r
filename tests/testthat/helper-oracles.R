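# Independent brute-force oracles used across the suite.

# Double-loop pair-count Ripley K (no edge correction).
brute_ripley_k <- function(pts, area, d) {
  n <- nrow(pts)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < d) cnt <- cnt + 1
  }
  area / n^2 * cnt
}

# Double-loop ACF estimator.
brute_acf <- function(counts, lag) {
  mu <- mean(counts)
  n <- length(counts)
  s <- 0
  for (t in seq_len(n - lag)) s <- s + (counts[t] - mu) * (counts[t + lag] - mu)
  (s / (n - lag)) / mu^2
}

# Exhaustive between-class-variance maximiser over all cut points.
brute_otsu <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- -Inf; thr <- NA
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next
    b <- (k / n) * ((n - k) / n) * (mean(v[1:k]) - mean(v[(k + 1):n]))^2
    if (b > best) { best <- b; thr <- (v[k] + v[k + 1]) / 2 }
  }
  thr
}

# Enumeration-based unique matcher under the prominence-priority rule:
# enumerate every injective peak->event assignment within the window and pick
# the lexicographic optimum in descending-prominence peak order (matched
# beats unmatched; smaller separation beats larger; earlier event breaks
# ties). Tractable for <= 5 peaks/events.
oracle_match_count <- function(peak_times, prominences, events, window) {
  w <- window * 60
  np <- length(peak_times)
  if (np == 0 || length(events) == 0) return(0)
  ord <- order(-prominences, peak_times)
  ev <- sort(events)
  ne <- length(ev)
  options <- lapply(ord, function(i) {
    ok <- which(abs(ev - peak_times[i]) <= w)
    c(ok, NA)
  })
  best_key <- NULL; best_cnt <- 0
  grid <- expand.grid(rev(options), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    as_r <- as.integer(grid[r, ])
    used <- as_r[!is.na(as_r)]
    if (anyDuplicated(used)) next
    key <- numeric(0)
    for (q in seq_len(np)) {
      i <- ord[q]
      if (is.na(as_r[q])) key <- c(key, Inf, Inf)
      else key <- c(key, abs(ev[as_r[q]] - peak_times[i]), as_r[q])
    }
    if (is.null(best_key) || lex_less(key, best_key)) {
      best_key <- key
      best_cnt <- sum(!is.na(as_r))
    }
  }
  best_cnt
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Reference parameter set and a segment generated from the S-phase model.
ref_model1_segment <- function(noise_frac = 0, seed = 1,
                               t_grid = seq(0, 500, 30)) {
  p <- model1_params()
  y <- model1_analytic(p, t_grid)$bound
  if (noise_frac > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_frac * max(y))
  }
  list(params = p, segment = pulse_segment(t_grid, y, neb_rel = max(t_grid)))
}
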