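#' Detect local-maximum peaks with a prominence filter
#'
#' A peak is a strict local maximum (the intensity at time t exceeds both
#' neighbours, comparison distance 1). The prominence of a peak is the
#' vertical distance between the peak and its lowest contour line: on each
#' side, the signal is scanned out to the nearest higher point (or the signal
#' edge) and the minimum over that stretch taken; the prominence is the peak
#' height minus the larger of the two side minima. Peaks with prominence below
#' `prominence_threshold` are discarded. If a `smooth_fit` is supplied, peaks
#' are called on its fitted curve and an empty set is returned when the
#' track's signal-to-noise ratio is below `min_snr`.
#'
#' @param x numeric signal, or a [smooth_fit()] object.
#' @param times optional time axis (defaults to the sample index, or the fit's
#'   time axis).
#' @param prominence_threshold minimum prominence for a called peak (default
#'   0.1, the working threshold for normalised fluorescence signals).
#' @param min_snr SNR gate applied when `x` is a `smooth_fit` (default 0.1).
#' @return an object of class `peak_set`: data.frame with columns `time`,
#'   `index`, `amplitude`, `prominence`, sorted by time.
#' @export
detect_peaks <- function(x, times = NULL, prominence_threshold = 0.1,
                         min_snr = 0.1) {
  if (inherits(x, "smooth_fit")) {
    if (!is.null(x$snr) && is.finite(x$snr) && x$snr < min_snr)
      return(empty_peak_set())
    times <- times %||% x$times
    x <- x$fitted
  }
  n <- length(x)
  times <- times %||% seq_len(n)
  if (n < 3) return(empty_peak_set())
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(is_peak)) return(empty_peak_set())
  prom <- vapply(is_peak, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= prominence_threshold
  structure(data.frame(time = times[is_peak[keep]], index = is_peak[keep],
                       amplitude = x[is_peak[keep]], prominence = prom[keep]),
            class = c("peak_set", "data.frame"))
}

empty_peak_set <- function() {
  structure(data.frame(time = numeric(0), index = integer(0),
                       amplitude = numeric(0), prominence = numeric(0)),
            class = c("peak_set", "data.frame"))
}

# Lowest-contour-line prominence of the peak at index p.
peak_prominence <- function(x, p) {
  n <- length(x)
  left <- x[p]
  i <- p - 1L
  lmin <- x[p]
  while (i >= 1L && x[i] <= x[p]) { lmin <- min(lmin, x[i]); i <- i - 1L }
  rmin <- x[p]
  i <- p + 1L
  while (i <= n && x[i] <= x[p]) { rmin <- min(rmin, x[i]); i <- i + 1L }
  x[p] - max(lmin, rmin)
}

# Asymmetric-least-squares baseline (Eilers-Boelens): solves
# (W + lambda D'D) z = W y with asymmetric weights, iterated.
als_baseline <- function(y, lambda = 1e5, p = 0.01, n_iter = 10) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Robust smooth fit: linear trend plus Gaussian mixture
#'
#' Fits the oscillatory fluorescence signal `y(t)` with
#' `y = (A + B t) + sum_i C_i exp(-(t - mu_i)^2 / sigma_i^2)` (note: no
#' factor 2 in the exponent) in two steps. First the trend `(A, B)` comes from
#' a linear regression on an asymmetric-least-squares baseline of the signal;
#' second, the number of Gaussians is set from the peaks detected on the
#' de-trended signal and the mixture is fit by iterative nonlinear regression
#' under a robust Cauchy loss. Signal parameters (acceleration and
#' deceleration rates, peak and trough times) are then extracted from the
#' refit curve.
#'
#' @param y numeric intensity signal (>= 20 samples).
#' @param times time axis in seconds (default: 30 s sampling).
#' @param prominence_threshold prominence used when seeding Gaussians from the
#'   de-trended signal.
#' @param lambda,p asymmetric-baseline smoothness and asymmetry.
#' @param cauchy_c Cauchy loss scale as a multiple of the residual MAD.
#' @return an object of class `smooth_fit`: `trend` (A, B), `gaussians`
#'   (data.frame C, mu, sigma), `fitted`, `residual_sd`, `snr` (SD of the
#'   fitted oscillatory component / SD of residuals), `acceleration_rate`,
#'   `deceleration_rate`, `peak_times`, `trough_times`, `times`.
#' @export
smooth_fit <- function(y, times = seq(0, by = 30, length.out = length(y)),
                       prominence_threshold = 0.1, lambda = 1e5, p = 0.01,
                       cauchy_c = 2.385) {
  if (length(y) < 20) stop_validation("smooth_fit needs >= 20 samples")
  base <- als_baseline(y, lambda = lambda, p = p)
  tr <- stats::lm.fit(cbind(1, times), base)$coefficients
  detr <- y - (tr[1] + tr[2] * times)
  pk <- detect_peaks(detr, times, prominence_threshold = prominence_threshold)
  n_g <- nrow(pk)
  if (n_g == 0) {
    fitted <- tr[1] + tr[2] * times
    return(finish_smooth_fit(y, times, tr, data.frame(C = numeric(0),
                                                      mu = numeric(0),
                                                      sigma = numeric(0)),
                             fitted))
  }
  sig0 <- max(diff(range(times)) / (4 * n_g), mean(diff(times)))
  par0 <- c(tr[1], tr[2], rbind(pk$amplitude, pk$time, rep(sig0, n_g)))
  model_curve <- function(par, t) {
    out <- par[1] + par[2] * t
    for (i in seq_len(n_g)) {
      C <- par[2 + 3 * (i - 1) + 1]; mu <- par[2 + 3 * (i - 1) + 2]
      s <- abs(par[2 + 3 * (i - 1) + 3])
      out <- out + C * exp(-(t - mu)^2 / s^2)
    }
    out
  }
  scale0 <- stats::mad(y - model_curve(par0, times))
  if (scale0 <= 0) scale0 <- stats::sd(y) / 10 + 1e-12
  cscale <- cauchy_c * scale0
  obj <- function(par) sum(log1p(((y - model_curve(par, times)) / cscale)^2))
  opt <- stats::optim(par0, obj, method = "BFGS", control = list(maxit = 500))
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 1000))
  par <- if (opt2$value < opt$value) opt2$par else opt$par
  g <- data.frame(C = par[seq(3, by = 3, length.out = n_g)],
                  mu = par[seq(4, by = 3, length.out = n_g)],
                  sigma = abs(par[seq(5, by = 3, length.out = n_g)]))
  finish_smooth_fit(y, times, par[1:2], g, model_curve(par, times))
}

finish_smooth_fit <- function(y, times, trend, gaussians, fitted) {
  resid <- y - fitted
  osc <- fitted - (trend[1] + trend[2] * times)
  rsd <- stats::sd(resid)
  snr <- if (rsd > 0) stats::sd(osc) / rsd else Inf
  d <- diff(fitted)
  pk <- detect_peaks(fitted, times, prominence_threshold = 0)
  trough <- detect_peaks(-fitted, times, prominence_threshold = 0)
  dtv <- diff(times)
  structure(list(trend = c(A = unname(trend[1]), B = unname(trend[2])),
                 gaussians = gaussians, fitted = fitted, times = times,
                 residual_sd = rsd, snr = snr,
                 acceleration_rate = if (any(d > 0)) max(d / dtv) else 0,
                 deceleration_rate = if (any(d < 0)) max(-d / dtv) else 0,
                 peak_times = pk$time, trough_times = trough$time),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("<smooth_fit> trend=(", signif(x$trend[1], 4), ", ",
      signif(x$trend[2], 4), "), ", nrow(x$gaussians), " gaussians, snr=",
      signif(x$snr, 3), "\n", sep = "")
  invisible(x)
}

#' Exact 1-D Otsu threshold
#'
#' Exhaustively maximises the between-class variance
#' `w1 * w2 * (mu1 - mu2)^2` over all cut points between consecutive sorted
#' values (exact for sample-sized inputs; no histogram binning).
#'
#' @param values numeric vector (>= 2 distinct values).
#' @return threshold placed midway between the two classes' boundary values.
#' @export
otsu_threshold <- function(values) {
  v <- sort(values)
  n <- length(v)
  if (n < 2 || v[1] == v[n])
    stop_validation("Otsu threshold undefined for constant values")
  best <- -Inf; thr <- NA_real_
  for (k in seq_len(n - 1)) {
    if (v[k] == v[k + 1]) next
    w1 <- k / n; w2 <- 1 - w1
    bcv <- w1 * w2 * (mean(v[1:k]) - mean(v[(k + 1):n]))^2
    if (bcv > best) { best <- bcv; thr <- (v[k] + v[k + 1]) / 2 }
  }
  thr
}

#' Classify centriole fertility from per-track SNR
#'
#' Computes an unbiased SNR threshold with Otsu's method (maximising
#' between-class variance on the SNR values) and classifies tracks above the
#' threshold as fertile. When ground-truth labels are supplied a confusion
#' matrix and per-class recalls are reported.
#'
#' @param snr numeric vector of per-track signal-to-noise ratios (SD of the
#'   fitted oscillatory component over SD of the residuals; see
#'   [smooth_fit()]).
#' @param labels optional character/factor vector (`"fertile"`/`"sterile"`)
#'   for evaluation.
#' @return an object of class `fertility_classification`: `threshold`,
#'   `class` (per track), and, with labels, `confusion` (proportions),
#'   `fertile_recall`, `sterile_recall`.
#' @export
classify_fertility <- function(snr, labels = NULL) {
  if (length(snr) < 2) stop_validation("need >= 2 tracks to classify")
  thr <- otsu_threshold(snr)
  cls <- ifelse(snr > thr, "fertile", "sterile")
  out <- list(threshold = thr, class = cls)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    tab <- table(truth = factor(labels, c("fertile", "sterile")),
                 called = factor(cls, c("fertile", "sterile")))
    out$confusion <- prop.table(tab)
    nf <- sum(labels == "fertile"); ns <- sum(labels == "sterile")
    out$fertile_recall <- if (nf) sum(labels == "fertile" & cls == "fertile") / nf else NA
    out$sterile_recall <- if (ns) sum(labels == "sterile" & cls == "sterile") / ns else NA
  }
  structure(out, class = "fertility_classification")
}

#' Uniquely match peaks to duplication events
#'
#' Peaks are ranked by prominence (high to low; ties by earlier time) and each
#' in turn takes the nearest not-yet-assigned event within `+/- window`
#' minutes; equidistant events resolve to the earlier one. Neither peaks nor
#' events are ever reused, so the assignment is a partial injection both ways.
#'
#' @param peaks a `peak_set` (or data.frame with `time` (s) and `prominence`).
#' @param events numeric duplication times, seconds.
#' @param window matching half-window in minutes (default 5; `Inf` for
#'   unrestricted nearest matching).
#' @return data.frame `assignments` with columns `peak_time`, `event_time`,
#'   `prominence`, `separation_s`.
#' @export
match_events <- function(peaks, events, window = 5) {
  if (window <= 0) stop_validation("window must be > 0")
  w_s <- window * 60
  if (nrow(peaks) == 0 || length(events) == 0)
    return(data.frame(peak_time = numeric(0), event_time = numeric(0),
                      prominence = numeric(0), separation_s = numeric(0)))
  ord <- order(-peaks$prominence, peaks$time)
  ev <- sort(events)
  taken <- rep(FALSE, length(ev))
  res <- list()
  for (i in ord) {
    d <- abs(ev - peaks$time[i])
    d[taken] <- Inf
    j <- which(d == min(d))[1]  # ties: earlier event wins (ev is sorted)
    if (is.finite(d[j]) && d[j] <= w_s) {
      taken[j] <- TRUE
      res[[length(res) + 1]] <- data.frame(peak_time = peaks$time[i],
                                           event_time = ev[j],
                                           prominence = peaks$prominence[i],
                                           separation_s = d[j])
    }
  }
  if (!length(res))
    return(data.frame(peak_time = numeric(0), event_time = numeric(0),
                      prominence = numeric(0), separation_s = numeric(0)))
  do.call(rbind, res)
}

#' Score peak-to-event matching: precision, recall, average precision
#'
#' Computes precision (matched peaks / all peaks), recall (matched events /
#' all events), the precision-recall curve obtained by sweeping the
#' peak-calling threshold down the prominence ranking, and its integrated
#' area, the average precision (AP). Baselines: the analytic no-correlation
#' AP `|events| / (|events| + |peaks|)`; a simulated random-ranking AP
#' (positives shuffled uniformly into the ranked retrieval list); and the
#' mean peak-event temporal separation when the same number of events is
#' redrawn uniformly over the observation window. A Pearson correlation and
#' least-squares line on the matched (peak time, event time) pairs (in
#' minutes) quantify temporal agreement.
#'
#' @inheritParams match_events
#' @param observation_window length-2 numeric, seconds, for the random-events
#'   baseline.
#' @param n_sims simulations for the random baselines.
#' @param seed RNG seed for the baselines.
#' @return an object of class `match_result`.
#' @export
score_matches <- function(peaks, events, window = 5,
                          observation_window = NULL, n_sims = 1000,
                          seed = NULL) {
  n_p <- nrow(peaks); n_e <- length(events)
  assignments <- match_events(peaks, events, window)
  matched <- nrow(assignments)
  undefined_precision <- n_p == 0
  precision <- if (n_p) matched / n_p else 0
  recall <- if (n_e) matched / n_e else 0
  # precision-recall curve along the descending prominence ranking
  pr <- NULL; ap <- NA_real_
  if (n_p > 0 && n_e > 0) {
    ord <- order(-peaks$prominence, peaks$time)
    prec_k <- numeric(n_p); rec_k <- numeric(n_p)
    for (k in seq_len(n_p)) {
      mk <- nrow(match_events(peaks[ord[seq_len(k)], , drop = FALSE],
                              events, window))
      prec_k[k] <- mk / k
      rec_k[k] <- mk / n_e
    }
    pr <- data.frame(prominence = peaks$prominence[ord],
                     precision = prec_k, recall = rec_k)
    ap <- sum(diff(c(0, rec_k)) * prec_k)
  }
  baseline_ap <- if (n_p + n_e > 0) n_e / (n_e + n_p) else NA_real_
  sim_ap <- sim_sep <- NULL
  if (n_sims > 0 && n_p > 0 && n_e > 0) {
    local_seed(seed, {
      sim_ap <- replicate(n_sims, random_ranking_ap(n_e, n_p))
      if (!is.null(observation_window)) {
        sim_sep <- replicate(n_sims, {
          ev <- stats::runif(n_e, observation_window[1], observation_window[2])
          a <- match_events(peaks, ev, window = Inf)
          if (nrow(a)) mean(a$separation_s) / 60 else NA_real_
        })
      }
    })
  }
  structure(list(assignments = assignments, window = window,
                 precision = precision, recall = recall,
                 undefined_precision = undefined_precision,
                 n_peaks = n_p, n_events = n_e, n_matched = matched,
                 pr_curve = pr, AP = ap, baseline_AP = baseline_ap,
                 sim_baseline_AP = if (!is.null(sim_ap)) mean(sim_ap) else NA_real_,
                 sim_baseline_AP_sd = if (!is.null(sim_ap)) stats::sd(sim_ap) else NA_real_,
                 random_mean_separation = if (!is.null(sim_sep))
                   mean(sim_sep, na.rm = TRUE) else NA_real_,
                 correlation = matched_correlation(assignments)),
            class = "match_result")
}

# AP of a random ranking: n_pos positives shuffled uniformly among
# n_pos + n_neg ranked items; AP = mean over positives of precision at their
# rank. Converges to n_pos / (n_pos + n_neg).
random_ranking_ap <- function(n_pos, n_neg) {
  ranks <- sort(sample.int(n_pos + n_neg, n_pos))
  mean(seq_len(n_pos) / ranks)
}

matched_correlation <- function(assignments) {
  if (nrow(assignments) < 3)
    return(list(pearson_r = NA_real_, slope = NA_real_, intercept = NA_real_,
                p_value = NA_real_))
  x <- assignments$peak_time / 60; y <- assignments$event_time / 60
  ct <- stats::cor.test(x, y)
  cf <- stats::coef(stats::lm(y ~ x))
  list(pearson_r = unname(ct$estimate), slope = unname(cf[2]),
       intercept = unname(cf[1]), p_value = ct$p.value)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$n_matched, " matched of ", x$n_peaks, " peaks / ",
      x$n_events, " events (window +/-", x$window, " min)\n",
      "  precision=", signif(x$precision, 4), " recall=", signif(x$recall, 4),
      " AP=", signif(x$AP, 4), " baseline AP=", signif(x$baseline_AP, 4),
      "\n", sep = "")
  invisible(x)
}
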