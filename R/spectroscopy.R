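#' Construct a photon-count trace
#'
#' @param counts non-negative integer photon counts per bin.
#' @param bin_width bin width in seconds.
#' @return an object of class `photon_trace` with fields `counts`,
#'   `bin_width`, `duration`.
#' @export
photon_trace <- function(counts, bin_width = 1e-3) {
  if (any(counts < 0)) stop_validation("photon counts must be >= 0")
  structure(list(counts = as.numeric(counts), bin_width = bin_width,
                 duration = length(counts) * bin_width),
            class = "photon_trace")
}

#' Autocorrelation function of an intensity trace
#'
#' Direct estimator of `G(tau) = <dI(t) dI(t+tau)> / <I(t)>^2`, where `dI` is
#' the fluctuation about the mean intensity and `< >` a time average over all
#' available pairs at each lag.
#'
#' @param trace a [photon_trace].
#' @param lags integer lags in bins (default: a log-spaced set up to a quarter
#'   of the trace).
#' @return an object of class `acf_record`: data.frame `tau` (ms), `G`, with
#'   attributes `duration` (s) and `mean_rate` (counts/s).
#' @export
compute_acf <- function(trace, lags = NULL) {
  stopifnot(inherits(trace, "photon_trace"))
  x <- trace$counts
  n <- length(x)
  mu <- mean(x)
  if (mu == 0) stop_validation("zero-mean trace: ACF normalisation undefined")
  if (is.null(lags))
    lags <- sort(unique(pmax(1, round(exp(seq(0, log(n / 4), length.out = 64))))))
  if (max(lags) >= n) stop_validation("trace shorter than the largest lag")
  d <- x - mu
  G <- vapply(lags, function(k)
    mean(d[seq_len(n - k)] * d[(k + 1):n]) / mu^2, numeric(1))
  structure(data.frame(tau = lags * trace$bin_width * 1000, G = G),
            class = c("acf_record", "data.frame"),
            duration = trace$duration, mean_rate = mu / trace$bin_width)
}

#' FCS diffusion/dark-state model specifications M1-M8
#'
#' The eight 3-D anomalous-diffusion models: one or two diffusing species,
#' with or without a blinking dark state (correlation time restricted to
#' 10-300 us) and with or without a triplet dark state (1-10 us). The
#' structural parameter `AR` and the anomalous subdiffusion exponent `alpha`
#' are held fixed (5 and 0.7).
#'
#' @param n_species 1 or 2 diffusing species.
#' @param blinking,triplet logical; include the dark state.
#' @param AR,alpha fixed structural/anomalous parameters.
#' @return an object of class `fcs_model_spec` (with a `name` field `M1`-`M8`).
#' @export
fcs_model_spec <- function(n_species = 1, blinking = FALSE, triplet = FALSE,
                           AR = 5, alpha = 0.7) {
  stopifnot(n_species %in% 1:2)
  code <- paste0(n_species, as.integer(blinking), as.integer(triplet))
  name <- c(`100` = "M1", `110` = "M2", `101` = "M3", `111` = "M4",
            `200` = "M5", `210` = "M6", `201` = "M7", `211` = "M8")[[code]]
  structure(list(n_species = n_species, blinking = isTRUE(blinking),
                 triplet = isTRUE(triplet), AR = AR, alpha = alpha,
                 name = name),
            class = "fcs_model_spec")
}

#' @rdname fcs_model_spec
#' @export
fcs_all_models <- function() {
  specs <- list()
  for (ds in 1:2) for (bs in c(FALSE, TRUE)) for (ts in c(FALSE, TRUE))
    specs[[length(specs) + 1]] <- fcs_model_spec(ds, bs, ts)
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs[order(names(specs))]
}

#' Evaluate an FCS model curve
#'
#' `G(tau) = G0 * sum_k A_k (1 + (tau/tauxy_k)^alpha)^-1
#' (1 + tau/(AR^2 tauxy_k))^-1/2 * prod_j (1 + T_j/(1-T_j) exp(-tau/tauT_j))`
#' with `sum_k A_k = 1`; `G0 = 1/N` is the diffusive amplitude.
#'
#' @param spec an [fcs_model_spec].
#' @param params named list: `G0`; `tauxy` (ms, length `n_species`); `A`
#'   (fractions summing to 1); `T_blink`, `tau_blink` (ms); `T_trip`,
#'   `tau_trip` (ms), as required by the spec.
#' @param tau lag times, ms.
#' @return numeric G values.
#' @export
fcs_model_curve <- function(spec, params, tau) {
  A <- params$A %||% 1
  if (abs(sum(A) - 1) > 1e-8) stop_validation("species fractions must sum to 1")
  g <- 0
  for (k in seq_len(spec$n_species)) {
    txy <- params$tauxy[k]
    g <- g + A[k] * (1 + (tau / txy)^spec$alpha)^-1 *
      (1 + tau / (spec$AR^2 * txy))^-0.5
  }
  dark <- 1
  if (spec$blinking)
    dark <- dark * (1 + params$T_blink / (1 - params$T_blink) *
                      exp(-tau / params$tau_blink))
  if (spec$triplet)
    dark <- dark * (1 + params$T_trip / (1 - params$T_trip) *
                      exp(-tau / params$tau_trip))
  params$G0 * g * dark
}

fcs_par_layout <- function(spec, acf) {
  g0_0 <- max(acf$G[1], 1e-3)
  # crude tau scale: lag where G first halves
  half <- acf$tau[which(acf$G <= acf$G[1] / 2)[1]]
  if (is.na(half)) half <- stats::median(acf$tau)
  nm <- c("G0", paste0("tauxy", seq_len(spec$n_species)))
  start <- c(g0_0, rep(half, spec$n_species) *
               if (spec$n_species == 2) c(0.3, 3) else 1)
  lower <- c(1e-8, rep(4e-4, spec$n_species))
  upper <- c(Inf, rep(1.5e3, spec$n_species))
  if (spec$n_species == 2) {
    nm <- c(nm, "A1"); start <- c(start, 0.5); lower <- c(lower, 0.01)
    upper <- c(upper, 0.99)
  }
  if (spec$blinking) {
    nm <- c(nm, "T_blink", "tau_blink")
    start <- c(start, 0.2, 0.05); lower <- c(lower, 1e-4, 0.01)
    upper <- c(upper, 0.8, 0.3)
  }
  if (spec$triplet) {
    nm <- c(nm, "T_trip", "tau_trip")
    start <- c(start, 0.1, 0.003); lower <- c(lower, 1e-4, 0.001)
    upper <- c(upper, 0.8, 0.01)
  }
  names(start) <- names(lower) <- names(upper) <- nm
  list(start = start, lower = lower, upper = upper)
}

fcs_vec_to_params <- function(spec, par) {
  p <- list(G0 = par[["G0"]],
            tauxy = unname(par[grep("^tauxy", names(par))]))
  p$A <- if (spec$n_species == 2) c(par[["A1"]], 1 - par[["A1"]]) else 1
  if (spec$blinking) { p$T_blink <- par[["T_blink"]]; p$tau_blink <- par[["tau_blink"]] }
  if (spec$triplet) { p$T_trip <- par[["T_trip"]]; p$tau_trip <- par[["tau_trip"]] }
  p
}

#' Fit FCS models to an autocorrelation curve and select by BIC
#'
#' Fits each candidate model by bounded nonlinear least squares within the
#' printed constraints (fit domain 4e-4 to 1.5e3 ms; blinking correlation time
#' 10-300 us; triplet 1-10 us; `AR = 5`, `alpha = 0.7` fixed) and selects the
#' model minimising `BIC = n log(SS/n) + k log(n)`. The particle number is
#' `N = 1/G0`; with a nonzero uncorrelated background `b` the amplitude is
#' corrected by `chi^2 = (1 + b/f)^2`, giving `N = 1/(chi^2 G0)` (with `f` the
#' sample signal count rate; `background_mode = "total_rate"` instead treats
#' `f` as the total measured rate, `N = (1/G0) ((f-b)/f)^2`). Concentration is
#' `N / (Veff N_A)`.
#'
#' @param acf an `acf_record` (see [compute_acf()]), or data.frame `tau`
#'   (ms), `G`.
#' @param models list of [fcs_model_spec()]s (default: all eight).
#' @param background background count rate `b`, counts/s.
#' @param mean_rate sample count rate `f`, counts/s (defaults to the record's
#'   attribute).
#' @param veff_fl effective confocal volume in femtolitres (default 0.28).
#' @param background_mode `"sample_rate"` (default) or `"total_rate"`.
#' @return an object of class `fcs_fit`: best model's `spec`, `params`, `SS`,
#'   `BIC`, `G0`, `N` (background-corrected), `concentration_nM`, plus
#'   `all_fits` (per-model summaries).
#' @export
fit_acf <- function(acf, models = fcs_all_models(), background = 0,
                    mean_rate = NULL, veff_fl = 0.28,
                    background_mode = c("sample_rate", "total_rate")) {
  background_mode <- match.arg(background_mode)
  if (inherits(models, "fcs_model_spec")) models <- list(models)
  keep <- acf$tau >= 4e-4 & acf$tau <= 1.5e3
  tau <- acf$tau[keep]; G <- acf$G[keep]
  n <- length(tau)
  mean_rate <- mean_rate %||% attr(acf, "mean_rate") %||% NA_real_
  fits <- list()
  for (spec in models) {
    lay <- fcs_par_layout(spec, data.frame(tau = tau, G = G))
    res <- tryCatch(minpack.lm::nls.lm(
      par = lay$start,
      fn = function(par) G - fcs_model_curve(spec, fcs_vec_to_params(spec, par), tau),
      lower = lay$lower, upper = lay$upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(res)) next
    ss <- sum(res$fvec^2)
    k <- length(lay$start)
    fits[[spec$name]] <- list(spec = spec, par = res$par,
                              params = fcs_vec_to_params(spec, res$par),
                              SS = ss, k = k,
                              BIC = n * log(ss / n) + k * log(n))
  }
  if (!length(fits)) stop_validation("no FCS model converged")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "BIC"))]]
  G0 <- best$params$G0
  chi2 <- 1
  if (background > 0 && is.finite(mean_rate) && mean_rate > 0) {
    if (background_mode == "total_rate" && mean_rate <= background)
      stop_validation("total rate must exceed background")
    chi2 <- switch(background_mode,
                   sample_rate = (1 + background / mean_rate)^2,
                   total_rate = (mean_rate / (mean_rate - background))^2)
  }
  N <- 1 / (chi2 * G0)
  conc_nM <- N / (veff_fl * 1e-15 * 6.02214076e23) * 1e9
  structure(list(spec = best$spec, model = best$spec$name, params = best$params,
                 SS = best$SS, BIC = best$BIC, G0 = G0, chi2 = chi2, N = N,
                 concentration_nM = conc_nM, veff_fl = veff_fl,
                 all_fits = lapply(fits, function(f)
                   f[c("params", "SS", "k", "BIC")])),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit> best=", x$model, " BIC=", signif(x$BIC, 5),
      " G0=", signif(x$G0, 4), " N=", signif(x$N, 4),
      " conc=", signif(x$concentration_nM, 4), " nM\n", sep = "")
  invisible(x)
}

#' Robust (ROUT-style) outlier filter for concentration series
#'
#' Fits a constant to the values by iteratively reweighted least squares with
#' Cauchy weights, scales residuals by the robust standard deviation (the
#' 68.27th percentile of absolute residuals with a small-sample correction),
#' converts them to two-sided t-tail p-values and flags outliers by an
#' FDR-style step-up from the most extreme residual at aggression `Q`
#' (percent). A MAD rule (`|residual| > mad_k * MAD`) is available as a
#' fallback method.
#'
#' @param values numeric vector (>= 4 values).
#' @param Q aggression, percent (default 1).
#' @param min_retained flag threshold: fewer retained values than this raises
#'   `insufficient_data` (at least four 10-s recordings are required per
#'   embryo).
#' @param method `"rout"` or `"mad"`.
#' @param mad_k MAD multiplier for the fallback rule.
#' @return list with `retained`, `outliers` (logical per value), `center`,
#'   `insufficient_data`.
#' @export
outlier_filter <- function(values, Q = 1, min_retained = 4,
                           method = c("rout", "mad"), mad_k = 5) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 4) stop_validation("outlier_filter needs >= 4 values")
  center <- stats::median(values)
  for (it in 1:25) {  # Cauchy IRLS for the constant model
    r <- values - center
    s <- stats::mad(r) %||% 0
    if (s == 0) s <- max(abs(r)) / 10 + 1e-12
    w <- 1 / (1 + (r / (2.385 * s))^2)
    new_center <- sum(w * values) / sum(w)
    if (abs(new_center - center) < 1e-12) break
    center <- new_center
  }
  r <- values - center
  if (method == "mad") {
    md <- stats::mad(r)
    out <- if (md == 0) abs(r) > 0 else abs(r) > mad_k * md
  } else {
    rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - 1)
    if (rsdr == 0) {
      out <- abs(r) > 0
    } else {
      t_stat <- abs(r) / rsdr
      p <- 2 * stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
      ord <- order(p)
      out <- rep(FALSE, n)
      thr_i <- 0
      for (i in seq_len(n))   # step-up from the most extreme residual
        if (p[ord[i]] <= (Q / 100) * i / n) thr_i <- i
      if (thr_i > 0) out[ord[seq_len(thr_i)]] <- TRUE
    }
  }
  list(retained = values[!out], outliers = out, center = center,
       insufficient_data = sum(!out) < min_retained)
}

#' Calibrate the PeCoS peak-counting threshold on control recordings
#'
#' Pools all control bins and scans thresholds `mean + n * SD` for
#' n = 1, 2, ...; returns the smallest n at which the mean number of peaks per
#' control recording falls below `max_mean_peaks` (default: fewer than five
#' peaks per 180-s control recording).
#'
#' @param control_traces list of [photon_trace]s from control embryos.
#' @param max_mean_peaks calibration criterion.
#' @param n_max largest n considered.
#' @return list with `n_sigma`, `threshold` (counts), `mean_control_peaks`,
#'   and the scanned `profile` (n, threshold, mean peak count).
#' @export
pecos_calibrate <- function(control_traces, max_mean_peaks = 5, n_max = 50) {
  if (inherits(control_traces, "photon_trace"))
    control_traces <- list(control_traces)
  if (!length(control_traces)) stop_validation("need >= 1 control trace")
  pooled <- unlist(lapply(control_traces, `[[`, "counts"))
  mu <- mean(pooled); sdev <- stats::sd(pooled)
  if (is.na(sdev)) sdev <- 0
  profile <- data.frame(n = integer(0), threshold = numeric(0),
                        mean_peaks = numeric(0))
  for (n in seq_len(n_max)) {
    thr <- mu + n * sdev
    mp <- mean(vapply(control_traces, function(tr)
      pecos_count(tr, thr)$peak_count, numeric(1)))
    profile <- rbind(profile, data.frame(n = n, threshold = thr, mean_peaks = mp))
    if (mp < max_mean_peaks)
      return(list(n_sigma = n, threshold = thr, mean_control_peaks = mp,
                  profile = profile))
  }
  stop_validation("no n <= ", n_max, " satisfies the calibration criterion")
}

#' Count PeCoS peaks above a threshold
#'
#' A peak is a maximal run of consecutive bins whose photon count strictly
#' surpasses the threshold.
#'
#' @param trace a [photon_trace].
#' @param threshold counts.
#' @return an object of class `pecos_result`: `threshold`, `peak_count`,
#'   `peaks_per_minute`.
#' @export
pecos_count <- function(trace, threshold) {
  stopifnot(inherits(trace, "photon_trace"))
  if (threshold < 0) stop_validation("threshold must be >= 0")
  above <- trace$counts > threshold
  starts <- sum(above & !c(FALSE, above[-length(above)]))
  structure(list(threshold = threshold, peak_count = starts,
                 peaks_per_minute = starts / (trace$duration / 60)),
            class = "pecos_result")
}
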