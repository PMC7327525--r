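#' Pulse shape functions
#'
#' The candidate regression shapes for a discrete S-phase Plk4 pulse.
#' The Lorentzian is parameterised as
#' `y = baseline + A / (1 + ((t - C)/w)^2)` and the Gaussian as
#' `y = baseline + A * exp(-((t - C)/w)^2 / 2)`; `A` is the amplitude above
#' baseline, `C` the pulse center (s) and `w` the half-width scale (s).
#'
#' @param t times, seconds.
#' @param A,C,w,baseline shape parameters.
#' @return numeric vector of intensities.
#' @export
lorentzian <- function(t, A, C, w, baseline = 0)
  baseline + A / (1 + ((t - C) / w)^2)

#' @rdname lorentzian
#' @export
gaussian_pulse <- function(t, A, C, w, baseline = 0)
  baseline + A * exp(-((t - C) / w)^2 / 2)

# Continuous piecewise-linear shapes. Breakpoints b (sorted), node values v.
piecewise_linear <- function(t, breaks, values) {
  stats::approx(breaks, values, xout = t, rule = 2)$y
}

fit_one_shape <- function(t, y, model) {
  amp0 <- max(y) - min(y)
  c0 <- t[which.max(y)]
  w0 <- max(diff(range(t)) / 6, 1e-6)
  b0 <- min(y)
  start <- c(A = amp0, C = c0, w = w0, b = b0)
  lower <- c(A = 0, C = min(t) - diff(range(t)), w = 1e-9, b = -Inf)
  res <- switch(model,
    Lorentzian = try_nls(function(p) lorentzian(t, p[1], p[2], p[3], p[4]),
                         y, start, lower),
    Gaussian = try_nls(function(p) gaussian_pulse(t, p[1], p[2], p[3], p[4]),
                       y, start, lower),
    IncConstDec = fit_piecewise_pulse(t, y, n_breaks = 2),
    IncDec = fit_piecewise_pulse(t, y, n_breaks = 1),
    stop_validation("unknown pulse model: ", model))
  res
}

try_nls <- function(curve_fn, y, start, lower) {
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = function(p) y - curve_fn(p), lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  yhat <- curve_fn(fit$par)
  list(params = as.list(fit$par), fitted = as.numeric(yhat),
       n_par = length(start))
}

# Profiled least squares for triangular (IncDec) / trapezoidal (IncConstDec)
# pulses: continuous piecewise-linear with interior breakpoints scanned on a
# grid, node values solved by linear least squares, then refined by optim.
fit_piecewise_pulse <- function(t, y, n_breaks) {
  rng <- range(t)
  design_ss <- function(breaks) {
    knots <- sort(unique(c(rng[1], breaks, rng[2])))
    if (length(knots) < n_breaks + 2) return(list(ss = Inf))
    B <- hinge_basis(t, knots)
    fit <- stats::lm.fit(B, y)
    list(ss = sum(fit$residuals^2), values = fit$coefficients, knots = knots,
         fitted = as.numeric(B %*% fit$coefficients))
  }
  cand <- seq(rng[1], rng[2], length.out = 12)[2:11]
  if (n_breaks == 1) {
    grids <- lapply(cand, function(b) b)
  } else {
    grids <- list()
    for (i in seq_along(cand)) for (j in seq_along(cand))
      if (j > i) grids[[length(grids) + 1]] <- c(cand[i], cand[j])
  }
  best <- NULL
  for (g in grids) {
    r <- design_ss(g)
    if (is.finite(r$ss) && (is.null(best) || r$ss < best$ss)) {
      best <- r; best$breaks <- g
    }
  }
  if (is.null(best)) return(NULL)
  opt <- stats::optim(best$breaks, function(b) {
    if (any(b <= rng[1]) || any(b >= rng[2]) || is.unsorted(b)) return(Inf)
    design_ss(b)$ss
  }, method = "Nelder-Mead",
  control = list(maxit = 300, warn.1d.NelderMead = FALSE))
  final <- design_ss(sort(pmin(pmax(opt$par, rng[1] + 1e-9), rng[2] - 1e-9)))
  if (!is.finite(final$ss)) final <- best
  list(params = list(breaks = final$knots, values = as.numeric(final$values)),
       fitted = final$fitted, n_par = length(final$knots) + length(final$values) - 2)
}

# Piecewise-linear interpolation basis on fixed knots (tent functions).
hinge_basis <- function(t, knots) {
  sapply(seq_along(knots), function(j) {
    v <- numeric(length(knots)); v[j] <- 1
    stats::approx(knots, v, xout = t, rule = 2)$y
  })
}

#' Fit candidate pulse shapes to an S-phase segment
#'
#' Fits each candidate model (Lorentzian, Gaussian, Increase-Constant-Decrease,
#' Increase-Decrease) to the segment's mean signal by least squares and selects
#' the best by R-squared (ties broken by absolute residual sum of squares, then
#' by fewer parameters). Also extracts the oscillation parameters used
#' downstream: amplitude `A`, area under the baseline-subtracted fitted curve
#' over S-phase `Omega` (a.u. s, integrated from CS to NEB), and the
#' center-to-NEB ratio `CN_ratio`.
#'
#' @param segment a `pulse_segment` (>= 6 points).
#' @param candidates character subset of
#'   `c("Lorentzian", "Gaussian", "IncConstDec", "IncDec")`.
#' @return an object of class `pulse_fit`: the best fit (fields `model`,
#'   `params`, `R2`, `SS_abs`, `A`, `center`, `Omega`, `CN_ratio`, `fitted`)
#'   plus `all_fits`, a per-candidate summary list.
#' @export
fit_pulse <- function(segment,
                      candidates = c("Lorentzian", "Gaussian",
                                     "IncConstDec", "IncDec")) {
  stopifnot(inherits(segment, "pulse_segment"))
  t <- segment$rel_times; y <- segment$mean_intensity
  if (length(t) < 6) stop_validation("fit_pulse needs >= 6 data points")
  fits <- list()
  for (m in candidates) {
    f <- fit_one_shape(t, y, m)
    if (is.null(f)) next
    f$model <- m
    f$SS_abs <- sum((y - f$fitted)^2)
    f$R2 <- r_squared(y, f$fitted)
    fits[[m]] <- f
  }
  if (!length(fits)) stop_validation("no pulse model converged")
  ord <- order(-vapply(fits, `[[`, 0, "R2"),
               vapply(fits, `[[`, 0, "SS_abs"),
               vapply(fits, `[[`, 0, "n_par"))
  best <- fits[[ord[1]]]
  out <- pulse_fit_summary(best, segment)
  out$all_fits <- lapply(fits, function(f)
    f[c("model", "params", "R2", "SS_abs", "n_par")])
  class(out) <- "pulse_fit"
  out
}

pulse_fit_summary <- function(best, segment) {
  t <- segment$rel_times
  neb <- segment$neb_rel
  grid <- seq(0, neb, length.out = 512)
  if (best$model %in% c("Lorentzian", "Gaussian")) {
    p <- best$params
    fun <- if (best$model == "Lorentzian") lorentzian else gaussian_pulse
    curve <- fun(grid, p$A, p$C, p$w, p$b)
    baseline <- p$b
    A <- p$A; center <- p$C
  } else {
    curve <- piecewise_linear(grid, best$params$breaks, best$params$values)
    baseline <- min(best$params$values)
    A <- max(best$params$values) - baseline
    center <- grid[which.max(curve)]
  }
  omega <- trapz(grid, pmax(curve - baseline, 0))
  list(model = best$model, params = best$params, fitted = best$fitted,
       R2 = best$R2, SS_abs = best$SS_abs, A = A, center = center,
       baseline = baseline, Omega = omega,
       CN_ratio = if (is.finite(neb) && neb > 0) center / neb else NA_real_,
       neb_rel = neb)
}

#' @export
print.pulse_fit <- function(x, ...) {
  cat("<pulse_fit> model=", x$model, " R2=", signif(x$R2, 4),
      " A=", signif(x$A, 4), " center=", signif(x$center, 4),
      " s Omega=", signif(x$Omega, 4), "\n", sep = "")
  invisible(x)
}

#' Peak-to-peak oscillation period across consecutive cycle fits
#'
#' @param fits list of `pulse_fit` objects, one per consecutive cycle.
#' @param cs_times absolute CS times (s) of the same cycles, to place the
#'   fitted centers on a common clock.
#' @return mean peak-to-peak interval in seconds (`NA` with < 2 fits).
#' @export
oscillation_period <- function(fits, cs_times) {
  if (length(fits) < 2) return(NA_real_)
  centers <- vapply(fits, `[[`, 0, "center") + cs_times
  mean(diff(sort(centers)))
}

#' Fit the S-phase oscillator model to a pulse segment
#'
#' Least-squares fit of the model's total-bound-Plk4 curve
#' (`scale * sum_i [Ai*](t)`) to a segment's mean signal, with all parameters
#' constrained positive and `k1, k2 < 1`. `N` is fixed (default 9) and `k3`
#' may be fixed (default: the reference value 0.06906). The initial bound pool
#' is taken from the first data point unless freed.
#'
#' @param segment a `pulse_segment`.
#' @param s_phase_only restrict the fit to `rel_times <= neb_rel` (the model
#'   is defined on S-phase only); default TRUE.
#' @param free character vector of parameters to estimate, from
#'   `c("k1", "k2", "k3", "A0_init", "Abound_init", "scale")`.
#' @param start named list overriding default starting values.
#' @param N number of phosphorylation steps (fixed).
#' @param k3 value of `k3` when not freed.
#' @param scale fluorescence scale when not freed.
#' @return an object of class `model1_fit` with the estimated [model1_params],
#'   `R2`, `residuals`, `fitted`, and the bounds used.
#' @export
fit_model1 <- function(segment, free = c("k1", "k2", "A0_init"),
                       start = list(), N = 9, k3 = 0.06906, scale = 1,
                       s_phase_only = TRUE) {
  stopifnot(inherits(segment, "pulse_segment"))
  t <- segment$rel_times; y <- segment$mean_intensity
  if (s_phase_only && is.finite(segment$neb_rel)) {
    keep <- t <= segment$neb_rel
    t <- t[keep]; y <- y[keep]
  }
  base <- list(k1 = 0.01, k2 = 0.05, k3 = k3, A0_init = max(y) / scale,
               Abound_init = max(y[1] / scale, 1e-6), scale = scale)
  base[names(start)] <- start
  lower <- c(k1 = 1e-8, k2 = 1e-8, k3 = 1e-8, A0_init = 1e-8,
             Abound_init = 1e-8, scale = 1e-8)
  upper <- c(k1 = 1, k2 = 1, k3 = Inf, A0_init = Inf, Abound_init = Inf,
             scale = Inf)
  free <- match.arg(free, names(lower), several.ok = TRUE)
  predict_bound <- function(par) {
    pl <- base; pl[free] <- as.list(par)
    prm <- model1_params(k1 = pl$k1, k2 = pl$k2, k3 = pl$k3, N = N,
                         A0_init = pl$A0_init, Abound_init = pl$Abound_init,
                         scale = pl$scale)
    model1_analytic(prm, t)$bound
  }
  obj <- function(par) sum((y - predict_bound(par))^2)
  p0 <- unlist(base[free])
  opt <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = lower[free], upper = upper[free],
                      control = list(maxit = 500, factr = 1e4))
  # polish with Levenberg-Marquardt on the residual vector
  lm <- tryCatch(minpack.lm::nls.lm(opt$par,
                                    fn = function(par) y - predict_bound(par),
                                    lower = lower[free], upper = upper[free],
                                    control = minpack.lm::nls.lm.control(maxiter = 200)),
                 error = function(e) NULL)
  par <- if (!is.null(lm) && sum(lm$fvec^2) <= opt$value) lm$par else opt$par
  pl <- base; pl[free] <- as.list(par)
  est <- model1_params(k1 = pl$k1, k2 = pl$k2, k3 = pl$k3, N = N,
                       A0_init = pl$A0_init, Abound_init = pl$Abound_init,
                       scale = pl$scale)
  fitted <- predict_bound(par)
  structure(list(params = est, free = free, R2 = r_squared(y, fitted),
                 fitted = fitted, residuals = y - fitted,
                 bounds = list(lower = lower[free], upper = upper[free]),
                 segment = segment),
            class = "model1_fit")
}

#' @export
print.model1_fit <- function(x, ...) {
  p <- x$params
  cat("<model1_fit> R2=", signif(x$R2, 5), " k1=", signif(p$k1, 4),
      " k2=", signif(p$k2, 4), " k3=", signif(p$k3, 4),
      " A0=", signif(p$A0_init, 4), "\n", sep = "")
  invisible(x)
}

#' Metropolis-Hastings exploration of the oscillator parameter space
#'
#' Explores `(k1, k2, k3, A0_init)` around the least-squares optimum with four
#' Markov chains, Gaussian proposals of width 5% of each parameter's starting
#' value (parameters span two orders of magnitude, so proposals are scaled per
#' parameter), and a Gaussian likelihood `exp(-SS / (2 sigma^2))`; `sigma` defaults
#' to the trust-region fit's residual SD, floored at 1% of the signal range so
#' the target stays proper on near-noise-free data. Samples are retained when
#' the corresponding
#' model fit reaches `R2 > r2_min`, mirroring how the parameter sensitivity of
#' the model is assessed: a parameter along which the retained cloud is wide is
#' one the fit is insensitive to.
#'
#' @param segment a `pulse_segment`.
#' @param start_points matrix (chains x 4) of starting values for
#'   `(k1, k2, k3, A0_init)`; default: 4 jittered copies of the trust-region
#'   fit.
#' @param steps MCMC steps per chain.
#' @param r2_min retention filter on goodness of fit.
#' @param proposal_frac proposal SD as a fraction of each parameter's starting
#'   value.
#' @param burn_frac fraction of each chain discarded as burn-in.
#' @param sigma noise SD of the Gaussian likelihood (default: residual SD of
#'   the least-squares fit, floored at 1% of the signal range).
#' @param N,k3_fix,scale fixed model structure (see [fit_model1()]); `k3` is a
#'   sampled parameter here, `k3_fix` only seeds the default starts.
#' @param seed RNG seed.
#' @return an object of class `mcmc_run`: `samples` (retained data.frame with
#'   chain, k1, k2, k3, A0_init, R2), `acceptance` rate, `spread` (per-parameter
#'   SD/mean of retained samples) and `best_R2`.
#' @export
mcmc_explore <- function(segment, start_points = NULL, steps = 2000,
                         r2_min = 0.95, proposal_frac = 0.05,
                         burn_frac = 0.2, sigma = NULL, N = 9,
                         k3_fix = 0.06906, scale = 1, seed = NULL) {
  stopifnot(inherits(segment, "pulse_segment"))
  t <- segment$rel_times; y <- segment$mean_intensity
  n <- length(y)
  lower <- c(k1 = 1e-6, k2 = 1e-6, k3 = 1e-6, A0_init = 1e-6)
  k3_upper <- max(1, 4 * k3_fix)
  upper <- c(k1 = 1, k2 = 1, k3 = k3_upper, A0_init = 4 * max(y) / scale)
  abound <- max(y[1] / scale, 1e-6)
  bound_curve <- function(par) {
    prm <- model1_params(k1 = par[1], k2 = par[2], k3 = par[3], N = N,
                         A0_init = par[4], Abound_init = abound, scale = scale)
    model1_analytic(prm, t)$bound
  }
  ss_of <- function(par) sum((y - bound_curve(par))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (is.null(start_points) || is.null(sigma)) {
    fit <- fit_model1(segment, free = c("k1", "k2", "A0_init"), N = N,
                      k3 = k3_fix, scale = scale)
    if (is.null(sigma))
      sigma <- max(stats::sd(fit$residuals), 0.01 * diff(range(y)))
    if (is.null(start_points)) {
      ctr <- c(fit$params$k1, fit$params$k2, fit$params$k3, fit$params$A0_init)
      start_points <- local_seed(seed, t(replicate(4, pmin(pmax(
        ctr * exp(stats::rnorm(4, 0, 0.05)), lower), upper))))
    }
  }
  stopifnot(ncol(start_points) == 4)
  local_seed(seed, {
    all_samples <- list(); acc_n <- 0; tot_n <- 0
    for (ch in seq_len(nrow(start_points))) {
      par <- pmin(pmax(as.numeric(start_points[ch, ]), lower), upper)
      prop_sd <- proposal_frac * pmax(abs(par), 1e-6)
      ss <- ss_of(par)
      chain <- matrix(NA_real_, steps, 5)
      for (s in seq_len(steps)) {
        cand <- par + stats::rnorm(4, 0, prop_sd)
        if (all(cand >= lower) && all(cand <= upper)) {
          ss_c <- ss_of(cand)
          log_alpha <- -(ss_c - ss) / (2 * sigma^2)
          tot_n <- tot_n + 1
          if (log(stats::runif(1)) < log_alpha) {
            par <- cand; ss <- ss_c; acc_n <- acc_n + 1
          }
        } else tot_n <- tot_n + 1
        chain[s, ] <- c(par, 1 - ss / ss_tot)
      }
      keep <- seq.int(floor(burn_frac * steps) + 1, steps)
      df <- as.data.frame(chain[keep, , drop = FALSE])
      names(df) <- c("k1", "k2", "k3", "A0_init", "R2")
      df$chain <- ch
      all_samples[[ch]] <- df
    }
    samples <- do.call(rbind, all_samples)
    retained <- samples[samples$R2 > r2_min, , drop = FALSE]
    if (acc_n == 0)
      stop_validation("MCMC never accepted a move; check proposal widths")
    spread <- vapply(c("k1", "k2", "k3", "A0_init"), function(nm)
      if (nrow(retained) > 1)
        stats::sd(retained[[nm]]) / mean(retained[[nm]]) else NA_real_,
      numeric(1))
    structure(list(samples = retained, all_samples = samples,
                   acceptance = acc_n / tot_n, spread = spread,
                   best_R2 = max(samples$R2), r2_min = r2_min, seed = seed),
              class = "mcmc_run")
  })
}

#' Fit a centriole growth curve (flat-rise-plateau)
#'
#' Fits a continuous piecewise-linear flat-rise-plateau model to a Sas-6
#' incorporation curve by profiled least squares over a breakpoint grid with
#' Nelder-Mead refinement. The two breakpoints are the times at which the
#' daughter centriole starts and stops growing; the rise slope is the growth
#' rate and the plateau-minus-start level the final size. If a Plk4 pulse fit
#' is supplied, the fitted Plk4 curve is evaluated at the two breakpoints,
#' giving the centriolar Plk4 levels at growth start/stop.
#'
#' A degenerate flag (`no_growth = TRUE`) is raised when the rise is not
#' detectable (the piecewise fit does not beat a flat fit by `min_gain` in
#' R-squared, or the fitted size is not positive).
#'
#' @param sas6_segment a `pulse_segment` of Sas-6 signal.
#' @param plk4_fit optional `pulse_fit` of the matching Plk4 pulse.
#' @param min_gain minimum R-squared improvement over a constant fit for growth
#'   to be called.
#' @return an object of class `growth_fit` with `rate` (a.u./s), `period` (s),
#'   `size` (a.u.), `start_time`, `stop_time`, `plk4_at_start`, `plk4_at_stop`,
#'   `R2` and `no_growth`.
#' @export
fit_growth_curve <- function(sas6_segment, plk4_fit = NULL, min_gain = 0.2) {
  stopifnot(inherits(sas6_segment, "pulse_segment"))
  t <- sas6_segment$rel_times; y <- sas6_segment$mean_intensity
  rng <- range(t)
  ss_flat <- sum((y - mean(y))^2)
  design <- function(b) {
    knots <- c(rng[1], sort(b), rng[2])
    # flat-rise-plateau: value v1 on [t0,b1], linear to v2 on [b1,b2], v2 after
    B <- cbind(1 - ramp01(t, knots[2], knots[3]), ramp01(t, knots[2], knots[3]))
    fit <- stats::lm.fit(B, y)
    list(ss = sum(fit$residuals^2), v = fit$coefficients,
         fitted = as.numeric(B %*% fit$coefficients), b = sort(b))
  }
  cand <- seq(rng[1], rng[2], length.out = 14)[2:13]
  best <- NULL
  for (i in seq_along(cand)) for (j in seq_along(cand)) if (j > i) {
    r <- design(c(cand[i], cand[j]))
    if (is.null(best) || r$ss < best$ss) best <- r
  }
  opt <- stats::optim(best$b, function(b) {
    if (b[1] >= b[2] || b[1] < rng[1] || b[2] > rng[2]) return(Inf)
    design(b)$ss
  }, method = "Nelder-Mead",
  control = list(maxit = 400, warn.1d.NelderMead = FALSE))
  if (is.finite(opt$value) && opt$value <= best$ss) best <- design(opt$par)
  r2 <- 1 - best$ss / ss_flat
  size <- best$v[2] - best$v[1]
  no_growth <- !is.finite(r2) || r2 < min_gain || size <= 0
  start_t <- best$b[1]; stop_t <- best$b[2]
  rate <- size / (stop_t - start_t)
  plk4_curve <- function(x) {
    if (is.null(plk4_fit)) return(NA_real_)
    if (plk4_fit$model %in% c("Lorentzian", "Gaussian")) {
      p <- plk4_fit$params
      fun <- if (plk4_fit$model == "Lorentzian") lorentzian else gaussian_pulse
      fun(x, p$A, p$C, p$w, p$b)
    } else piecewise_linear(x, plk4_fit$params$breaks, plk4_fit$params$values)
  }
  structure(list(rate = unname(rate), period = stop_t - start_t,
                 size = unname(size),
                 start_time = start_t, stop_time = stop_t,
                 plk4_at_start = plk4_curve(start_t),
                 plk4_at_stop = plk4_curve(stop_t),
                 R2 = r_squared(y, best$fitted), fitted = best$fitted,
                 no_growth = no_growth),
            class = "growth_fit")
}

# 0 before a, linear to 1 between a and b, 1 after b.
ramp01 <- function(t, a, b) pmin(pmax((t - a) / (b - a), 0), 1)
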