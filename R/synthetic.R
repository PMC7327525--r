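#' Specification of a synthetic cycling embryo
#'
#' Study conditions for the cycling-embryo generator: per-cycle Lorentzian
#' Plk4 pulses riding on a linear trend with Gaussian noise, sampled every
#' 30 s, with CS/NEB annotations. Defaults emulate syncytial cycles 11-13:
#' ~12 min cycles, S-phase 70% of the cycle, pulse amplitudes of order 1 a.u.
#' growing slightly weaker at later cycles, pulse width ~100 s and noise a few
#' percent of the amplitude.
#'
#' @param n_cycles number of cycles.
#' @param cycle_periods seconds per cycle (recycled to `n_cycles`).
#' @param s_fraction fraction of each period in S-phase.
#' @param pulse_amplitudes a.u. per cycle (recycled).
#' @param pulse_widths Lorentzian half-width scale, seconds (recycled).
#' @param center_frac pulse center as a fraction of S-phase length.
#' @param trend_intercept,trend_slope linear trend, a.u. and a.u./s.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param n_tracks number of centriole tracks.
#' @param dt sampling interval, seconds.
#' @param seed RNG seed.
#' @return an object of class `cycling_embryo_spec`.
#' @export
cycling_embryo_spec <- function(n_cycles = 3, cycle_periods = 720,
                                s_fraction = 0.7, pulse_amplitudes = c(1, 0.9, 0.8),
                                pulse_widths = 100, center_frac = 0.45,
                                trend_intercept = 0.1, trend_slope = 0,
                                noise_sd = 0.03, n_tracks = 10, dt = 30,
                                seed = 1L) {
  if (s_fraction <= 0 || s_fraction >= 1) stop_validation("s_fraction in (0,1)")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_periods = rep_len(cycle_periods, n_cycles),
                 s_fraction = s_fraction,
                 pulse_amplitudes = rep_len(pulse_amplitudes, n_cycles),
                 pulse_widths = rep_len(pulse_widths, n_cycles),
                 center_frac = center_frac,
                 trend_intercept = trend_intercept, trend_slope = trend_slope,
                 noise_sd = noise_sd, n_tracks = as.integer(n_tracks),
                 dt = dt, seed = seed),
            class = "cycling_embryo_spec")
}

#' Generate a synthetic cycling embryo
#'
#' Every track's intensity is the sum over cycles of a Lorentzian pulse
#' (amplitude `A_c`, center at `center_frac` of S-phase after CS, width
#' `w_c`) plus the linear trend and i.i.d. Gaussian noise. The generating
#' parameters are returned as ground truth so downstream fits close a
#' recovery loop. Deterministic given the spec's seed.
#'
#' @param spec a [cycling_embryo_spec].
#' @return list with `dataset` (an [embryo_dataset] with cycle annotations)
#'   and `truth` (per-cycle data.frame: cs_time, neb_time, amplitude, center
#'   (absolute s), center_rel (s after CS), width, plus trend and noise_sd).
#' @export
gen_cycling_embryo <- function(spec) {
  stopifnot(inherits(spec, "cycling_embryo_spec"))
  cs <- cumsum(c(0, spec$cycle_periods))[seq_len(spec$n_cycles)]
  s_len <- spec$s_fraction * spec$cycle_periods
  centers <- cs + spec$center_frac * s_len
  t_end <- sum(spec$cycle_periods)
  times <- seq(0, t_end, by = spec$dt)
  clean <- spec$trend_intercept + spec$trend_slope * times
  for (c in seq_len(spec$n_cycles))
    clean <- clean + lorentzian(times, spec$pulse_amplitudes[c], centers[c],
                                spec$pulse_widths[c])
  local_seed(spec$seed, {
    tracks <- lapply(seq_len(spec$n_tracks), function(j)
      centriole_track(sprintf("t%03d", j), "synth_cycling", times,
                      clean + stats::rnorm(length(times), 0, spec$noise_sd)))
    anns <- lapply(seq_len(spec$n_cycles), function(c)
      cycle_annotation(10L + c, cs[c], cs[c] + s_len[c],
                       if (c < spec$n_cycles) cs[c + 1] else NA_real_))
    dataset <- embryo_dataset("synth_cycling", tracks, anns,
                              condition = "synthetic",
                              observation_window = c(0, t_end))
    truth <- data.frame(cycle_index = 10L + seq_len(spec$n_cycles),
                        cs_time = cs, neb_time = cs + s_len,
                        amplitude = spec$pulse_amplitudes,
                        center = centers, center_rel = centers - cs,
                        width = spec$pulse_widths)
    list(dataset = dataset,
         truth = list(cycles = truth, trend = c(intercept = spec$trend_intercept,
                                                slope = spec$trend_slope),
                      noise_sd = spec$noise_sd))
  })
}

#' Specification of a synthetic non-cycling (cyclin-depleted) embryo
#'
#' Emulates embryos arrested by dsRNA against cyclins A/B/B3: "fertile"
#' centrioles carry stochastic low-amplitude Plk4 oscillations (per-receptor
#' model with a constant phosphatase at 10% of mitotic activity) and duplicate
#' preferentially near high-prominence oscillation peaks; "sterile" centrioles
#' carry noise only.
#'
#' @param n_fertile,n_sterile track counts.
#' @param params a [model2_params] for the per-receptor model.
#' @param n_receptors receptors per centriole.
#' @param amplitude a.u. per unit bound fraction for fertile tracks.
#' @param baseline a.u. offset for every track.
#' @param noise_sd measurement noise SD, a.u.
#' @param duplication_link function mapping peak prominence (of the smoothed
#'   bound-fraction signal, in intensity a.u.) to the probability that a
#'   duplication event occurs within `+/- link_window` minutes of the peak.
#'   Default: logistic with midpoint at the working prominence threshold 0.12.
#' @param link_window half-window for planting events, minutes.
#' @param observation_window seconds.
#' @param dt output sampling interval, seconds.
#' @param seed RNG seed.
#' @return an object of class `noncycling_embryo_spec`.
#' @export
noncycling_embryo_spec <- function(n_fertile = 12, n_sterile = 12,
                                   params = model2_params(),
                                   n_receptors = 30, amplitude = 1,
                                   baseline = 0.1, noise_sd = 0.04,
                                   duplication_link = function(prom)
                                     stats::plogis((prom - 0.12) / 0.03),
                                   link_window = 2,
                                   observation_window = c(0, 5400),
                                   dt = 30, seed = 1L) {
  structure(list(n_fertile = as.integer(n_fertile),
                 n_sterile = as.integer(n_sterile), params = params,
                 n_receptors = as.integer(n_receptors), amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 duplication_link = duplication_link,
                 link_window = link_window,
                 observation_window = observation_window, dt = dt, seed = seed),
            class = "noncycling_embryo_spec")
}

#' Generate a synthetic non-cycling embryo
#'
#' Fertile tracks: one simulated centriole each (stochastic receptor chain,
#' constant phosphatase), scaled to fluorescence; candidate duplication sites
#' are the peaks of the 5-point running mean of the noiseless signal, and an
#' event is planted uniformly within `+/- link_window` minutes of each peak
#' with probability `duplication_link(prominence)`. Sterile tracks are
#' baseline plus Gaussian noise. Fate labels and planted peak/event times are
#' returned as ground truth.
#'
#' @param spec a [noncycling_embryo_spec].
#' @return list with `dataset` and `truth` (per-track fate, planted events,
#'   candidate peak times/prominences).
#' @export
gen_noncycling_embryo <- function(spec) {
  stopifnot(inherits(spec, "noncycling_embryo_spec"))
  t0 <- spec$observation_window[1]; t1 <- spec$observation_window[2]
  times <- seq(t0, t1, by = spec$dt)
  duration <- t1 - t0
  local_seed(spec$seed, {
    tracks <- list(); truth <- list()
    for (j in seq_len(spec$n_fertile)) {
      ens <- receptor_ensemble(1, spec$n_receptors, spec$params,
                               pptase_mode = "constant_fraction",
                               dt = spec$dt, seed = NULL)
      sim <- model3_simulate(ens, duration)
      sig <- spec$baseline + spec$amplitude *
        sim$bound_frac[seq_along(times), 1]
      smooth_sig <- stats::filter(sig, rep(1 / 5, 5), sides = 2)
      smooth_sig[is.na(smooth_sig)] <- sig[is.na(smooth_sig)]
      pk <- detect_peaks(as.numeric(smooth_sig), times,
                         prominence_threshold = 0.02)
      events <- numeric(0)
      if (nrow(pk)) {
        p_dup <- spec$duplication_link(pk$prominence)
        hit <- stats::runif(nrow(pk)) < p_dup
        if (any(hit)) {
          ev <- pk$time[hit] +
            stats::runif(sum(hit), -spec$link_window * 60,
                         spec$link_window * 60)
          events <- sort(pmin(pmax(ev, t0), t1))
        }
      }
      noisy <- sig + stats::rnorm(length(times), 0, spec$noise_sd)
      id <- sprintf("fert%03d", j)
      tracks[[id]] <- centriole_track(id, "synth_noncycling", times, noisy,
                                      fate = "fertile",
                                      duplication_times = events)
      truth[[id]] <- list(fate = "fertile", events = events,
                          peak_times = pk$time, prominences = pk$prominence)
    }
    for (j in seq_len(spec$n_sterile)) {
      noisy <- spec$baseline + stats::rnorm(length(times), 0, spec$noise_sd)
      id <- sprintf("ster%03d", j)
      tracks[[id]] <- centriole_track(id, "synth_noncycling", times, noisy,
                                      fate = "sterile")
      truth[[id]] <- list(fate = "sterile", events = numeric(0),
                          peak_times = numeric(0), prominences = numeric(0))
    }
    dataset <- embryo_dataset("synth_noncycling", unname(tracks),
                              condition = "cyclin-depleted (synthetic)",
                              observation_window = spec$observation_window)
    list(dataset = dataset, truth = truth)
  })
}

#' Generate a 2-D spatial point pattern
#'
#' `"CSR"` draws n i.i.d. uniform points in the region (complete spatial
#' randomness); `"clustered"` draws a parent-offspring (Thomas-type) pattern:
#' `n_parents` uniform parents, offspring scattered around them with isotropic
#' Gaussian displacements of SD `cluster_sd`, resampled into the region.
#'
#' @param n number of points.
#' @param region `c(xmin, xmax, ymin, ymax)`.
#' @param pattern `"CSR"` or `"clustered"`.
#' @param n_parents,cluster_sd cluster parameters.
#' @param seed RNG seed.
#' @return a [point_pattern].
#' @export
gen_spatial_points <- function(n, region = c(0, 100, 0, 100),
                               pattern = c("CSR", "clustered"),
                               n_parents = 5, cluster_sd = 2, seed = 1L) {
  pattern <- match.arg(pattern)
  if (n < 0) stop_validation("n must be >= 0")
  local_seed(seed, {
    if (n == 0) {
      pts <- matrix(numeric(0), ncol = 2)
    } else if (pattern == "CSR") {
      pts <- cbind(stats::runif(n, region[1], region[2]),
                   stats::runif(n, region[3], region[4]))
    } else {
      px <- stats::runif(n_parents, region[1], region[2])
      py <- stats::runif(n_parents, region[3], region[4])
      pts <- matrix(NA_real_, n, 2)
      filled <- 0
      while (filled < n) {
        k <- sample.int(n_parents, 1)
        cand <- c(px[k] + stats::rnorm(1, 0, cluster_sd),
                  py[k] + stats::rnorm(1, 0, cluster_sd))
        if (cand[1] >= region[1] && cand[1] <= region[2] &&
            cand[2] >= region[3] && cand[2] <= region[4]) {
          filled <- filled + 1
          pts[filled, ] <- cand
        }
      }
    }
    point_pattern(pts, region)
  })
}

#' Specification of a synthetic photon-count trace
#'
#' @param duration seconds (PeCoS default 180 s).
#' @param bin_width seconds per bin.
#' @param background_rate mean background counts per bin (Poisson).
#' @param emitter_concentration arbitrary units; bursts arrive as a Poisson
#'   process with rate `burst_rate_per_conc * emitter_concentration` per
#'   second.
#' @param burst_amplitude peak burst intensity, counts/bin.
#' @param burst_duration burst decay time (transit time), seconds.
#' @param burst_rate_per_conc bursts per second per concentration unit.
#' @param seed RNG seed.
#' @return an object of class `photon_trace_spec`.
#' @export
photon_trace_spec <- function(duration = 180, bin_width = 1e-3,
                              background_rate = 0.2,
                              emitter_concentration = 1,
                              burst_amplitude = 8, burst_duration = 2e-3,
                              burst_rate_per_conc = 0.5, seed = 1L) {
  if (any(c(duration, bin_width, background_rate, emitter_concentration,
            burst_amplitude, burst_duration) < 0))
    stop_validation("all rates and durations must be >= 0")
  structure(list(duration = duration, bin_width = bin_width,
                 background_rate = background_rate,
                 emitter_concentration = emitter_concentration,
                 burst_amplitude = burst_amplitude,
                 burst_duration = burst_duration,
                 burst_rate_per_conc = burst_rate_per_conc, seed = seed),
            class = "photon_trace_spec")
}

#' Generate a synthetic photon-count trace
#'
#' Poisson background plus Poisson-arriving exponential-decay bursts (a
#' fluorophore transiting the effective volume): the per-bin intensity is
#' `background_rate + sum_bursts amplitude * exp(-(t - t0)/burst_duration)`
#' and counts are Poisson draws from it. The expected burst count is
#' proportional to `emitter_concentration`.
#'
#' @param spec a [photon_trace_spec].
#' @return list with `trace` (a [photon_trace]) and `truth` (`n_bursts`,
#'   `burst_times`).
#' @export
gen_photon_trace <- function(spec) {
  stopifnot(inherits(spec, "photon_trace_spec"))
  n_bins <- round(spec$duration / spec$bin_width)
  t_bins <- (seq_len(n_bins) - 0.5) * spec$bin_width
  local_seed(spec$seed, {
    rate <- rep(spec$background_rate, n_bins)
    lambda_bursts <- spec$burst_rate_per_conc * spec$emitter_concentration *
      spec$duration
    n_bursts <- stats::rpois(1, lambda_bursts)
    t0s <- sort(stats::runif(n_bursts, 0, spec$duration))
    for (t0 in t0s) {
      i0 <- max(1L, ceiling(t0 / spec$bin_width))
      i1 <- min(n_bins, i0 + ceiling(8 * spec$burst_duration / spec$bin_width))
      idx <- i0:i1
      dt <- pmax(t_bins[idx] - t0, 0)
      rate[idx] <- rate[idx] + spec$burst_amplitude *
        exp(-dt / spec$burst_duration)
    }
    counts <- stats::rpois(n_bins, rate)
    list(trace = photon_trace(counts, spec$bin_width),
         truth = list(n_bursts = n_bursts, burst_times = t0s))
  })
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Evaluates an FCS model (see [fcs_model_curve()]) on a lag grid and adds
#' i.i.d. Gaussian noise; the generating parameters are the ground truth for
#' fit-recovery tests. Species fractions must sum to 1.
#'
#' @param spec an [fcs_model_spec].
#' @param params model parameters (see [fcs_model_curve()]).
#' @param tau_grid lag times, ms (default: log-spaced over the fit domain).
#' @param noise_sd Gaussian noise SD on G.
#' @param mean_rate count rate attribute to attach, counts/s.
#' @param seed RNG seed.
#' @return list with `acf` (an `acf_record`-style data.frame) and `truth`.
#' @export
gen_acf_curve <- function(spec, params,
                          tau_grid = 10^seq(log10(4e-4), log10(1.5e3),
                                            length.out = 120),
                          noise_sd = 0, mean_rate = 5e4, seed = 1L) {
  g <- fcs_model_curve(spec, params, tau_grid)
  local_seed(seed, {
    gn <- g + stats::rnorm(length(g), 0, noise_sd)
    acf <- structure(data.frame(tau = tau_grid, G = gn),
                     class = c("acf_record", "data.frame"),
                     duration = NA_real_, mean_rate = mean_rate)
    list(acf = acf, truth = list(spec = spec, params = params,
                                 noise_sd = noise_sd))
  })
}
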