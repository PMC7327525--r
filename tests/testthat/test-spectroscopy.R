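test_that("ACF estimator matches hand values and the brute-force double loop", {
  # alternating counts: <dI dI> = -1, <I>^2 = 4
  tr <- photon_trace(rep(c(1, 3), 60), 1e-3)
  expect_equal(compute_acf(tr, lags = 1)$G, -0.25)
  # constant trace: zero fluctuations
  expect_equal(compute_acf(photon_trace(rep(4, 50), 1e-3), lags = 1:3)$G,
               rep(0, 3))
  expect_error(compute_acf(photon_trace(rep(0, 50), 1e-3), lags = 1), "zero-mean")
  # brute-force equivalence
  set.seed(17)
  counts <- rpois(400, 2)
  tr2 <- photon_trace(counts, 1e-3)
  for (lag in c(1, 5, 20))
    expect_equal(compute_acf(tr2, lags = lag)$G, brute_acf(counts, lag))
  # white Poisson noise decorrelates
  big <- photon_trace(rpois(20000, 3), 1e-3)
  expect_lt(max(abs(compute_acf(big, lags = c(1, 10, 100))$G)), 0.01)
})

test_that("FCS fitting closes the generator loop and obeys N = 1/G0", {
  g0 <- gen_acf_curve(fcs_model_spec(1), list(G0 = 0.1, tauxy = 0.5, A = 1),
                      noise_sd = 0, seed = 1)
  f0 <- fit_acf(g0$acf, models = fcs_model_spec(1))
  expect_equal(f0$N, 10, tolerance = 1e-4)
  # Avogadro arithmetic: N = 10 in 0.28 fL is ~59.3 nM
  expect_equal(f0$concentration_nM, 59.3, tolerance = 0.01)
  # BIC selects the generating dark-state model most of the time
  spec4 <- fcs_model_spec(1, blinking = TRUE, triplet = TRUE)
  truth <- list(G0 = 0.1, tauxy = 0.5, A = 1, T_blink = 0.25, tau_blink = 0.05,
                T_trip = 0.15, tau_trip = 0.004)
  hits <- 0; tau_ok <- 0
  for (s in 1:25) {
    f <- fit_acf(gen_acf_curve(spec4, truth, noise_sd = 2e-4, seed = s)$acf)
    hits <- hits + (f$model == "M4")
    tau_ok <- tau_ok + (abs(f$params$tauxy[1] / truth$tauxy - 1) < 0.1)
  }
  expect_gte(hits, 20)    # >= 80%
  expect_gte(tau_ok, 20)
  # species fractions always sum to 1
  f2 <- fit_acf(gen_acf_curve(fcs_model_spec(2),
                              list(G0 = 0.2, tauxy = c(0.3, 30), A = c(0.4, 0.6)),
                              noise_sd = 1e-4, seed = 3)$acf,
                models = fcs_model_spec(2))
  expect_equal(sum(f2$params$A), 1)
})

test_that("background correction reduces the apparent particle number", {
  g <- gen_acf_curve(fcs_model_spec(1), list(G0 = 0.1, tauxy = 0.5, A = 1),
                     noise_sd = 0, mean_rate = 1e4, seed = 1)
  f_clean <- fit_acf(g$acf, models = fcs_model_spec(1))
  f_bg <- fit_acf(g$acf, models = fcs_model_spec(1), background = 3e3)
  expect_lt(f_bg$N, f_clean$N)
  expect_equal(f_bg$N, f_clean$N / (1 + 3e3 / 1e4)^2, tolerance = 1e-6)
  f_tot <- fit_acf(g$acf, models = fcs_model_spec(1), background = 3e3,
                   background_mode = "total_rate")
  expect_lt(f_tot$N, f_clean$N)
})

test_that("ROUT-style filter flags gross outliers and spares clean data", {
  res <- outlier_filter(c(10, 11, 9, 10, 10, 1000), Q = 1)
  expect_equal(which(res$outliers), 6L)
  expect_false(res$insufficient_data)
  none <- outlier_filter(rep(7, 6), Q = 1)
  expect_false(any(none$outliers))
  # fewer than four survivors raises the insufficiency flag
  few <- outlier_filter(c(1, 1, 1.02, 500, 600, 700), Q = 1)
  expect_true(few$insufficient_data || sum(!few$outliers) >= 4)
  expect_error(outlier_filter(c(1, 2, 3)), ">= 4")
})

test_that("PeCoS counting and calibration behave as the run definition forces", {
  tr <- photon_trace(c(1, 1, 5, 6, 1, 7, 1), 1)
  expect_equal(pecos_count(tr, 4)$peak_count, 2L)
  expect_equal(pecos_count(tr, 10)$peak_count, 0L)
  expect_equal(pecos_count(tr, 4)$peaks_per_minute, 2 / (7 / 60))
  # monotone non-increasing in threshold for separated unimodal bursts
  # (with noisy backgrounds a rising threshold can split a run in two, so the
  # guarantee is a property of burst-shaped signals)
  burst <- function(center, amp) amp * exp(-abs(seq_len(300) - center) / 4)
  tr2 <- photon_trace(round(burst(50, 12) + burst(130, 7) + burst(240, 20)), 0.1)
  counts <- vapply(0:25, function(th) pecos_count(tr2, th)$peak_count, 1L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 3L)
  expect_equal(pecos_count(tr2, max(tr2$counts))$peak_count, 0L)
  # all-zero controls calibrate at n = 1 with zero peaks
  zero <- pecos_calibrate(list(photon_trace(rep(0, 100), 1)))
  expect_equal(zero$n_sigma, 1L)
  expect_equal(zero$mean_control_peaks, 0)
  # calibration returns the smallest qualifying n (independent scan oracle)
  ctrl <- lapply(1:6, function(s)
    gen_photon_trace(photon_trace_spec(duration = 30,
                                       emitter_concentration = 2,
                                       seed = s))$trace)
  cal <- pecos_calibrate(ctrl, max_mean_peaks = 5)
  pooled <- unlist(lapply(ctrl, `[[`, "counts"))
  scan <- vapply(1:50, function(n) mean(vapply(ctrl, function(t)
    sum(diff(c(FALSE, t$counts > mean(pooled) + n * sd(pooled))) == 1),
    1)), 1)
  expect_equal(cal$n_sigma, which(scan < 5)[1])
  # mean control peak count is non-increasing in n
  expect_true(all(diff(scan) <= 1e-12))
})

test_that("PeCoS count responds near-linearly to concentration in the low range", {
  concs <- c(0.2, 0.4, 0.8, 1.6, 3.2)
  counts <- vapply(seq_along(concs), function(i)
    mean(vapply(1:3, function(r)
      pecos_count(gen_photon_trace(photon_trace_spec(
        duration = 60, emitter_concentration = concs[i],
        seed = 100 * i + r))$trace, 3)$peak_count, 1)), 1)
  expect_gt(cor(concs, counts), 0.95)
})
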