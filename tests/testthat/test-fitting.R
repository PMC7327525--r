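test_that("pulse regression recovers noise-free shapes exactly", {
  tt <- seq(0, 500, 30)
  seg <- pulse_segment(tt, lorentzian(tt, 1, 230, 90, 0.1), neb_rel = 500)
  f <- fit_pulse(seg)
  expect_equal(f$model, "Lorentzian")
  expect_equal(f$R2, 1, tolerance = 1e-8)
  expect_equal(f$params$A, 1, tolerance = 1e-6)
  expect_equal(f$params$C, 230, tolerance = 1e-6)
  expect_equal(f$params$w, 90, tolerance = 1e-5)
  # symmetric pulse centered mid-window
  seg2 <- pulse_segment(seq(0, 600, 30),
                        gaussian_pulse(seq(0, 600, 30), 2, 300, 80),
                        neb_rel = 600)
  f2 <- fit_pulse(seg2, candidates = "Gaussian")
  expect_equal(f2$params$C, 300, tolerance = 1e-6)
  expect_error(fit_pulse(pulse_segment(c(0, 30, 60), c(0, 1, 0))), ">= 6")
})

test_that("area under the pulse is baseline-invariant and the C/N ratio sane", {
  tt <- seq(0, 500, 25)
  f0 <- fit_pulse(pulse_segment(tt, lorentzian(tt, 1, 200, 80, 0), neb_rel = 450),
                  candidates = "Lorentzian")
  f5 <- fit_pulse(pulse_segment(tt, lorentzian(tt, 1, 200, 80, 5), neb_rel = 450),
                  candidates = "Lorentzian")
  expect_equal(f0$Omega, f5$Omega, tolerance = 1e-4)
  expect_gt(f0$Omega, 0)
  expect_equal(f0$CN_ratio, 200 / 450, tolerance = 1e-6)
})

test_that("model selection prefers the generating Lorentzian under noise", {
  wins <- 0
  for (s in 1:40) {
    gen <- gen_cycling_embryo(cycling_embryo_spec(n_cycles = 1,
                                                  pulse_amplitudes = 1,
                                                  noise_sd = 0.05, seed = s))
    f <- fit_pulse(segment_and_aggregate(gen$dataset, 11),
                   candidates = c("Lorentzian", "Gaussian"))
    wins <- wins + (f$model == "Lorentzian")
  }
  expect_gte(wins, 36)  # >= 90% of trials
})

test_that("kinetic-model fit is self-consistent and degrades gracefully with noise", {
  ref <- ref_model1_segment()
  fit <- fit_model1(ref$segment)
  expect_gt(fit$R2, 1 - 1e-9)
  expect_equal(fit$params$k1, ref$params$k1, tolerance = 1e-4)
  expect_equal(fit$params$k2, ref$params$k2, tolerance = 1e-4)
  expect_equal(fit$params$A0_init, ref$params$A0_init, tolerance = 1e-3)
  # bounds respected
  expect_lte(fit$params$k1, 1)
  expect_gt(fit$params$k1, 0)
  # recovery error grows with noise level
  err_at <- function(nf) {
    e <- vapply(1:8, function(s) {
      r <- ref_model1_segment(noise_frac = nf, seed = s)
      f <- fit_model1(r$segment)
      max(abs(c(f$params$k1 / r$params$k1, f$params$k2 / r$params$k2,
                f$params$A0_init / r$params$A0_init) - 1))
    }, 1)
    mean(e)
  }
  e0 <- err_at(0); e1 <- err_at(0.01); e5 <- err_at(0.05)
  expect_lt(e0, e1)
  expect_lt(e1, e5)
})

test_that("the fit improves with chain length N then plateaus beyond 4", {
  ref <- ref_model1_segment(noise_frac = 0.01, seed = 2)
  r2 <- vapply(c(1, 4, 9, 14), function(N)
    fit_model1(ref$segment, N = N)$R2, 1)
  expect_lt(r2[1], r2[2])          # N = 1 clearly worse
  expect_gt(min(r2[2:4]), 0.985)   # any N > 4 fits essentially equally well
  expect_lt(max(r2[2:4]) - min(r2[2:4]), 0.015)
})

test_that("Metropolis-Hastings exploration is consistent with the trust-region fit", {
  ref <- ref_model1_segment(noise_frac = 0.01, seed = 20)
  fit <- fit_model1(ref$segment)
  mc <- mcmc_explore(ref$segment, steps = 500, seed = 11)
  expect_lte(mc$best_R2, fit$R2 + 1e-6)
  expect_true(all(mc$samples$R2 > mc$r2_min))
  # retained cloud is widest along k3 (release is not rate-limiting)
  expect_equal(names(which.max(mc$spread)), "k3")
  # sample means near the optimum for the identified parameters
  expect_lt(abs(mean(mc$samples$k1) / fit$params$k1 - 1), 0.25)
  expect_lt(abs(mean(mc$samples$k2) / fit$params$k2 - 1), 0.25)
  # zero proposal width: the chain never moves
  mc0 <- mcmc_explore(ref$segment, steps = 50, proposal_frac = 0,
                      seed = 3)
  expect_equal(nrow(unique(mc0$all_samples[, 1:4])), 4L)
})

test_that("growth-curve fit recovers exact flat-rise-plateau input and flags no growth", {
  tt <- seq(0, 600, 30)
  y <- approx(c(0, 100, 400, 600), c(0.2, 0.2, 3.2, 3.2), xout = tt, rule = 2)$y
  g <- fit_growth_curve(pulse_segment(tt, y))
  expect_false(g$no_growth)
  expect_equal(g$start_time, 100, tolerance = 0.01)
  expect_equal(g$stop_time, 400, tolerance = 0.01)
  expect_equal(g$rate, 0.01, tolerance = 1e-4)
  expect_equal(g$size, 3, tolerance = 1e-3)
  expect_equal(g$size, g$rate * g$period, tolerance = 1e-3)
  # flat input: degenerate growth
  set.seed(1)
  flat <- fit_growth_curve(pulse_segment(tt, rnorm(length(tt), 1, 0.01)))
  expect_true(flat$no_growth)
})

test_that("Plk4 levels at growth start and stop match by construction", {
  tt <- seq(0, 600, 30)
  # symmetric Plk4 pulse; growth breakpoints placed symmetrically about its
  # center, so fitted Plk4 at start == at stop
  plk4 <- fit_pulse(pulse_segment(tt, lorentzian(tt, 1, 300, 90, 0.05),
                                  neb_rel = 600), candidates = "Lorentzian")
  y <- approx(c(0, 150, 450, 600), c(0.1, 0.1, 2.1, 2.1), xout = tt, rule = 2)$y
  g <- fit_growth_curve(pulse_segment(tt, y), plk4_fit = plk4)
  expect_equal(g$plk4_at_start, g$plk4_at_stop, tolerance = 1e-3)
})
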