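test_that("S-phase model: degenerate closed forms", {
  tg <- seq(0, 600, 20)
  # all fluxes zero: constant at the initial bound pool
  p0 <- model1_params(k1 = 0, k2 = 0, k3 = 0, Abound_init = 0.05)
  expect_equal(model1_analytic(p0, tg)$bound, rep(0.05, length(tg)))
  # k2 = 0: chain blocked, bound(t) = Abound + A0 (1 - exp(-k1 t))
  p1 <- model1_params(k1 = 0.03, k2 = 0, k3 = 0.2, A0_init = 1,
                      Abound_init = 0.05)
  expect_equal(model1_analytic(p1, tg)$bound,
               0.05 + 1 * (1 - exp(-0.03 * tg)), tolerance = 1e-12)
  expect_error(model1_params(k1 = -1), "rates")
})

test_that("analytic and adaptive-numerical trajectories agree on a random sweep", {
  set.seed(42)
  for (i in 1:25) {
    p <- model1_params(k1 = runif(1, 1e-3, 0.5), k2 = runif(1, 1e-3, 0.8),
                       k3 = runif(1, 1e-3, 0.3), N = sample(c(1, 4, 9), 1),
                       A0_init = runif(1, 0.5, 2), Abound_init = runif(1, 0, 0.2))
    tg <- seq(0, 600, length.out = 16)
    a <- model1_analytic(p, tg)$bound
    n <- model1_numeric(p, tg)$bound
    expect_lt(max(abs(a - n)) / max(abs(n)), 1e-6)
  }
  # repeated-eigenvalue stress: k1 == k2 exactly
  pe <- model1_params(k1 = 0.05, k2 = 0.05)
  tg <- seq(0, 400, 25)
  expect_lt(max(abs(model1_analytic(pe, tg)$bound -
                      model1_numeric(pe, tg)$bound)), 1e-8)
})

test_that("receptor mass is conserved with released-pool bookkeeping", {
  p <- model1_params()
  tg <- seq(0, 500, 10)
  tr <- model1_numeric(p, tg)
  a_tot <- p$A0_init + p$Abound_init
  bound_cols <- grep("^Astar", names(tr))
  total <- tr$A0 + rowSums(tr[, bound_cols]) + tr$released
  expect_lt(max(abs(total - a_tot)), 1e-9)
  # independent quadrature of the release flux matches the released pool
  fine <- seq(0, 500, 0.25)
  trf <- model1_numeric(p, fine)
  flux <- p$k3 * trf[[paste0("Astar", p$N)]]
  released_quad <- cumsum(c(0, diff(fine) * (flux[-1] + flux[-length(flux)]) / 2))
  expect_lt(max(abs(released_quad - trf$released)), 1e-6)
  # total released Plk4 is non-decreasing
  expect_true(all(diff(tr$released) >= -1e-12))
})

test_that("multi-cycle model sustains one pulse per cycle; no resetting, no pulses", {
  sched <- cycle_schedule(T = 720, n_cycles = 14)
  m2 <- model2_simulate(model2_params(), sched)
  expect_lt(max(abs(m2$mass - 1)), 1e-9)
  pk <- detect_peaks(m2$bound_frac, m2$time,
                     prominence_threshold = 0.05 * max(m2$bound_frac))
  expect_equal(nrow(pk), 14L)
  # k4 = 0: the irreversible chain exhausts receptors after one pulse
  m2z <- model2_simulate(model2_params(k4 = 0), sched)
  pkz <- detect_peaks(m2z$bound_frac, m2z$time,
                      prominence_threshold = 0.05 * max(m2z$bound_frac))
  expect_equal(nrow(pkz), 1L)
  expect_lt(m2z$bound_frac[nrow(m2z)], 0.02 * max(m2z$bound_frac))
})

test_that("conserved-pool variant: receptor mass exact, cytosolic Plk4 declines late", {
  sched <- cycle_schedule(T = 720, n_cycles = 14)
  mc <- model2_simulate(conserved_params(), sched, conserved = TRUE)
  expect_lt(max(abs(mc$mass - 1)), 1e-8)
  # cycle-start snapshots of free cytosolic Plk4 are non-increasing over the
  # last cycles (receptor pool doubles each cycle and sequesters more Plk4)
  starts <- vapply(10:14, function(c)
    mc$P_frac[which.min(abs(mc$time - (c - 1) * 720 - 30))], 1)
  expect_true(all(diff(starts) <= 1e-6))
  # bound-Plk4 percentage grows across late cycles as centrioles multiply
  peak_by_cycle <- vapply(c(8, 11, 14), function(c)
    max(mc$bound_plk4_pct[mc$cycle == c]), 1)
  expect_true(all(diff(peak_by_cycle) > 0))
})

test_that("stochastic receptor chain: frozen at zero rates, stationary occupancy,
           and agreement between fixed-step and exact-jump simulation", {
  pz <- model2_params(k1 = 0, k2 = 0, k3 = 0, k4 = 0)
  ez <- receptor_ensemble(2, 10, pz, pptase_mode = "constant_fraction",
                          dt = 1, seed = 1)
  sz <- model3_simulate(ez, 50)
  expect_true(all(sz$bound_frac == 0))
  expect_true(all(sz$states == 0L))
  # stationary bound occupancy vs the exact CTMC stationary distribution
  p <- model2_params(k1 = 0.05, k2 = 5, k3 = 0.1, k4 = 0.08, N = 1)
  ens <- receptor_ensemble(1, 400, p, pptase_mode = "constant_fraction",
                           pptase_constant_frac = 1, dt = 0.05, seed = 3)
  sim <- model3_simulate(ens, 3000)
  occ <- mean(sim$mean_bound[sim$time > 300])
  # states (A0, A1, A0*, A1*); solve pi Q = 0 by hand-built generator
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- p$k1; Q[2, 1] <- p$k4; Q[3, 4] <- p$k2
  Q[4, 2] <- p$k3; Q[4, 3] <- p$k4
  diag(Q) <- -rowSums(Q)
  pi_st <- abs(MASS::Null(Q)); pi_st <- pi_st / sum(pi_st)
  expect_lt(abs(occ - sum(pi_st[3:4])), 0.03)
  g <- model3_simulate(receptor_ensemble(1, 150, p,
                                         pptase_mode = "constant_fraction",
                                         pptase_constant_frac = 1, dt = 0.05,
                                         seed = 5),
                       3000, method = "gillespie")
  expect_lt(abs(mean(g$mean_bound[g$time > 300]) - sum(pi_st[3:4])), 0.04)
  # seeded determinism
  expect_identical(model3_simulate(ens, 100)$bound_frac,
                   model3_simulate(ens, 100)$bound_frac)
})

test_that("centrioles start synchronised and lose synchrony under constant phosphatase", {
  ens <- receptor_ensemble(10, 30, model2_params(),
                           pptase_mode = "constant_fraction", dt = 2, seed = 12)
  sim <- model3_simulate(ens, 7200)
  # synchrony = mean cross-centriole correlation of the bound fraction:
  # all centrioles start unbound and ride the first pulse together, then the
  # receptors drift apart under the weak constant phosphatase
  first_pulse <- sim$time <= 600 & sim$time > 100
  late <- sim$time >= 4000
  ce <- cor(sim$bound_frac[first_pulse, ])
  cl <- cor(sim$bound_frac[late, ])
  expect_gt(mean(ce[upper.tri(ce)]), 0.5)
  expect_lt(mean(cl[upper.tri(cl)]), 0.3)
})

test_that("model 3 ensemble mean tracks the mean-field ODE", {
  sched <- cycle_schedule(T = 720, n_cycles = 2)
  m2 <- model2_simulate(model2_params(), sched, dt_out = 2)
  ens <- receptor_ensemble(1, 4000, model2_params(),
                           pptase_mode = "mitotic_burst", dt = 0.5, seed = 7)
  m3 <- model3_simulate(ens, 1440, schedule = sched, separation = FALSE)
  m2i <- approx(m2$time, m2$bound_frac, xout = m3$time)$y
  expect_lt(max(abs(m3$mean_bound - m2i)) / max(m2i), 0.05)
})
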