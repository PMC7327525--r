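test_that("peak detection follows the lowest-contour-line prominence definition", {
  # hand-computed prominences: 1.0 for the tall peak, 0.01 for the bump
  x <- c(0, 1, 0, 0.05, 0.06, 0.05)
  pk <- detect_peaks(x, prominence_threshold = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$index, 2L)
  expect_equal(pk$prominence, 1)
  pk_all <- detect_peaks(x, prominence_threshold = 0)
  expect_equal(pk_all$prominence, c(1, 0.01))
  # monotone signal: no local maxima
  expect_equal(nrow(detect_peaks(1:50 / 10, prominence_threshold = 0)), 0L)
  # isolated peak on a flat baseline: prominence equals height above baseline
  y <- rep(0.2, 21); y[11] <- 1.7
  expect_equal(detect_peaks(y, prominence_threshold = 0)$prominence, 1.5)
})

test_that("smooth fit: pure line yields an empty mixture; planted Gaussian recovered", {
  tt <- seq(0, 1500, 30)
  sf <- smooth_fit(0.4 + 0.002 * tt, tt)
  expect_equal(nrow(sf$gaussians), 0L)
  expect_equal(unname(sf$trend["A"]), 0.4, tolerance = 0.05)
  expect_equal(unname(sf$trend["B"]), 0.002, tolerance = 0.05)
  # planted single Gaussian on a line with 1% noise: center within 5 s
  set.seed(8)
  y <- 0.3 + 2e-4 * tt + 1 * exp(-(tt - 300)^2 / 60^2) +
    rnorm(length(tt), 0, 0.01)
  sf2 <- smooth_fit(y, tt)
  expect_equal(nrow(sf2$gaussians), 1L)
  expect_lt(abs(sf2$gaussians$mu - 300), 5)
  # fitted-curve peaks sit at the planted centers
  expect_lt(abs(sf2$peak_times[which.max(sf2$fitted[match(sf2$peak_times, tt)])] - 300), 31)
})

test_that("Otsu threshold equals the exhaustive between-class-variance maximiser", {
  expect_equal(otsu_threshold(c(1, 2, 3, 10, 11, 12)),
               brute_otsu(c(1, 2, 3, 10, 11, 12)))
  set.seed(5)
  for (i in 1:20) {
    v <- c(rnorm(sample(3:10, 1), 0.3, 0.1), rnorm(sample(3:10, 1), 3, 0.5))
    expect_equal(otsu_threshold(v), brute_otsu(v))
  }
  # well-separated modes: threshold strictly between them, perfect classes
  cl <- classify_fertility(c(0.1, 0.1, 0.1, 5, 5, 5),
                           labels = rep(c("sterile", "fertile"), each = 3))
  expect_gt(cl$threshold, 0.1); expect_lt(cl$threshold, 5)
  expect_equal(cl$fertile_recall, 1)
  expect_equal(cl$sterile_recall, 1)
  expect_error(classify_fertility(rep(1, 5)), "constant")
})

test_that("fertility classification separates the synthetic non-cycling embryo", {
  gen <- gen_noncycling_embryo(noncycling_embryo_spec(n_fertile = 8,
                                                      n_sterile = 8, seed = 4))
  snr <- vapply(gen$dataset$tracks,
                function(t) smooth_fit(t$intensity, t$times)$snr, 1)
  fate <- vapply(gen$dataset$tracks, `[[`, "", "fate")
  cl <- classify_fertility(snr, fate)
  expect_gt(cl$fertile_recall, 0.5)
  expect_gt(cl$sterile_recall, 0.5)
})

test_that("unique matching follows prominence priority with nearest-event choice", {
  # hand enumeration: peak at 10 min takes the 12-min event, peak at 30 min
  # takes the 29-min event; the 50-min event stays unmatched
  pk <- data.frame(time = c(10, 30) * 60, prominence = c(0.5, 0.3))
  a <- match_events(pk, c(12, 29, 50) * 60, window = 5)
  expect_equal(sort(a$peak_time), c(600, 1800))
  expect_equal(a$event_time[order(a$peak_time)], c(720, 1740))
  # no peaks: no assignments
  expect_equal(nrow(match_events(empty <- data.frame(time = numeric(0),
                                                     prominence = numeric(0)),
                                 c(100, 200), 5)), 0L)
  # two peaks competing for one event: higher prominence wins
  pk2 <- data.frame(time = c(100, 140), prominence = c(0.2, 0.9))
  a2 <- match_events(pk2, 120, window = 5)
  expect_equal(a2$peak_time, 140)
  # equidistant events: earlier event wins
  pk3 <- data.frame(time = 300, prominence = 1)
  a3 <- match_events(pk3, c(240, 360), window = 5)
  expect_equal(a3$event_time, 240)
})

test_that("greedy matcher equals the enumeration oracle under the priority rule", {
  set.seed(7)
  for (trial in 1:60) {
    np <- sample(0:5, 1); ne <- sample(0:5, 1)
    pt <- sort(runif(np, 0, 3600)); pr <- runif(np)
    ev <- sort(runif(ne, 0, 3600))
    g <- match_events(data.frame(time = pt, prominence = pr), ev, window = 5)
    expect_equal(nrow(g), oracle_match_count(pt, pr, ev, 5))
    # partial injection both ways
    expect_lte(nrow(g), min(np, ne))
    expect_equal(anyDuplicated(g$event_time), 0L)
    expect_equal(anyDuplicated(g$peak_time), 0L)
  }
})

test_that("precision/recall/AP arithmetic matches the printed Venn counts", {
  # 49 peaks, 52 events, 40 matched: precision 40/49, recall 40/52
  peaks <- data.frame(
    time = c(seq(600, by = 600, length.out = 40),        # near an event
             seq(45000, by = 3600, length.out = 9)),     # isolated
    prominence = seq(1, 0.2, length.out = 49))
  events <- c(seq(600, by = 600, length.out = 40) + 60,  # 1 min away
              seq(120000, by = 3600, length.out = 12))   # unreachable
  res <- score_matches(peaks, events, window = 5, n_sims = 0)
  expect_equal(res$n_matched, 40L)
  expect_equal(res$precision, 40 / 49)
  expect_equal(res$recall, 40 / 52)
  expect_gte(res$precision, 0.8)
  expect_equal(res$baseline_AP, 52 / 101)
  # perfectly aligned peaks and events: everything is 1
  t0 <- seq(300, by = 900, length.out = 6)
  perfect <- score_matches(data.frame(time = t0, prominence = 6:1),
                           t0, window = 5, n_sims = 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$AP, 1)
  expect_equal(perfect$correlation$pearson_r, 1)
  expect_equal(perfect$correlation$slope, 1, tolerance = 1e-9)
  expect_equal(perfect$correlation$intercept, 0, tolerance = 1e-9)
  # no peaks: precision reported as 0 with the undefined flag
  none <- score_matches(data.frame(time = numeric(0), prominence = numeric(0)),
                        t0, window = 5, n_sims = 0)
  expect_equal(none$precision, 0)
  expect_true(none$undefined_precision)
})

test_that("PR curve is monotone along the ranking and the random AP converges", {
  set.seed(13)
  peaks <- data.frame(time = sort(runif(30, 0, 20000)), prominence = runif(30))
  events <- sort(runif(25, 0, 20000))
  res <- score_matches(peaks, events, window = 5,
                       observation_window = c(0, 20000), n_sims = 400,
                       seed = 99)
  expect_true(all(diff(res$pr_curve$recall) >= -1e-12))
  # random-ranking AP converges to events/(events+peaks)
  expect_lt(abs(res$sim_baseline_AP - res$baseline_AP),
            3 * res$sim_baseline_AP_sd)
  expect_gt(res$random_mean_separation, 0)
})
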