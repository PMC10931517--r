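test_that("curve combination floors and averages as specified", {
  # single curve above the floor passes through unchanged
  cv <- c(-1, -2, -0.5)
  expect_identical(combine_loglik(list(cv), -5), cv)
  # full truncation gives a flat curve at the floor
  expect_identical(combine_loglik(cbind(c(-9, -8), c(-7, -10)), -5),
                   c(-5, -5))
  # hand arithmetic: mean(-2, max(-10, -5)) = -3.5
  expect_identical(combine_loglik(cbind(-2, -10), -5), -3.5)
  expect_error(combine_loglik(list(), -5), "empty")
  expect_error(combine_loglik(cbind(-2, -3), 0.5), "negative")
})

test_that("lowering the floor never raises the combined curve (200 draws)", {
  set.seed(12)
  for (k in 1:200) {
    curves <- matrix(stats::rnorm(40, mean = -6, sd = 3), 10, 4)
    l1 <- -stats::runif(1, 1, 6)
    l2 <- l1 - stats::runif(1, 0.5, 6)  # lower floor
    c1 <- combine_loglik(curves, l1)
    c2 <- combine_loglik(curves, l2)
    expect_true(all(c2 <= c1 + 1e-12))
    expect_lte(max(c2), max(c1) + 1e-12)  # hence ML is non-increasing
    expect_true(all(c1 >= l1 - 1e-12))
  }
})

test_that("phase estimation takes the earliest global maximum with flags", {
  grid <- seq(0, 24, length.out = 241)[-241]
  ll <- -((grid - 13)^2) / 10
  ph <- estimate_phase(ll, grid)
  expect_equal(ph$T, 13)
  expect_equal(ph$ML, exp(max(ll)))
  flat <- estimate_phase(rep(-2, 240), grid)
  expect_equal(flat$T, 0)
  expect_true("flat_curve" %in% flat$flags)
  bimod <- -pmin((grid - 4)^2, (grid - 16)^2)
  ph2 <- estimate_phase(bimod, grid)
  expect_equal(ph2$T, 4)
  expect_true("multimodal" %in% ph2$flags)
})

test_that("Theta matches direct grid accounting in the edge cases", {
  grid <- seq(0, 24, length.out = 1441)[-1441]
  # flat LRF at its maximum: C stays below 1, so Theta = 1
  expect_equal(theta_metric(rep(1, 1440), grid, T = 6), 1)
  # constant below eta*eps except a single grid point
  lrf <- rep(0.05, 1440)
  lrf[301] <- 1
  expect_equal(theta_metric(lrf, grid, T = grid[301], eta = 0.35,
                            eps = 0.15), 1 / 1440)
  expect_error(theta_metric(rep(1, 10), grid[1:10], 0, eta = 0.6,
                            eps = 1), "Theta configuration")
})

test_that("Theta of a shifted reference curve equals the brute-force fraction", {
  grid <- seq(0, 24, length.out = 1441)[-1441]
  eta <- 0.35; eps <- 0.15
  eta2 <- 0.45; Tp <- 9.25; T0 <- 3.5
  lrf <- eta2 * (1 + eps + cos(2 * pi * (grid - Tp) / 24))
  lrf <- lrf / max(lrf)  # LRF convention: max 1
  got <- theta_metric(lrf, grid, T0, eta, eps)
  oracle <- mean(lrf > eta * (1 + eps + cos(2 * pi * (grid - T0) / 24)))
  expect_equal(got, oracle)
  expect_gt(got, 0)
  expect_lt(got, 1)
})

test_that("raising eta never raises Theta (200 random profiles)", {
  set.seed(13)
  grid <- seq(0, 24, length.out = 241)[-241]
  for (k in 1:200) {
    lrf <- stats::runif(240)
    lrf[sample(240, 1)] <- 1
    etas <- sort(stats::runif(3, 0.05, 0.45))
    th <- vapply(etas, function(e) theta_metric(lrf, grid, T = 12,
                                                eta = e, eps = 0.15),
                 numeric(1))
    expect_true(all(diff(th) <= 0))
  }
})

test_that("Theta is stable under grid refinement on smooth profiles", {
  mk <- function(n) {
    g <- seq(0, 24, length.out = n + 1)[-(n + 1)]
    lrf <- exp(-((g - 10)^2) / 6)
    theta_metric(lrf / max(lrf), g, T = 10)
  }
  expect_lt(abs(mk(1440) - mk(720)), 2 / 720)
})

test_that("peak detection is circular, plateau-aware and height-ranked", {
  grid <- seq(0, 24, length.out = 1441)[-1441]
  # bimodal: heights 1 and 0.8 at 3 h and 15 h, both above C
  lrf <- pmax(exp(-((grid - 3)^2) / 2), 0.8 * exp(-((grid - 15)^2) / 2))
  pk <- find_lrf_peaks(lrf, grid, T = 3)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$time[1], 3, tolerance = 0.02)
  expect_equal(pk$time[2], 15, tolerance = 0.02)
  expect_equal(pk$height, c(1, 0.8), tolerance = 1e-6)
  # unimodal: a single peak, no second
  uni <- exp(-((grid - 9)^2) / 3)
  expect_equal(nrow(find_lrf_peaks(uni, grid, T = 9)), 1)
  # a peak split across the midnight seam is found exactly once
  seam <- exp(-(pmin(abs(grid - 0), 24 - abs(grid - 0))^2) / 2)
  pks <- find_lrf_peaks(seam, grid, T = 0)
  expect_equal(nrow(pks), 1)
  expect_true(pks$time[1] < 0.5 || pks$time[1] > 23.5)
})

test_that("second-peak adjustment follows the window rule", {
  grid <- seq(0, 24, length.out = 1441)[-1441]
  lrf <- pmax(exp(-((grid - 3)^2) / 2), 0.8 * exp(-((grid - 13.5)^2) / 2))
  prof <- list(T = 3, peaks = find_lrf_peaks(lrf, grid, T = 3))
  adj <- adjust_time_by_second_peak(prof, window = c(0, 7))
  expect_true(adj$adjusted)
  expect_equal(adj$T_adjusted, 13.5, tolerance = 0.02)
  prof2 <- list(T = 13, peaks = prof$peaks)
  expect_false(adjust_time_by_second_peak(prof2, c(0, 7))$adjusted)
  prof3 <- list(T = 3, peaks = prof$peaks[1, , drop = FALSE])
  adj3 <- adjust_time_by_second_peak(prof3, c(0, 7))
  expect_equal(adj3$T_adjusted, 3)
  expect_true(adj3$no_second_peak)
})

test_that("profiles on the model's own training data look functional", {
  m <- fx_model()
  pred <- fx_base_pred()
  expect_true(all(pred$theta < 0.5))
  expect_true(all(is.finite(pred$log_ML)))
  expect_true(all(pred$lambda <= 1e-9))  # ML cannot beat the model peak
  # timing close to truth in-sample
  err <- abs(signed_circular_error(pred$T, fx_bundle_es()$times))
  expect_lt(stats::median(err), 1)
})

test_that("the floor recommendation trades off its two conditions", {
  m <- fx_model()
  es <- fx_bundle_es()
  ac <- perturb_clock_data(es, "amplitude_collapse", list(rho = 0.65))
  res <- choose_lthresh(m, es, ac, candidates = seq(-8, -3))
  expect_equal(res$recommended, -6)
  tab <- res$table
  # recommended = largest feasible candidate
  expect_true(tab$feasible[tab$lthresh == -6])
  expect_true(all(!tab$feasible[tab$lthresh > -6]))
  # condition fractions move monotonically with the floor
  expect_true(all(diff(tab$frac_train_flat) <= 0))
  expect_true(all(diff(tab$frac_test_ml_above) >= 0))
  expect_error(choose_lthresh(m, es, ac, numeric(0)), "empty")
  # infeasible scenario falls back with a warning
  expect_warning(
    res2 <- choose_lthresh(m, es, ac, candidates = c(-0.5, -0.2),
                           beta = 1.1),
    "no candidate")
  expect_true(res2$recommended %in% c(-0.5, -0.2))
})

test_that("dysfunction flags separate the perturbation archetypes", {
  m <- fx_model()
  es <- fx_bundle_es()
  base <- fx_base_pred()
  # training-like samples: flags are rare by construction of the cutoffs
  flagged <- predict(m, es, true_times = es$times)
  expect_lt(mean(grepl("lowML", flagged$flags)), 0.1)
  # amplitude collapse drives lowML
  ac <- perturb_clock_data(es, "amplitude_collapse", list(rho = 0.2))
  pa <- predict(m, ac, true_times = es$times)
  expect_gt(mean(grepl("lowML", pa$flags)), 0.5)
  # a frozen clock reliably reports the wrong time with a confident
  # profile: relTwrong at sampling times distant from the frozen phase
  fz <- perturb_clock_data(es, "frozen_clock", list(t_f = 8))
  pf <- predict(m, fz, true_times = es$times)
  distant <- abs(signed_circular_error(es$times, 8)) > 5
  expect_gt(mean(grepl("relTwrong", pf$flags[distant])), 0.5)
  expect_lt(mean(grepl("lowML", pf$flags)), 0.3)
})

test_that("relTwrong needs a collection time and says so", {
  m <- fx_model()
  es <- fx_bundle_es()
  p <- likelihood_profile(m, es$values[, 1, drop = FALSE],
                          instance = es$instances[1])
  expect_message(classify_dysfunction(p, m, true_time = NA),
                 "not assessed")
})

test_that("per-sample results are independent of batch composition", {
  m <- fx_model()
  es <- fx_bundle_es()
  sub <- sample(ncol(es$values), 8)
  batch <- predict(m, es$values[, sub], instances = es$instances[sub],
                   classify = FALSE)
  for (k in seq_along(sub)) {
    single <- predict(m, es$values[, sub[k], drop = FALSE],
                      instances = es$instances[sub[k]], classify = FALSE)
    expect_equal(single$T, batch$T[k], tolerance = 1e-12)
    expect_equal(single$log_ML, batch$log_ML[k], tolerance = 1e-12)
    expect_equal(single$theta, batch$theta[k], tolerance = 1e-12)
  }
})

test_that("rotating the clock of the training data rotates T exactly", {
  es <- fx_bundle_es()
  m <- fx_model()
  es6 <- expression_set(es$values, (es$times + 6) %% 24, es$instances)
  m6 <- clock_model(es6, fx_panel(), training_summary = FALSE)
  for (k in c(3, 40)) {
    p0 <- likelihood_profile(m, es$values[, k, drop = FALSE],
                             instance = es$instances[k])
    p6 <- likelihood_profile(m6, es$values[, k, drop = FALSE],
                             instance = es$instances[k])
    expect_equal(p6$T, (p0$T + 6) %% 24, tolerance = 1e-9)
  }
})
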