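test_that("signed circular errors wrap into (-12, 12]", {
  expect_equal(signed_circular_error(1, 23), 2)
  expect_equal(signed_circular_error(23, 1), -2)
  expect_equal(signed_circular_error(7.5, 7.5), 0)
  expect_equal(signed_circular_error(18, 6), 12)  # +12 at the boundary
  set.seed(14)
  e <- signed_circular_error(stats::runif(100, 0, 24),
                             stats::runif(100, 0, 24))
  expect_true(all(e > -12 & e <= 12))
})

test_that("circular means handle wrap and near-uniform degeneracy", {
  expect_equal(circular_mean_hours(c(23, 1)), 0)
  expect_equal(chronotell:::circular_mean_signed(c(11, -11)), 12)
  expect_warning(
    expect_true(is.na(chronotell:::circular_mean_signed(c(0, 6, 12, 18)))),
    "undefined")
})

test_that("timing displacement corrects a consistent group shift", {
  err <- data.frame(sample_id = paste0("s", 1:6),
                    instance = rep(c("a", "b"), each = 3),
                    T = c(8, 14, 20, 6, 12, 18),
                    T_a = c(6, 12, 18, 6, 12, 18))
  err$signed_error <- signed_circular_error(err$T, err$T_a)
  td <- timing_displacement(err)
  expect_equal(td$displacements$displacement[
    td$displacements$group == "a"], 2, tolerance = 1e-10)
  expect_equal(td$displacements$displacement[
    td$displacements$group == "b"], 0, tolerance = 1e-10)
  expect_equal(td$corrected$corrected_error[1:3], rep(0, 3),
               tolerance = 1e-10)
  expect_equal(nrow(td$pairwise), 1)
})

test_that("group comparisons hold their type-I error under the null", {
  set.seed(15)
  reps <- 400
  rej <- logical(reps)
  for (k in seq_len(reps)) {
    err <- data.frame(instance = rep(c("a", "b"), each = 10),
                      T = 12, T_a = 12)
    err$signed_error <- stats::rnorm(20, 0, 1)
    td <- suppressWarnings(timing_displacement(err))
    rej[k] <- td$pairwise$p < 0.05
  }
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("cosinor fits recover known rhythms", {
  t <- seq(0, 21, by = 3)
  f <- cosinor_fit(t, cos(2 * pi * (t - 6) / 24))
  expect_equal(f$mesor, 0, tolerance = 1e-10)
  expect_equal(f$amplitude, 1, tolerance = 1e-10)
  expect_equal(f$acrophase, 6, tolerance = 1e-8)
  expect_equal(f$phase_lead, 18, tolerance = 1e-8)
  expect_lt(f$p_rhythm, 1e-12)
  fc <- cosinor_fit(t, rep(2, 8))
  expect_equal(fc$amplitude, 0, tolerance = 1e-12)
  expect_equal(fc$p_rhythm, 1)
  # Monte-Carlo recovery within 3 SE at n = 24
  set.seed(16)
  tt <- stats::runif(24, 0, 24)
  y <- 2 + 0.5 * cos(2 * pi * (tt - 20) / 24) + stats::rnorm(24, 0, 0.1)
  fit <- cosinor_fit(tt, y)
  se <- 0.1 / sqrt(12)  # rough scale of the harmonic coefficient SEs
  expect_lt(abs(fit$mesor - 2), 3 * se)
  expect_lt(abs(fit$amplitude - 0.5), 3 * se)
  expect_lt(abs(signed_circular_error(fit$acrophase, 20)),
            3 * se / 0.5 * 24 / (2 * pi))
  expect_error(cosinor_fit(c(0, 0, 12, 12), 1:4), "3 distinct")
})

test_that("PDP regression detects coherent and incoherent phase structure", {
  disp <- c(-2, -1, 0, 1, 2)
  phases <- rbind(g1 = 5 + disp, g2 = 11 + disp, g3 = 23 + disp)
  res <- pdp_regression(phases, disp)
  expect_equal(res$slope, rep(1, 3), tolerance = 1e-10)
  expect_equal(res$r_squared, rep(1, 3), tolerance = 1e-10)
  expect_false(any(res$unwrap_flagged))
  # g3 wraps around midnight; unwrapping must keep it coherent
  phases2 <- rbind(g = (23 + disp) %% 24)
  expect_equal(pdp_regression(phases2, disp)$slope, 1, tolerance = 1e-10)
  # slope recovery with noise
  set.seed(17)
  ph <- 8 + 0.5 * disp + stats::rnorm(5, 0, 0.05)
  fit <- pdp_regression(rbind(g = ph), disp)
  expect_equal(fit$slope, 0.5, tolerance = 0.15)
  expect_error(pdp_regression(phases[, 1:2], disp[1:2]), "3 groups")
})

test_that("null PDP p-values are approximately uniform", {
  set.seed(18)
  n_groups <- 12
  disp <- stats::rnorm(n_groups)
  phases <- matrix(stats::runif(500 * n_groups, 0, 24), 500, n_groups)
  res <- pdp_regression(phases, disp)
  expect_lt(stats::median(res$r_squared), 0.3)
  ks <- stats::ks.test(res$p_slope, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the rank-sum engine matches wilcox.test", {
  set.seed(19)
  x <- matrix(stats::rnorm(5 * 10), 5)
  y <- matrix(stats::rnorm(5 * 14, mean = 0.5), 5)
  p <- chronotell:::rank_sum_rows(x, y)
  for (k in 1:5) {
    ref <- suppressWarnings(stats::wilcox.test(x[k, ], y[k, ],
                                               exact = FALSE))$p.value
    expect_equal(p[k], ref, tolerance = 1e-10)
  }
  # invariant to monotone transforms of the values
  p2 <- chronotell:::rank_sum_rows(exp(x), exp(y))
  expect_equal(p, p2, tolerance = 1e-12)
})

test_that("Theta stratification separates a planted effect from chance", {
  m <- fx_model()
  es <- fx_bundle_es()
  pn <- fx_panel()
  set.seed(20)
  sc <- perturb_clock_data(es, "phase_shift",
                           list(delta = stats::runif(12, -6, 6)))
  coh <- cbind(extract_revs(es, pn)[, 1:48], extract_revs(sc, pn)[, 49:72])
  inst <- c(es$instances[1:48], sc$instances[49:72])
  expr <- matrix(stats::rnorm(40 * 72), 40, 72,
                 dimnames = list(paste0("x", 1:40), colnames(coh)))
  expr[1:10, 49:72] <- expr[1:10, 49:72] + 2.5
  st <- theta_stratify(m, coh, expr, n_range = c(15, 25),
                       instances = inst, iters = 150, seed = 7)
  expect_true(all(diff(st$p_rand$p) <= 0))
  expect_true(all(diff(st$p_theta$p) <= 0))
  expect_gt(st$p_theta$p[st$p_theta$m == 5],
            20 * max(st$p_rand$p[st$p_rand$m == 5], 1 / 150))
  expect_length(intersect(st$bcg, st$gcg), 0)
  # a DE engine that finds nothing yields all-zero curves
  st0 <- theta_stratify(m, coh, expr, n_range = c(15, 25),
                        instances = inst, iters = 100,
                        de_test = function(a, b) character(0), seed = 8)
  expect_true(all(st0$p_rand$p == 0))
  expect_true(all(st0$p_theta$p == 0))
  expect_error(theta_stratify(m, coh, expr, n_range = c(40, 50),
                              instances = inst, iters = 100),
               "half the cohort")
})

test_that("Monte-Carlo curves converge with the iteration count", {
  m <- fx_model()
  es <- fx_bundle_es()
  pn <- fx_panel()
  coh <- extract_revs(es, pn)
  expr <- matrix(stats::rnorm(20 * 72), 20, 72,
                 dimnames = list(paste0("x", 1:20), colnames(coh)))
  expr[1:5, ] <- expr[1:5, ] +
    2 * rep(fx_base_pred()$theta > stats::median(fx_base_pred()$theta),
            each = 5)
  st_a <- theta_stratify(m, coh, expr, n_range = c(10, 20),
                         instances = es$instances, iters = 100, seed = 5)
  st_b <- theta_stratify(m, coh, expr, n_range = c(10, 20),
                         instances = es$instances, iters = 400, seed = 5)
  se <- sqrt(st_a$p_rand$se^2 + st_b$p_rand$se^2)
  expect_true(all(abs(st_a$p_rand$p - st_b$p_rand$p) <=
                    3 * pmax(se, 1 / 100)))
})

test_that("the timestamp-free precision estimator matches the linear oracle", {
  set.seed(21)
  n <- 200
  a <- 2
  sig <- 0.5
  T <- stats::runif(n, 12, 16)
  s <- a * T + stats::rnorm(n, 0, sig)
  loads <- c(1, -0.5, 0.8, 0.3, -1.2)
  revs <- outer(loads, s) + matrix(stats::rnorm(5 * n, 0, 0.05), 5, n)
  rownames(revs) <- paste0("g", 1:5)
  pr <- precision_without_timestamps(revs, T, c(12, 16))
  expect_lt(abs(pr$sd_estimate - sig / a) / (sig / a), 0.15)
  # noiseless limit: deviations vanish
  revs0 <- outer(loads, a * T)
  rownames(revs0) <- paste0("g", 1:5)
  pr0 <- precision_without_timestamps(revs0, T, c(12, 16))
  expect_lt(pr0$sd_estimate, 4 / 240)
  expect_error(precision_without_timestamps(revs[, 1:20], T[1:20],
                                            c(12, 16)), "at least 30")
  # a non-monotone summary errors out
  sN <- sin(2 * pi * T / 2) + stats::rnorm(n, 0, 0.01)
  revsN <- outer(loads, sN)
  rownames(revsN) <- paste0("g", 1:5)
  expect_error(precision_without_timestamps(revsN, T, c(12, 16)),
               "non-monotone")
})
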