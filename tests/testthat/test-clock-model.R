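test_that("local projections recover exact low-rank structure", {
  set.seed(8)
  G <- 10
  U <- qr.Q(qr(matrix(stats::rnorm(G * 3), G)))
  coords <- matrix(stats::rnorm(3 * 15), 3)
  ctr <- stats::rnorm(G)
  X <- ctr + U %*% coords
  pr <- fit_local_projection(X, d = 3)
  Xc <- X - rowMeans(X)
  recon <- pr$basis %*% crossprod(pr$basis, Xc)
  expect_lt(max(abs(recon - Xc)), 1e-8)
  expect_equal(sum(pr$evar), 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  for (k in 1:3) {
    expect_gt(pr$basis[which.max(abs(pr$basis[, k])), k], 0)
  }
})

test_that("rank-deficient timepoints succeed with a warning", {
  X <- matrix(rep(stats::rnorm(6), 5), 6, 5)  # identical columns
  expect_warning(pr <- fit_local_projection(X, d = 3), "degenerate rank")
  expect_equal(pr$evar[2:3], c(0, 0), tolerance = 1e-20)
  expect_error(fit_local_projection(matrix(0, 5, 3), d = 3),
               "lower d")
})

test_that("explained variance matches a full eigendecomposition oracle", {
  set.seed(9)
  X <- matrix(stats::rnorm(144), 12, 12)
  pr <- fit_local_projection(X, d = 3)
  ev <- eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pr$evar, (ev / sum(ev))[1:3], tolerance = 1e-10)
})

test_that("timepoint Gaussians are the sample moments, repaired to PD", {
  f <- fit_timepoint_mvn(matrix(c(0, 0, 0, 2, 0, 0), 3, 2))
  expect_equal(f$mu, c(1, 0, 0))
  expect_true(f$regularised)
  expect_equal(f$sigma[1, 1], 2, tolerance = 1e-6)
  expect_gt(min(eigen(f$sigma, symmetric = TRUE)$values), 0)
  expect_error(fit_timepoint_mvn(matrix(1:3, 3, 1)), "at least 2")
  # Monte-Carlo oracle: moments of a known Gaussian within 3 SE
  set.seed(10)
  S <- matrix(c(2, 0.6, 0.1, 0.6, 1, -0.3, 0.1, -0.3, 0.5), 3)
  R <- chol(S)
  X <- t(matrix(stats::rnorm(3000), ncol = 3) %*% R) + c(1, -2, 0.5)
  f2 <- fit_timepoint_mvn(X)
  se_mu <- sqrt(diag(S) / 1000)
  expect_true(all(abs(f2$mu - c(1, -2, 0.5)) < 3 * se_mu))
  se_S <- sqrt((diag(S) %o% diag(S) + S^2) / 1000)
  expect_true(all(abs(f2$sigma - S) < 3 * se_S))
})

test_that("the fitted model has the right structure and knot fidelity", {
  m <- fx_model()
  expect_s3_class(m, "clock_model")
  expect_length(m$projections, 6)
  expect_length(m$mvn_knots, 6)
  expect_equal(dim(m$mvn_knots[[1]]$mu), c(6, 3))
  expect_equal(length(m$grid_times), 1440)
  # splined means interpolate the fitted knot means (knots lie on grid)
  for (i in 1:6) {
    ki <- round(m$times / m$grid_step) + 1
    expect_lt(max(abs(m$dense[[i]]$mu[ki, ] - m$mvn_knots[[i]]$mu)),
              1e-10)
  }
  # orthonormal bases
  for (i in 1:6) {
    U <- m$projections[[i]]$basis
    expect_lt(max(abs(crossprod(U) - diag(3))), 1e-8)
  }
})

test_that("covariance splines are 24-periodic and PD on the dense grid", {
  m <- fx_model()
  idx <- m$entry_index
  for (i in 1:6) {
    for (e in seq_len(nrow(idx))) {
      sp <- periodic_pchip(m$times,
                           m$mvn_knots[[i]]$sigma[, idx[e, 1], idx[e, 2]])
      expect_lt(abs(sp(0) - sp(24)), 1e-10)
    }
    # independent PD check by eigendecomposition on a grid subsample
    for (r in seq(1, 1440, by = 24)) {
      S <- chronotell:::sym_from_entries(m$dense[[i]]$sigma_entries[r, ],
                                         idx, 3)
      expect_gt(min(eigen(S, symmetric = TRUE)$values), 0)
    }
  }
})

test_that("model fitting is deterministic and archives round-trip", {
  es <- fx_bundle_es()
  panel <- fx_panel()
  m1 <- clock_model(es, panel, training_summary = FALSE)
  m2 <- clock_model(es, panel, training_summary = FALSE)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_clock_model(m1, f1)
  write_clock_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  m3 <- read_clock_model(f1)
  # restored model scores identically
  g <- es$values[, 5, drop = FALSE]
  p1 <- likelihood_profile(m1, g, instance = es$instances[5])
  p3 <- likelihood_profile(m3, g, instance = es$instances[5])
  expect_equal(p1$log_L, p3$log_L, tolerance = 1e-12)
  expect_equal(p1$T, p3$T)
})

test_that("unequal timepoint counts are rejected unless tolerated", {
  es <- fx_bundle_es()
  es_un <- expression_set(es$values[, -1], es$times[-1], es$instances[-1])
  expect_error(clock_model(es_un, fx_panel(), training_summary = FALSE),
               "unequal")
  expect_warning(
    clock_model(es_un, fx_panel(), allow_unequal = TRUE,
                training_summary = FALSE),
    "unequal")
})

test_that("a single-timepoint family reduces to the directly fitted MVN", {
  # with the splined family pinned at a knot, the model density equals a
  # Gaussian fitted directly to the projected data of that timepoint
  m <- fx_model()
  es <- fx_bundle_es()
  revs <- extract_revs(es, fx_panel())
  nrm <- normalise_revs(revs, m$norm, es$instances, m$recipe)
  i <- 2
  j <- 2
  D <- nrm[, es$timepoint_index == j, drop = FALSE]
  P <- crossprod(m$projections[[i]]$basis, D)
  direct <- fit_timepoint_mvn(P)
  ki <- round(m$times[j] / m$grid_step) + 1
  for (k in c(1, 30, 60)) {
    x <- crossprod(m$projections[[i]]$basis, nrm[, k])
    expect_equal(per_timepoint_loglik(m, nrm[, k], i)[ki],
                 mvn_logpdf(drop(x), direct$mu, direct$sigma),
                 tolerance = 1e-8)
  }
})
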