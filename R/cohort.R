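#' Leave-one-out cross-validated timing errors
#'
#' For each held-out unit the model is refitted without it and the held
#' samples are scored against that refit, so every estimate is
#' out-of-sample. `unit = "sample"` removes one column at a time (the
#' refit then tolerates the unequal per-timepoint counts);
#' `unit = "instance"` removes an instance's entire timecourse, the
#' appropriate scheme when asking about instance-level displacement.
#'
#' @param es training [expression_set()].
#' @param panel [gene_panel()] or gene ids.
#' @param unit `"sample"` or `"instance"`.
#' @param ... further arguments to [clock_model()] (`d`, `norm`,
#'   `lthresh`, `grid_n`, ...).
#' @return data.frame of class `timing_errors`: `sample_id`, `instance`,
#'   `T`, `T_a`, `signed_error` (circular, in `(-12, 12]`), `abs_error`,
#'   `log_ML`, `theta`.
#' @export
leave_one_out <- function(es, panel, unit = c("sample", "instance"), ...) {
  unit <- match.arg(unit)
  if (!inherits(panel, "gene_panel")) panel <- gene_panel(panel)
  n <- ncol(es$values)
  holdouts <- if (unit == "sample") {
    as.list(seq_len(n))
  } else {
    lapply(unique(es$instances), function(j) which(es$instances == j))
  }
  if (unit == "sample") {
    warning("leave-one-sample-out leaves unequal timepoint counts; ",
            "refits use unequal-count tolerant fitting", call. = FALSE)
  }
  rows <- lapply(holdouts, function(out_idx) {
    keep <- setdiff(seq_len(n), out_idx)
    es_tr <- expression_set(es$values[, keep, drop = FALSE],
                            es$times[keep], es$instances[keep])
    fit <- suppressWarnings(
      clock_model(es_tr, panel, allow_unequal = (unit == "sample"),
                  training_summary = FALSE, ...))
    held <- extract_revs(es, panel)[, out_idx, drop = FALSE]
    pred <- if (unit == "instance" && fit$norm != "intergene") {
      # the held-out instance has no entry in the refit recipe, so it is
      # timecourse-normalised on its own held-out series -- the standard
      # treatment of timecoursed test data
      es_out <- expression_set(es$values[, out_idx, drop = FALSE],
                               es$times[out_idx], es$instances[out_idx])
      rec_out <- fit_timecourse(es_out, panel)
      norm_mat <- normalise_revs(held, fit$norm, es$instances[out_idx],
                                 rec_out)
      score_norm_matrix(fit, norm_mat, es$sample_ids[out_idx])
    } else {
      predict(fit, held, instances = es$instances[out_idx],
              classify = FALSE)
    }
    data.frame(sample_id = es$sample_ids[out_idx],
               instance = es$instances[out_idx],
               T = pred$T, T_a = es$times[out_idx],
               signed_error = signed_circular_error(pred$T,
                                                    es$times[out_idx]),
               abs_error = abs(signed_circular_error(pred$T,
                                                     es$times[out_idx])),
               log_ML = pred$log_ML, theta = pred$theta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("timing_errors", "data.frame")
  out
}

#' Timing displacement per group and chronotype-corrected errors
#'
#' The timing displacement of a group (tissue, individual or condition)
#' is the circular mean of its signed timing errors; it captures a
#' consistent advance or delay of the group's molecular clock relative
#' to the collection time (its molecular chronotype). Corrected errors
#' subtract the displacement circularly:
#' `signed_circular_error(T, T_a + displacement)`. Groups are compared
#' pairwise on their signed errors with the two-sided Wilcoxon rank-sum
#' test.
#'
#' @param errors a `timing_errors` table from [leave_one_out()] (or any
#'   data.frame with `T`, `T_a`, `signed_error` and the group column).
#' @param group name of the grouping column (default `"instance"`).
#' @return list of class `timing_displacement`: `displacements` (per
#'   group: `displacement`, `n`, `dispersion`, `p_vs_zero` from a
#'   Wilcoxon signed-rank test when `n >= 2`), `corrected` (the input
#'   with `corrected_error`/`corrected_abs_error` columns), `pairwise`
#'   (long table of rank-sum p-values).
#' @export
timing_displacement <- function(errors, group = "instance") {
  g <- as.character(errors[[group]])
  groups <- unique(g)
  disp <- vapply(groups, function(j) {
    circular_mean_signed(errors$signed_error[g == j])
  }, numeric(1))
  n <- vapply(groups, function(j) sum(g == j), numeric(1))
  dispn <- vapply(groups, function(j) {
    e <- errors$signed_error[g == j]
    if (length(e) < 2) return(NA_real_)
    circular_dispersion_hours(e %% 24)
  }, numeric(1))
  p0 <- vapply(groups, function(j) {
    e <- errors$signed_error[g == j]
    if (length(e) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(e, mu = 0)$p.value)
  }, numeric(1))
  displacements <- data.frame(group = groups, displacement = disp, n = n,
                              dispersion = dispn, p_vs_zero = p0,
                              stringsAsFactors = FALSE)
  corrected <- errors
  corr <- signed_circular_error(errors$T, errors$T_a + disp[match(g, groups)])
  corrected$corrected_error <- corr
  corrected$corrected_abs_error <- abs(corr)
  pairs <- if (length(groups) > 1) utils::combn(groups, 2) else NULL
  pairwise <- if (!is.null(pairs)) {
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
               p = apply(pairs, 2, function(pr) {
                 suppressWarnings(stats::wilcox.test(
                   errors$signed_error[g == pr[1]],
                   errors$signed_error[g == pr[2]])$p.value)
               }),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group1 = character(0), group2 = character(0), p = numeric(0))
  }
  structure(list(displacements = displacements, corrected = corrected,
                 pairwise = pairwise),
            class = "timing_displacement")
}

#' @export
print.timing_displacement <- function(x, ...) {
  cat("timing displacements (circular mean of signed errors, hours):\n")
  print(transform(x$displacements,
                  displacement = round(displacement, 2),
                  dispersion = round(dispersion, 2),
                  p_vs_zero = signif(p_vs_zero, 3)), row.names = FALSE)
  invisible(x)
}

#' Cosinor fit of a 24-hour rhythm
#'
#' Least-squares fit of `M + A * cos(2*pi*(t - phi)/24)` through the
#' linearised cosine/sine design. The rhythmicity p-value is the F-test
#' of the two harmonic coefficients against the intercept-only model.
#'
#' @param times sample times in hours.
#' @param values expression values.
#' @param period period in hours (default 24).
#' @return list with `mesor` M, `amplitude` A (>= 0), `acrophase` phi in
#'   `[0, period)` (the peak time), `phase_lead` (`-phi` modulo the
#'   period: the classical cosinor sign convention, under which an
#'   advanced clock has a larger phase -- the convention in which
#'   coherent phase shifts regress on timing displacement with slope
#'   +1), `p_rhythm`, and the underlying `lm` fit.
#' @export
cosinor_fit <- function(times, values, period = 24) {
  if (length(times) < 4) stop("cosinor needs at least 4 samples")
  if (length(unique(times %% period)) < 3) {
    stop("cosinor needs at least 3 distinct times")
  }
  w <- 2 * pi / period
  cx <- cos(w * times)
  sx <- sin(w * times)
  fit <- stats::lm(values ~ cx + sx)
  if (anyNA(stats::coef(fit))) stop("collinear cosinor design")
  b <- stats::coef(fit)
  A <- sqrt(b[["cx"]]^2 + b[["sx"]]^2)
  phi <- (atan2(b[["sx"]], b[["cx"]]) * period / (2 * pi)) %% period
  if (stats::var(values) <= .Machine$double.eps^0.5 *
      max(1, mean(values)^2)) {
    # constant series: no rhythm, and the F-test is 0/0
    p <- 1
  } else {
    a0 <- stats::anova(stats::lm(values ~ 1), fit)
    p <- a0[["Pr(>F)"]][2]
    if (is.na(p)) p <- 1  # zero residual variation in the null fit
  }
  list(mesor = unname(b[1]), amplitude = A, acrophase = phi,
       phase_lead = (-phi) %% period, p_rhythm = p, fit = fit)
}

#' Phase-displacement regression (PDP)
#'
#' For each gene, ordinary least squares of its per-group acrophase on
#' the groups' timing displacements. A slope near 1 with high r-squared
#' indicates the group differences are a coherent phase shift of the
#' whole panel; low r-squared indicates a more complex rearrangement.
#' Acrophases are unwrapped before regression: each phase is shifted by
#' a multiple of 24 h to its nearest representative around the gene's
#' circular mean (the regression presumes the displacements are local,
#' i.e. small relative to the period). Genes whose unwrapped phases
#' still span more than 6 h are flagged but reported.
#'
#' @param phases genes x groups matrix of acrophases (hours); rownames
#'   are gene ids, colnames group labels.
#' @param displacements numeric vector of per-group timing displacements
#'   (hours), aligned to the columns of `phases`.
#' @return data.frame of class `pdp_result`: per gene `slope`,
#'   `intercept`, `r_squared`, `p_slope` (F-test of non-zero slope),
#'   `unwrap_flagged`.
#' @export
pdp_regression <- function(phases, displacements) {
  phases <- as.matrix(phases)
  if (ncol(phases) < 3) stop("PDP regression needs at least 3 groups")
  if (length(displacements) != ncol(phases)) {
    stop("one displacement per group (column) required")
  }
  genes <- rownames(phases)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(phases)))
  rows <- lapply(seq_len(nrow(phases)), function(k) {
    ph <- phases[k, ]
    ctr <- circular_mean_hours(ph)
    unwrapped <- ctr + signed_circular_error(ph, ctr)
    flagged <- diff(range(unwrapped)) > 6
    fit <- stats::lm(unwrapped ~ displacements)
    # perfect coherence is a legitimate input; silence the exact-fit note
    sm <- suppressWarnings(summary(fit))
    fstat <- sm$fstatistic
    p <- if (is.null(fstat)) NA_real_ else {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    }
    data.frame(gene = genes[k],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_slope = unname(p),
               unwrap_flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pdp_result", "data.frame")
  out
}

# Two-sample rank-sum test per gene (rows), normal approximation with
# tie correction and continuity correction -- the deliberately simple
# default differential-expression engine for the Theta stratification.
rank_sum_rows <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  n <- nx + ny
  vapply(seq_len(nrow(x)), function(k) {
    r <- rank(c(x[k, ], y[k, ]))
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- W - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

default_de_test <- function(x, y, alpha = 0.05) {
  p <- rank_sum_rows(x, y)
  padj <- stats::p.adjust(p, method = "BH")
  rownames(x)[padj < alpha]
}

#' Theta stratification with differential-expression resampling
#'
#' Splits a cohort into the `n` samples with the worst clocks by Theta
#' (the bad clock group, BCG) versus the rest (GCG) and asks whether
#' more differentially expressed genes separate them than chance would
#' produce. Two Monte-Carlo curves are estimated over the DEG count `m`:
#' `p_rand(m)`, the probability of seeing `m` or more DEGs when the BCG
#' is a random group of size `n`, and `p_theta(m)`, the same probability
#' when the BCG is the Theta-ranked worst group while the log floor and
#' `n` are drawn randomly from their ranges (so the result is not an
#' artefact of one tuning choice). The default DE engine is a per-gene
#' two-sample rank-sum test with Benjamini-Hochberg adjustment at 0.05;
#' any function `(bcg_matrix, gcg_matrix) -> character vector of gene
#' ids` can be plugged in.
#'
#' @param model a [clock_model()] used to (re)score Theta.
#' @param revs panel expression for the cohort ([expression_set()] or
#'   genes x samples matrix) -- used to recompute Theta at each sampled
#'   log floor.
#' @param expr full expression matrix (genes x samples, same columns) to
#'   test for DEGs.
#' @param n_range integer range `c(lo, hi)` for the BCG size.
#' @param lthresh_range numeric range for the log floor draws (default:
#'   the model's floor, fixed).
#' @param instances instance labels for timecourse-matched modes.
#' @param de_test pluggable DE function; default rank-sum + BH.
#' @param iters Monte-Carlo iterations per curve (>= 100).
#' @param m_values DEG counts at which to report the curves.
#' @param seed optional RNG seed.
#' @return list of class `theta_stratification`: `p_rand`, `p_theta`
#'   (data.frames `m`, `p`, `se`), `bcg`, `gcg` (ids at the model's
#'   floor and the midpoint `n`), `theta` (per-sample values used),
#'   `iters`.
#' @export
theta_stratify <- function(model, revs, expr, n_range,
                           lthresh_range = NULL, instances = NULL,
                           de_test = default_de_test, iters = 1000,
                           m_values = 1:20, seed = NULL) {
  if (iters < 100) stop("use at least 100 Monte-Carlo iterations")
  if (inherits(revs, "expression_set")) {
    if (is.null(instances)) instances <- revs$instances
    revs <- extract_revs(revs, model$panel)
  }
  expr <- as.matrix(expr)
  ncoh <- ncol(revs)
  if (ncol(expr) != ncoh) stop("revs and expr must cover the same samples")
  if (max(n_range) > ncoh / 2) {
    stop("BCG size range exceeds half the cohort")
  }
  if (!is.null(seed)) set.seed(seed)
  # per-sample per-timepoint curves, computed once
  curves <- lapply(seq_len(ncoh), function(k) {
    g <- normalise_test_rev(model, revs[, k, drop = FALSE],
                            if (!is.null(instances)) instances[k])
    vapply(seq_along(model$times), function(i) {
      per_timepoint_loglik(model, g, i)
    }, numeric(length(model$grid_times)))
  })
  theta_at <- function(lth) {
    vapply(curves, function(cv) {
      profile_from_curves(model, cv, lthresh = lth)$theta
    }, numeric(1))
  }
  theta0 <- theta_at(model$lthresh)
  n_draw <- function() sample(seq(n_range[1], n_range[2]), 1)
  lth_draw <- function() {
    if (is.null(lthresh_range)) model$lthresh else {
      stats::runif(1, min(lthresh_range), max(lthresh_range))
    }
  }
  count_degs <- function(bcg_idx) {
    gcg_idx <- setdiff(seq_len(ncoh), bcg_idx)
    length(de_test(expr[, bcg_idx, drop = FALSE],
                   expr[, gcg_idx, drop = FALSE]))
  }
  m_rand <- vapply(seq_len(iters), function(it) {
    count_degs(sample(ncoh, n_draw()))
  }, numeric(1))
  # cache Theta rankings per drawn floor (rounded) to avoid recombining
  theta_cache <- new.env(parent = emptyenv())
  m_theta <- vapply(seq_len(iters), function(it) {
    lth <- lth_draw()
    key <- format(round(lth, 2))
    th <- if (!is.null(theta_cache[[key]])) theta_cache[[key]] else {
      theta_cache[[key]] <- if (is.null(lthresh_range)) theta0 else {
        theta_at(lth)
      }
    }
    n <- n_draw()
    bcg_idx <- order(th, decreasing = TRUE)[seq_len(n)]
    count_degs(bcg_idx)
  }, numeric(1))
  curve <- function(counts) {
    p <- vapply(m_values, function(m) mean(counts >= m), numeric(1))
    data.frame(m = m_values, p = p, se = sqrt(p * (1 - p) / iters))
  }
  n_mid <- round(mean(n_range))
  bcg <- order(theta0, decreasing = TRUE)[seq_len(n_mid)]
  ids <- colnames(revs)
  if (is.null(ids)) ids <- as.character(seq_len(ncoh))
  structure(list(p_rand = curve(m_rand), p_theta = curve(m_theta),
                 bcg = ids[bcg], gcg = ids[-bcg], theta = theta0,
                 iters = iters),
            class = "theta_stratification")
}

#' @export
print.theta_stratification <- function(x, ...) {
  cat("Theta stratification (", x$iters, " iterations):\n", sep = "")
  cat("  BCG size:", length(x$bcg), " GCG size:", length(x$gcg), "\n")
  show <- x$p_rand$m %in% c(1, 2, 5, 10, 20)
  tab <- data.frame(m = x$p_rand$m, p_rand = x$p_rand$p,
                    p_theta = x$p_theta$p)[show, ]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Timing precision without timestamps
#'
#' Estimates an upper bound for the standard deviation of the timing
#' estimate given the expression state, without using any collection
#' times: the window's expression vectors are projected onto their
#' first principal component to give a scalar summary per sample, a
#' Gaussian-kernel local-linear smoothed mean of that summary over
#' the estimated times is fitted (local-linear rather than a local
#' constant so a trend is recovered without boundary bias), and each
#' sample's deviation is the
#' horizontal distance from the smoothed curve (`T` minus the nearest
#' preimage of its summary under the curve, which must be essentially
#' monotone within the window). The SD of these deviations bounds the
#' SD of the conditional timing distribution.
#'
#' @param revs genes x samples expression matrix for the cohort.
#' @param T_values estimated timing per sample (hours).
#' @param window `c(start, end)` hours; only samples with `T` inside are
#'   used (at least 30 required).
#' @param bandwidth kernel bandwidth in hours; default Silverman's rule
#'   on the window's `T` values.
#' @param grid_n number of grid points for the smoothed curve (default
#'   240).
#' @param max_nonmonotone tolerated fraction of wrong-sign slope in the
#'   smoothed curve before erroring (default 0.2).
#' @return list of class `timing_precision`: `sd_estimate`, `deviations`,
#'   `g_tilde` (the PC1 scores), `curve` (grid of `T` and smoothed
#'   mean), `bandwidth`, `n`.
#' @export
precision_without_timestamps <- function(revs, T_values, window,
                                         bandwidth = NULL, grid_n = 240,
                                         max_nonmonotone = 0.2) {
  revs <- as.matrix(revs)
  sel <- T_values >= window[1] & T_values <= window[2]
  if (sum(sel) < 30) {
    stop("need at least 30 samples with T inside the window (have ",
         sum(sel), ")")
  }
  Tw <- T_values[sel]
  X <- t(revs[, sel, drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  g_tilde <- pc$x[, 1]
  if (is.null(bandwidth)) {
    bandwidth <- 0.9 * min(stats::sd(Tw),
                           stats::IQR(Tw) / 1.34) * length(Tw)^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      bandwidth <- diff(window) / 10
    }
  }
  tg <- seq(window[1], window[2], length.out = grid_n)
  mcurve <- vapply(tg, function(t0) {
    w <- stats::dnorm(Tw - t0, sd = bandwidth)
    u <- Tw - t0
    s0 <- sum(w); s1 <- sum(w * u); s2 <- sum(w * u^2)
    den <- s0 * s2 - s1^2
    if (den <= .Machine$double.eps * s0 * s2 || s2 == 0) {
      sum(w * g_tilde) / s0  # degenerate design: local constant
    } else {
      (s2 * sum(w * g_tilde) - s1 * sum(w * u * g_tilde)) / den
    }
  }, numeric(1))
  slopes <- diff(mcurve)
  main_sign <- sign(mcurve[length(mcurve)] - mcurve[1])
  if (main_sign == 0) main_sign <- sign(sum(slopes))
  frac_bad <- mean(sign(slopes) == -main_sign)
  if (frac_bad > max_nonmonotone) {
    stop("smoothed mean curve is non-monotone over ",
         round(100 * frac_bad), "% of the window; use a narrower window")
  }
  # invert via the monotone envelope of the smoothed curve (flip a
  # decreasing curve so the interpolation abscissae ascend)
  if (main_sign >= 0) {
    mono <- cummax(mcurve)
    T_star <- stats::approx(x = mono, y = tg, xout = g_tilde, rule = 2,
                            ties = "ordered")$y
  } else {
    mono <- cummin(mcurve)
    T_star <- stats::approx(x = rev(mono), y = rev(tg), xout = g_tilde,
                            rule = 2, ties = "ordered")$y
  }
  deviations <- Tw - T_star
  structure(list(sd_estimate = stats::sd(deviations),
                 deviations = deviations, g_tilde = g_tilde,
                 curve = data.frame(T = tg, mean_g = mcurve),
                 bandwidth = bandwidth, n = length(Tw)),
            class = "timing_precision")
}

#' @export
print.timing_precision <- function(x, ...) {
  cat(sprintf(paste0("timing precision (n = %d, bandwidth = %.2f h): ",
                     "SD upper bound %.3f h\n"),
              x$n, x$bandwidth, x$sd_estimate))
  invisible(x)
}
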