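check_theta_config <- function(eta, eps) {
  if (!(eta > 0 && eps > 0 && eta * eps < eta * (2 + eps) &&
        eta * (2 + eps) < 1)) {
    stop("invalid Theta configuration: need 0 < eta*eps < eta*(2+eps) < 1",
         " (eta = ", eta, ", eps = ", eps, ")")
  }
  invisible(TRUE)
}

# reference cosine curve for the Theta metric
theta_reference <- function(grid_times, T, eta, eps) {
  eta * (1 + eps + cos(2 * pi * (grid_times - T) / 24))
}

#' Per-timepoint log-likelihood curve of one normalised sample
#'
#' Log-density of the sample's projection through the local basis of
#' training timepoint `i`, evaluated under the splined Gaussian family of
#' that timepoint at every grid time of day.
#'
#' @param model a [clock_model()].
#' @param g_norm normalised panel expression vector (model's
#'   normalisation mode already applied).
#' @param i training timepoint index.
#' @return numeric vector of log-likelihoods, one per model grid time.
#' @export
per_timepoint_loglik <- function(model, g_norm, i) {
  if (length(g_norm) != length(model$panel$genes)) {
    stop("sample vector length does not match the panel")
  }
  x <- drop(crossprod(model$projections[[i]]$basis, g_norm))
  dn <- model$dense[[i]]
  err <- sweep(-dn$mu, 2, x, FUN = "+")  # grid x d residuals
  idx <- model$entry_index
  w <- ifelse(idx[, 1] == idx[, 2], 1, 2)
  quad <- numeric(nrow(err))
  for (e in seq_len(nrow(idx))) {
    quad <- quad + w[e] * dn$inv_entries[, e] *
      err[, idx[e, 1]] * err[, idx[e, 2]]
  }
  -0.5 * (model$d * log(2 * pi) + dn$logdet + quad)
}

#' Combine per-timepoint log-likelihood curves with a floor
#'
#' The combined curve is the pointwise mean of the per-timepoint curves
#' after each is floored at `lthresh`:
#' `log L(t) = mean_i max(log L_i(t), lthresh)`. The floor protects the
#' average from unreliable, exceptionally low local densities; the
#' output is everywhere at least `lthresh`.
#'
#' @param curves matrix (grid x timepoints) or list of equal-length
#'   per-timepoint log-likelihood vectors.
#' @param lthresh negative log floor.
#' @return combined log-likelihood vector.
#' @export
combine_loglik <- function(curves, lthresh) {
  if (is.list(curves)) {
    if (!length(curves)) stop("empty curve list")
    curves <- do.call(cbind, curves)
  }
  curves <- as.matrix(curves)
  if (!ncol(curves)) stop("empty curve list")
  if (lthresh >= 0) stop("lthresh must be negative (log scale)")
  rowMeans(pmax(curves, lthresh))
}

#' Internal phase estimate from a combined likelihood curve
#'
#' The internal phase `T` is the grid time of the global maximum
#' (earliest such time when tied, with ties reported: `multimodal` for
#' several exact global maxima, `flat_curve` for an all-equal curve).
#'
#' @param log_L combined log-likelihood vector.
#' @param grid_times grid times in hours (same length).
#' @return list with `T`, `ML` (= `exp(max)`), `log_ML`, `flags`.
#' @export
estimate_phase <- function(log_L, grid_times) {
  if (!length(log_L)) stop("empty likelihood curve")
  m <- max(log_L)
  at <- which(log_L == m)
  flags <- character(0)
  if (length(at) == length(log_L)) {
    flags <- "flat_curve"
  } else if (length(at) > 1) {
    flags <- "multimodal"
  }
  list(T = grid_times[at[1]], ML = exp(m), log_ML = m, flags = flags)
}

#' Theta: time spent by the LRF above the reference cosine
#'
#' The dysfunction metric Theta is the proportion of the day on which
#' the likelihood-ratio function strictly exceeds
#' `C(t|T) = eta * (1 + eps + cos(2*pi*(t - T)/24))`, the scaled cosine
#' whose maximum sits at the estimated phase `T`. A sharply peaked LRF
#' gives small Theta; wide peaks, secondary peaks and flat truncated
#' regions all add to it.
#'
#' @param lrf likelihood-ratio values on the grid (max 1 at `T`).
#' @param grid_times grid times in hours.
#' @param T internal phase estimate.
#' @param eta,eps reference-curve parameters (defaults 0.35, 0.15; must
#'   satisfy `0 < eta*eps < eta*(2+eps) < 1`).
#' @return Theta in `[0, 1]`.
#' @export
theta_metric <- function(lrf, grid_times, T, eta = 0.35, eps = 0.15) {
  check_theta_config(eta, eps)
  mean(lrf > theta_reference(grid_times, T, eta, eps))
}

#' Circular peak detection on a likelihood-ratio function
#'
#' Local maxima of the LRF on the circular grid (plateaus count once;
#' peaks split across the midnight seam are wrapped). By default a peak
#' is kept when its height exceeds the Theta reference curve `C(t|T)` at
#' its location -- the "significant" peaks that contribute to Theta; a
#' stricter absolute `min_height` can be given instead. Peaks are sorted
#' by descending height, so the first row is the main peak and the
#' second row, when present, is the second peak used for second-peak
#' timing adjustment.
#'
#' @param lrf likelihood-ratio values on the grid.
#' @param grid_times grid times in hours.
#' @param T internal phase (reference-curve anchor).
#' @param eta,eps reference-curve parameters.
#' @param min_height optional absolute height threshold replacing the
#'   reference-curve rule.
#' @return data.frame with columns `time` and `height` (possibly zero
#'   rows).
#' @export
find_lrf_peaks <- function(lrf, grid_times, T, eta = 0.35, eps = 0.15,
                           min_height = NULL) {
  n <- length(lrf)
  r <- rle(lrf)
  k <- length(r$values)
  if (k == 1) {
    return(data.frame(time = numeric(0), height = numeric(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # circular neighbours of each run; runs 1 and k are distinct values
  # here unless the curve wraps with equal value at the seam
  wrap_merge <- r$values[1] == r$values[k]
  run_ids <- seq_len(k)
  is_peak <- logical(k)
  for (q in run_ids) {
    prev <- if (q == 1) k else q - 1
    nxt <- if (q == k) 1 else q + 1
    if (wrap_merge) {
      if (q == 1) prev <- k - 1
      if (q == k) next  # merged into run 1
    }
    is_peak[q] <- r$values[q] > r$values[prev] && r$values[q] > r$values[nxt]
  }
  peak_time <- numeric(0)
  peak_height <- numeric(0)
  for (q in which(is_peak)) {
    if (wrap_merge && q == 1) {
      len1 <- r$lengths[1]
      lenk <- r$lengths[k]
      members <- c(seq(starts[k], n), seq_len(len1))
      mid <- members[ceiling(length(members) / 2)]
    } else {
      mid <- floor((starts[q] + ends[q]) / 2)
    }
    peak_time <- c(peak_time, grid_times[mid])
    peak_height <- c(peak_height, r$values[q])
  }
  keep <- if (is.null(min_height)) {
    peak_height > theta_reference(peak_time, T, eta, eps)
  } else {
    peak_height >= min_height
  }
  out <- data.frame(time = peak_time[keep], height = peak_height[keep])
  out[order(-out$height), , drop = FALSE]
}

# Full single-sample profile from an already-normalised panel vector.
profile_from_norm <- function(model, g_norm, sample_id = "sample",
                              lthresh = model$lthresh) {
  nt <- length(model$times)
  curves <- vapply(seq_len(nt), function(i) {
    per_timepoint_loglik(model, g_norm, i)
  }, numeric(length(model$grid_times)))
  profile_from_curves(model, curves, sample_id, lthresh)
}

profile_from_curves <- function(model, curves, sample_id = "sample",
                                lthresh = model$lthresh) {
  nt <- length(model$times)
  grid <- model$grid_times
  log_L <- combine_loglik(curves, lthresh)
  ph <- estimate_phase(log_L, grid)
  lrf <- exp(log_L - ph$log_ML)
  Cref <- theta_reference(grid, ph$T, model$eta, model$eps)
  theta <- mean(lrf > Cref)
  peaks <- find_lrf_peaks(lrf, grid, ph$T, model$eta, model$eps)
  flat <- log_L <= min(log_L) + 1e-9
  flat_fraction <- if (min(log_L) <= lthresh + 1e-9) mean(flat) else 0
  flat_above_C <- flat_fraction > 0 && any(flat & lrf > Cref)
  # model's own peak density at T, on the same truncated-log scale
  ti <- which.min(abs(grid - ph$T))
  log_M <- mean(vapply(seq_len(nt), function(i) {
    max(-0.5 * (model$d * log(2 * pi) + model$dense[[i]]$logdet[ti]),
        lthresh)
  }, numeric(1)))
  structure(list(sample_id = sample_id,
                 grid_times = grid,
                 log_L = log_L,
                 lrf = lrf,
                 T = ph$T,
                 ML = ph$ML,
                 log_ML = ph$log_ML,
                 theta = theta,
                 lambda = ph$log_ML - log_M,
                 peaks = peaks,
                 flat_fraction = flat_fraction,
                 flat_above_C = flat_above_C,
                 lthresh = lthresh,
                 flags = ph$flags),
            class = "likelihood_profile")
}

#' Likelihood profile of a single test sample
#'
#' Normalises one raw panel expression vector with the model's recipe
#' and mode, evaluates its per-timepoint likelihood curves, combines
#' them under the log floor, and derives the internal phase `T`, the
#' maximum likelihood ML, the likelihood-ratio function, Theta, the
#' peak list, the flat-region accounting and the likelihood-ratio
#' statistic `lambda = log(ML / M)` (with `M` the model's own maximum
#' density at `T`).
#'
#' @param model a [clock_model()].
#' @param rev raw panel expression vector, named by gene or in panel
#'   order.
#' @param instance instance label (required for timecourse-matched
#'   normalisation modes).
#' @param sample_id label carried through to the output.
#' @param lthresh log floor; defaults to the model's.
#' @return An object of class `likelihood_profile`.
#' @export
likelihood_profile <- function(model, rev, instance = NULL,
                               sample_id = "sample",
                               lthresh = model$lthresh) {
  g_norm <- normalise_test_rev(model, rev, instance)
  profile_from_norm(model, g_norm, sample_id, lthresh)
}

# score an already-normalised genes x samples matrix; used where the
# normalisation was necessarily done outside the model's recipe (e.g.
# leave-one-instance-out, where the held-out instance normalises on its
# own timecourse)
score_norm_matrix <- function(model, norm_mat, ids = colnames(norm_mat),
                              lthresh = model$lthresh) {
  if (is.null(ids)) ids <- paste0("sample_", seq_len(ncol(norm_mat)))
  rows <- lapply(seq_len(ncol(norm_mat)), function(k) {
    p <- profile_from_norm(model, norm_mat[, k], ids[k], lthresh)
    data.frame(sample_id = ids[k], T = p$T, ML = p$ML, log_ML = p$log_ML,
               theta = p$theta, lambda = p$lambda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# normalise a raw test vector (or matrix) per the model's mode
normalise_test_rev <- function(model, rev, instance = NULL) {
  genes <- model$panel$genes
  m <- if (is.matrix(rev)) rev else matrix(rev, ncol = 1)
  if (!is.null(rownames(m))) {
    missing <- setdiff(genes, trimws(rownames(m)))
    if (length(missing)) {
      stop("panel gene(s) missing from test data: ",
           paste(missing, collapse = ", "))
    }
    rownames(m) <- trimws(rownames(m))
    m <- m[genes, , drop = FALSE]
  } else if (nrow(m) != length(genes)) {
    stop("unnamed test vector must have one entry per panel gene")
  } else {
    rownames(m) <- genes
  }
  if (model$norm == "intergene") {
    out <- intergene_normalise(m)
  } else {
    if (is.null(instance)) {
      stop("normalisation mode '", model$norm,
           "' needs the test sample's instance label")
    }
    out <- normalise_revs(m, model$norm,
                          rep_len(as.character(instance), ncol(m)),
                          model$recipe)
  }
  if (ncol(out) == 1) drop(out) else out
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat("likelihood_profile '", x$sample_id, "':\n", sep = "")
  cat(sprintf("  T = %.2f h   log-ML = %.3f   Theta = %.4f   lambda = %.3f\n",
              x$T, x$log_ML, x$theta, x$lambda))
  cat("  peaks above C(t|T):", nrow(x$peaks),
      if (nrow(x$peaks) >= 2) sprintf(" (second peak at %.2f h)",
                                      x$peaks$time[2]) else "", "\n")
  if (x$flat_fraction > 0) {
    cat(sprintf("  truncated-flat fraction: %.3f%s\n", x$flat_fraction,
                if (x$flat_above_C) " (contributes to Theta)" else ""))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.likelihood_profile <- function(x, ...) {
  graphics::plot(x$grid_times, x$lrf, type = "l", xlab = "time of day (h)",
                 ylab = "likelihood ratio", ylim = c(0, 1),
                 main = x$sample_id, ...)
  mdl_C <- theta_reference(x$grid_times, x$T, 0.35, 0.15)
  graphics::lines(x$grid_times, mdl_C, lty = 2, col = "grey40")
  graphics::abline(v = x$T, col = "red3", lty = 3)
  invisible(x)
}

#' Second-peak timing adjustment
#'
#' When the estimated phase falls inside a window of implausible times
#' (for example before 7 am for daytime clinic sampling) and the LRF has
#' a second significant peak, the timing is replaced by the second
#' peak's time; otherwise it is returned unchanged.
#'
#' @param profile a `likelihood_profile`.
#' @param window `c(start, end)` hours defining the implausible window
#'   (default `c(0, 7)`).
#' @return list with `T_adjusted`, `adjusted` (logical) and
#'   `no_second_peak` (logical flag set when adjustment was wanted but
#'   no second peak exists).
#' @export
adjust_time_by_second_peak <- function(profile, window = c(0, 7)) {
  T <- profile$T
  in_window <- T >= window[1] && T < window[2]
  if (in_window && nrow(profile$peaks) >= 2) {
    list(T_adjusted = profile$peaks$time[2], adjusted = TRUE,
         no_second_peak = FALSE)
  } else {
    list(T_adjusted = T, adjusted = FALSE,
         no_second_peak = in_window && nrow(profile$peaks) < 2)
  }
}

#' Score test samples against a fitted clock model
#'
#' Computes one likelihood profile per sample and returns the per-sample
#' diagnostics as a data frame. Each sample is scored independently: the
#' result for a sample is identical whether it is scored alone or in any
#' batch.
#'
#' @param object a [clock_model()].
#' @param newdata an [expression_set()] or a genes x samples matrix with
#'   gene rownames.
#' @param instances instance labels (taken from `newdata` when it is an
#'   expression set); required for timecourse-matched modes.
#' @param true_times optional known collection times for dysfunction
#'   classification of the `relTwrong` type.
#' @param lthresh log floor (defaults to the model's).
#' @param adjust_window optional `c(start, end)` window for second-peak
#'   timing adjustment; when given a `T_adjusted` column is filled.
#' @param classify add dysfunction flags using the model's training
#'   score distributions (default: when those are available).
#' @param ... unused.
#' @return data.frame of class `clock_prediction` with one row per
#'   sample (`sample_id`, `T`, `T_adjusted`, `ML`, `log_ML`, `theta`,
#'   `lambda`, `n_peaks`, `second_peak_time`, `flat_fraction`, `flags`);
#'   the full profiles are attached as attribute `"profiles"`.
#' @export
predict.clock_model <- function(object, newdata, instances = NULL,
                                true_times = NULL,
                                lthresh = object$lthresh,
                                adjust_window = NULL,
                                classify = !is.null(object$training),
                                ...) {
  if (inherits(newdata, "expression_set")) {
    if (is.null(instances)) instances <- newdata$instances
    mat <- extract_revs(newdata, object$panel)
  } else {
    mat <- as.matrix(newdata)
  }
  n <- ncol(mat)
  ids <- colnames(mat)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(n))
  if (!is.null(instances)) instances <- rep_len(instances, n)
  profiles <- lapply(seq_len(n), function(k) {
    likelihood_profile(object, mat[, k, drop = FALSE],
                       instance = if (!is.null(instances)) instances[k],
                       sample_id = ids[k], lthresh = lthresh)
  })
  rows <- lapply(seq_len(n), function(k) {
    p <- profiles[[k]]
    adj <- if (!is.null(adjust_window)) {
      adjust_time_by_second_peak(p, adjust_window)
    } else {
      list(T_adjusted = NA_real_, adjusted = FALSE)
    }
    flags <- p$flags
    if (classify) {
      flags <- c(flags, classify_dysfunction(
        p, object,
        true_time = if (!is.null(true_times)) true_times[k]))
    }
    data.frame(sample_id = p$sample_id, T = p$T,
               T_adjusted = adj$T_adjusted, ML = p$ML, log_ML = p$log_ML,
               theta = p$theta, lambda = p$lambda,
               n_peaks = nrow(p$peaks),
               second_peak_time = if (nrow(p$peaks) >= 2) {
                 p$peaks$time[2]
               } else NA_real_,
               flat_fraction = p$flat_fraction,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  class(out) <- c("clock_prediction", "data.frame")
  out
}

#' Classify dysfunction type of a scored sample
#'
#' Flags relative to the training-score distributions stored in the
#' model: `lowML` when the sample's log-ML falls below the `ql` training
#' quantile (the sample lies far from the training clock's manifold);
#' `highTvar` when Theta exceeds the `qh` training quantile with a
#' non-flat contribution (secondary peaks or a wide main peak);
#' `relTwrong` when, despite a confident profile (neither of the above),
#' the timing is further than `err_thresh` hours (circularly) from the
#' known collection time.
#'
#' @param profile a `likelihood_profile`.
#' @param model the fitted [clock_model()] (with training summary).
#' @param true_time known collection time in hours, or `NULL` (then
#'   `relTwrong` is skipped with a notice).
#' @param ql,qh training quantiles for the lowML / highTvar cutoffs
#'   (defaults 0.01, 0.99).
#' @param err_thresh circular timing-error threshold in hours for
#'   `relTwrong` (default 4).
#' @return character vector of flags (possibly empty).
#' @export
classify_dysfunction <- function(profile, model, true_time = NULL,
                                 ql = 0.01, qh = 0.99, err_thresh = 4) {
  if (is.null(model$training)) {
    stop("model has no training summary; refit with training_summary = TRUE")
  }
  flags <- character(0)
  ml_cut <- stats::quantile(model$training$log_ml, ql, names = FALSE)
  th_cut <- stats::quantile(model$training$theta, qh, names = FALSE)
  if (profile$log_ML < ml_cut) flags <- c(flags, "lowML")
  nonflat <- nrow(profile$peaks) >= 2 || !profile$flat_above_C
  if (profile$theta > th_cut && nonflat) flags <- c(flags, "highTvar")
  if (is.null(true_time)) {
    return(flags)
  }
  if (is.na(true_time)) {
    message("no collection time for '", profile$sample_id,
            "': relTwrong not assessed")
    return(flags)
  }
  err <- abs(signed_circular_error(profile$T, true_time))
  if (err > err_thresh && !("lowML" %in% flags) &&
      !("highTvar" %in% flags)) {
    flags <- c(flags, "relTwrong")
  }
  flags
}

#' Data-driven recommendation for the log floor
#'
#' Picks the largest candidate floor such that (i) at most `alpha` of
#' the training/control samples have truncated-flat LRF regions rising
#' above the Theta reference curve (so flat regions contribute to Theta
#' for very few good clocks), and (ii) at least `beta` of the test
#' samples keep their maximum likelihood above `exp(lthresh)`. When no
#' candidate satisfies both, the candidate maximising (ii) subject to
#' (i) is returned with a warning; the full trade-off table accompanies
#' the recommendation either way. Per-timepoint curves are computed once
#' and re-combined per candidate, so scanning many candidates is cheap.
#'
#' @param model a [clock_model()].
#' @param train training/control samples: [expression_set()] or matrix.
#' @param test test samples: [expression_set()] or matrix.
#' @param candidates numeric vector of candidate floors (negative).
#' @param alpha cap on the flat-contribution fraction in training
#'   samples (default 0.05).
#' @param beta target fraction of test samples with `log ML` above the
#'   floor (default 0.9).
#' @param train_instances,test_instances instance labels when matrices
#'   are supplied under timecourse-matched modes.
#' @return list with `recommended` and `table` (one row per candidate:
#'   `frac_train_flat`, `frac_test_ml_above`, `feasible`).
#' @export
choose_lthresh <- function(model, train, test, candidates,
                           alpha = 0.05, beta = 0.9,
                           train_instances = NULL, test_instances = NULL) {
  if (!length(candidates)) stop("empty candidate list")
  candidates <- sort(candidates, decreasing = TRUE)
  curves_of <- function(data, inst) {
    if (inherits(data, "expression_set")) {
      inst <- data$instances
      data <- extract_revs(data, model$panel)
    }
    data <- as.matrix(data)
    lapply(seq_len(ncol(data)), function(k) {
      g <- normalise_test_rev(model, data[, k, drop = FALSE],
                              if (!is.null(inst)) inst[k])
      vapply(seq_along(model$times), function(i) {
        per_timepoint_loglik(model, g, i)
      }, numeric(length(model$grid_times)))
    })
  }
  train_curves <- curves_of(train, train_instances)
  test_curves <- curves_of(test, test_instances)
  # test MLs evaluated once, essentially untruncated (floor well below
  # every candidate), then compared against each candidate floor
  ref_floor <- min(candidates) - 5
  te_ml <- vapply(test_curves, function(cv) {
    max(combine_loglik(cv, ref_floor))
  }, numeric(1))
  rows <- lapply(candidates, function(cand) {
    tr_flat <- vapply(train_curves, function(cv) {
      p <- profile_from_curves(model, cv, lthresh = cand)
      p$flat_above_C
    }, logical(1))
    data.frame(lthresh = cand,
               frac_train_flat = mean(tr_flat),
               frac_test_ml_above = mean(te_ml > cand))
  })
  tab <- do.call(rbind, rows)
  tab$feasible <- tab$frac_train_flat <= alpha &
    tab$frac_test_ml_above >= beta
  if (any(tab$feasible)) {
    rec <- tab$lthresh[which(tab$feasible)[1]]
  } else {
    ok_i <- tab$frac_train_flat <= alpha
    pool <- if (any(ok_i)) which(ok_i) else seq_len(nrow(tab))
    rec <- tab$lthresh[pool[which.max(tab$frac_test_ml_above[pool])]]
    warning("no candidate satisfies both conditions; returning the ",
            "candidate maximising test-ML coverage (see the table)")
  }
  list(recommended = rec, table = tab)
}
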