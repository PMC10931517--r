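#' Local PCA projection for one training timepoint
#'
#' Principal components of the normalised panel vectors observed at one
#' training timepoint. The data are centred by the timepoint mean before
#' extracting components; the returned basis is the first `d` principal
#' directions with a fixed sign convention (the largest-magnitude loading
#' of each component is positive) so that repeated fits are reproducible.
#' Projection of a sample is `t(basis) %*% g` (uncentred: the centring
#' shift is absorbed into the projected means of the fitted Gaussians).
#'
#' @param revs_at_t G x N_s matrix of normalised expression vectors.
#' @param d projection dimension (default 3).
#' @return list with `basis` (G x d, orthonormal columns), `evar`
#'   (explained-variance fractions of the d components), `centre`
#'   (timepoint mean vector).
#' @export
fit_local_projection <- function(revs_at_t, d = 3) {
  X <- as.matrix(revs_at_t)
  if (!all(is.finite(X))) stop("non-finite values in projection input")
  ns <- ncol(X)
  if (ns <= d) {
    stop("need more than d = ", d, " samples per timepoint (have ", ns,
         "); lower d or pool more instances")
  }
  ctr <- rowMeans(X)
  Xc <- X - ctr
  sv <- svd(Xc, nu = d, nv = 0)
  tot <- sum(sv$d^2)
  evar <- if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d))
  if (any(evar[seq_len(d)] < .Machine$double.eps)) {
    warning("degenerate rank at timepoint: component(s) ",
            paste(which(evar[seq_len(d)] < .Machine$double.eps),
                  collapse = ", "),
            " carry no variance")
  }
  U <- sv$u
  for (k in seq_len(d)) {
    top <- which.max(abs(U[, k]))
    if (U[top, k] < 0) U[, k] <- -U[, k]
  }
  list(basis = U, evar = evar[seq_len(d)], centre = ctr)
}

#' Fit a multivariate normal to projected samples
#'
#' Sample mean and sample covariance (divisor `n - 1`). When the
#' covariance is ill-conditioned (condition number above `ridge_cond`) a
#' ridge `ridge_tau * trace/d` is added to the diagonal, which keeps the
#' density well defined when the number of samples is barely above the
#' dimension.
#'
#' @param projected d x N_s matrix of projected samples.
#' @param ridge_cond condition-number cap (default 1e8).
#' @param ridge_tau relative ridge size (default 1e-6).
#' @return list with `mu` (d-vector), `sigma` (d x d), `regularised`
#'   (logical).
#' @export
fit_timepoint_mvn <- function(projected, ridge_cond = 1e8,
                              ridge_tau = 1e-6) {
  X <- as.matrix(projected)
  d <- nrow(X)
  n <- ncol(X)
  if (n < 2) stop("need at least 2 samples to fit a Gaussian")
  mu <- rowMeans(X)
  S <- stats::cov(t(X))
  reg <- FALSE
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) >
      ridge_cond) {
    S <- S + diag(ridge_tau * max(sum(pmax(ev, 0)) / d,
                                  .Machine$double.eps), d)
    reg <- TRUE
  }
  list(mu = mu, sigma = S, regularised = reg)
}

# upper-triangle (incl. diagonal) index pairs for the E = d(d+1)/2
# distinct covariance entries, in column-major order
sym_entry_index <- function(d) {
  which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
}

sym_from_entries <- function(entries, idx, d) {
  S <- matrix(0, d, d)
  S[cbind(idx[, 1], idx[, 2])] <- entries
  S[cbind(idx[, 2], idx[, 1])] <- entries
  S
}

#' Fit the time-indexed clock probability model
#'
#' The central fitting function. Training samples are normalised
#' according to `norm`, then for each training timepoint `i` a local PCA
#' projection is fitted to the samples at that timepoint; the data of
#' every training timepoint `j` are projected through that basis and a
#' d-dimensional Gaussian is fitted per `j`. The Gaussian means and the
#' `d(d+1)/2` distinct covariance entries are interpolated over the full
#' day with periodic PCHIP splines, and the interpolated covariances are
#' repaired to the nearest positive-definite matrix wherever
#' interpolation leaves the positive-definite cone. The resulting family
#' of Gaussians indexed by (timepoint, clock time) is the probability
#' model against which single test samples are scored.
#'
#' @param es training [expression_set()]; every timepoint should carry
#'   the same number of samples (one per instance).
#' @param panel [gene_panel()] or character vector of panel gene ids.
#' @param d projection dimension (default 3; must be below the panel
#'   size and the per-timepoint sample count).
#' @param norm normalisation mode: `"timecourse"` (default),
#'   `"intergene"` or `"both"` (timecourse then intergene).
#' @param lthresh log-likelihood floor applied when per-timepoint curves
#'   are averaged (default -5); see [combine_loglik()].
#' @param grid_n number of grid points per day for dense evaluation
#'   (default 1440, i.e. 1-minute resolution).
#' @param eta,eps parameters of the Theta reference curve
#'   `C(t|T) = eta * (1 + eps + cos(2*pi*(t - T)/24))`; defaults 0.35 and
#'   0.15 (must satisfy `0 < eta*eps < eta*(2 + eps) < 1`).
#' @param ridge_cond,ridge_tau covariance regularisation, see
#'   [fit_timepoint_mvn()].
#' @param allow_unequal tolerate unequal per-timepoint sample counts
#'   (with a warning); used by leave-one-sample-out cross-validation.
#' @param training_summary if `TRUE` (default) every training sample is
#'   scored against the fitted model and the resulting log-ML and Theta
#'   distributions are stored for dysfunction classification.
#' @param timepoint_tol unused here (grouping happens in
#'   [expression_set()]); kept for interface clarity.
#' @return An object of class `clock_model`.
#' @seealso [predict.clock_model()], [likelihood_profile()],
#'   [leave_one_out()]
#' @export
clock_model <- function(es, panel, d = 3,
                        norm = c("timecourse", "intergene", "both"),
                        lthresh = -5, grid_n = 1440,
                        eta = 0.35, eps = 0.15,
                        ridge_cond = 1e8, ridge_tau = 1e-6,
                        allow_unequal = FALSE, training_summary = TRUE,
                        timepoint_tol = 0.25) {
  norm <- match.arg(norm)
  if (!inherits(panel, "gene_panel")) panel <- gene_panel(panel)
  check_theta_config(eta, eps)
  if (lthresh >= 0) stop("lthresh must be negative (log scale)")
  G <- length(panel$genes)
  if (d >= G) stop("projection dimension d must be below the panel size")
  revs <- extract_revs(es, panel)
  times <- es$timepoints
  nt <- length(times)
  if (nt < 3) stop("need at least 3 training timepoints for periodic splines")
  counts <- tabulate(es$timepoint_index, nbins = nt)
  if (length(unique(counts)) > 1) {
    if (!allow_unequal) {
      stop("unequal sample counts per timepoint (",
           paste(counts, collapse = ", "),
           "); set allow_unequal = TRUE to tolerate this")
    }
    warning("unequal sample counts per timepoint: ",
            paste(counts, collapse = ", "))
  }
  recipe <- if (norm != "intergene") fit_timecourse(es, panel) else NULL
  norm_train <- normalise_revs(revs, norm, es$instances, recipe)

  projections <- vector("list", nt)
  mvn_knots <- vector("list", nt)
  repairs_knots <- 0L
  for (i in seq_len(nt)) {
    Di <- norm_train[, es$timepoint_index == i, drop = FALSE]
    projections[[i]] <- fit_local_projection(Di, d)
    mu_k <- matrix(NA_real_, nt, d)
    sig_k <- array(NA_real_, c(nt, d, d))
    for (j in seq_len(nt)) {
      Pj <- crossprod(projections[[i]]$basis,
                      norm_train[, es$timepoint_index == j, drop = FALSE])
      fit <- fit_timepoint_mvn(Pj, ridge_cond, ridge_tau)
      S <- fit$sigma
      if (inherits(tryCatch(chol(S), error = identity), "error")) {
        S <- nearest_pd(S)
        repairs_knots <- repairs_knots + 1L
      }
      mu_k[j, ] <- fit$mu
      sig_k[j, , ] <- S
    }
    mvn_knots[[i]] <- list(mu = mu_k, sigma = sig_k)
  }

  core <- list(panel = panel, norm = norm, recipe = recipe, d = d,
               times = times, grid_n = grid_n, lthresh = lthresh,
               eta = eta, eps = eps, N_s = counts,
               projections = projections, mvn_knots = mvn_knots,
               repairs_knots = repairs_knots)
  model <- model_from_core(core)

  if (training_summary) {
    prof <- lapply(seq_len(ncol(norm_train)), function(k) {
      profile_from_norm(model, norm_train[, k], es$sample_ids[k])
    })
    model$training <- list(
      log_ml = vapply(prof, function(p) p$log_ML, numeric(1)),
      theta = vapply(prof, function(p) p$theta, numeric(1)))
  }
  model$call <- match.call()
  model
}

# Assemble the dense-grid representation (splined means, repaired
# covariances, their inverses and log-determinants) from the knot-level
# components. Shared by clock_model() and read_clock_model().
model_from_core <- function(core) {
  d <- core$d
  nt <- length(core$times)
  idx <- sym_entry_index(d)
  E <- nrow(idx)
  grid_times <- seq(0, 24, length.out = core$grid_n + 1)[-(core$grid_n + 1)]
  dense <- vector("list", nt)
  repairs_grid <- 0L
  for (i in seq_len(nt)) {
    mu_k <- core$mvn_knots[[i]]$mu
    sig_k <- core$mvn_knots[[i]]$sigma
    mu_g <- vapply(seq_len(d), function(c) {
      periodic_pchip(core$times, mu_k[, c])(grid_times)
    }, numeric(length(grid_times)))
    sig_g <- vapply(seq_len(E), function(e) {
      periodic_pchip(core$times,
                     sig_k[, idx[e, 1], idx[e, 2]])(grid_times)
    }, numeric(length(grid_times)))
    pd <- grid_pd_repair(sig_g, idx, d)
    repairs_grid <- repairs_grid + pd$n_repaired
    inv <- grid_inverse(pd$entries, idx, d)
    dense[[i]] <- list(mu = mu_g, sigma_entries = pd$entries,
                       inv_entries = inv$inv, logdet = inv$logdet)
  }
  out <- c(core, list(grid_times = grid_times,
                      grid_step = 24 / core$grid_n,
                      entry_index = idx,
                      dense = dense,
                      repairs_grid = repairs_grid))
  class(out) <- "clock_model"
  out
}

# Vectorised positive-definiteness check + eigenvalue-clipping repair on
# the dense grid. For d = 3 Sylvester's criterion on the leading minors
# is evaluated in vectorised form; other dimensions fall back to a
# per-point Cholesky attempt.
grid_pd_repair <- function(entries, idx, d) {
  n <- nrow(entries)
  if (d == 3) {
    s11 <- entries[, 1]; s12 <- entries[, 2]; s22 <- entries[, 3]
    s13 <- entries[, 4]; s23 <- entries[, 5]; s33 <- entries[, 6]
    det3 <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
      s13 * (s12 * s23 - s22 * s13)
    bad <- !(s11 > 0 & (s11 * s22 - s12^2) > 0 & det3 > 0)
  } else {
    bad <- vapply(seq_len(n), function(r) {
      inherits(tryCatch(chol(sym_from_entries(entries[r, ], idx, d)),
                        error = identity), "error")
    }, logical(1))
  }
  for (r in which(bad)) {
    S <- nearest_pd(sym_from_entries(entries[r, ], idx, d))
    entries[r, ] <- S[cbind(idx[, 1], idx[, 2])]
  }
  list(entries = entries, n_repaired = sum(bad))
}

# Vectorised inverse + log-determinant of the (repaired) grid
# covariances; closed-form adjugate for d = 3, per-point Cholesky
# otherwise.
grid_inverse <- function(entries, idx, d) {
  n <- nrow(entries)
  if (d == 3) {
    s11 <- entries[, 1]; s12 <- entries[, 2]; s22 <- entries[, 3]
    s13 <- entries[, 4]; s23 <- entries[, 5]; s33 <- entries[, 6]
    det3 <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
      s13 * (s12 * s23 - s22 * s13)
    inv <- cbind(
      (s22 * s33 - s23^2) / det3,        # (1,1)
      (s23 * s13 - s12 * s33) / det3,    # (1,2)
      (s11 * s33 - s13^2) / det3,        # (2,2)
      (s12 * s23 - s13 * s22) / det3,    # (1,3)
      (s12 * s13 - s11 * s23) / det3,    # (2,3)
      (s11 * s22 - s12^2) / det3)        # (3,3)
    # reorder to match the entry index (column-major upper triangle:
    # (1,1),(1,2),(2,2),(1,3),(2,3),(3,3)) -- already in that order
    logdet <- log(det3)
    # near-degenerate covariances can lose the determinant sign to
    # cancellation in the adjugate formulas; recompute those rows
    # through an eigendecomposition
    bad <- which(!is.finite(logdet) | det3 <= 0 |
                 !apply(is.finite(inv), 1, all))
    for (r in bad) {
      S <- nearest_pd(sym_from_entries(entries[r, ], idx, d))
      ev <- eigen(S, symmetric = TRUE)
      logdet[r] <- sum(log(ev$values))
      Si <- ev$vectors %*% ((1 / ev$values) * t(ev$vectors))
      inv[r, ] <- Si[cbind(idx[, 1], idx[, 2])]
    }
    list(inv = inv, logdet = logdet)
  } else {
    inv <- matrix(NA_real_, n, nrow(idx))
    logdet <- numeric(n)
    for (r in seq_len(n)) {
      S <- sym_from_entries(entries[r, ], idx, d)
      R <- chol(S)
      logdet[r] <- 2 * sum(log(diag(R)))
      Si <- chol2inv(R)
      inv[r, ] <- Si[cbind(idx[, 1], idx[, 2])]
    }
    list(inv = inv, logdet = logdet)
  }
}

#' @export
print.clock_model <- function(x, ...) {
  cat("clock_model: time-indexed Gaussian model of a circadian panel\n")
  cat("  panel:", length(x$panel$genes), "genes; projection d =", x$d, "\n")
  cat("  timepoints:", paste(format(x$times, digits = 4), collapse = ", "),
      " (", paste(x$N_s, collapse = "/"), "samples each )\n")
  cat("  normalisation:", x$norm, "  lthresh:", x$lthresh,
      "  grid:", x$grid_n, "points/day\n")
  ev <- vapply(x$projections, function(p) sum(p$evar), numeric(1))
  cat("  explained variance (d comps): ",
      paste(sprintf("%.1f%%", 100 * ev), collapse = ", "), "\n", sep = "")
  cat("  covariance repairs: ", x$repairs_knots, " at knots, ",
      x$repairs_grid, " on the grid\n", sep = "")
  invisible(x)
}

#' @export
summary.clock_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$training)) {
    out$log_ml_quantiles <- stats::quantile(
      object$training$log_ml, c(0.01, 0.05, 0.5, 0.95, 0.99))
    out$theta_quantiles <- stats::quantile(
      object$training$theta, c(0.01, 0.05, 0.5, 0.95, 0.99))
  }
  class(out) <- "summary.clock_model"
  out
}

#' @export
print.summary.clock_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$log_ml_quantiles)) {
    cat("  training log-ML quantiles:\n")
    print(round(x$log_ml_quantiles, 3))
    cat("  training Theta quantiles:\n")
    print(round(x$theta_quantiles, 4))
  }
  invisible(x)
}

#' @export
#' @describeIn clock_model knot-level Gaussian means (timepoints x d) for
#'   one local projection.
#' @param object,projection a fitted `clock_model` and the projection
#'   index whose coefficients to return.
#' @param ... unused.
coef.clock_model <- function(object, projection = 1, ...) {
  mu <- object$mvn_knots[[projection]]$mu
  dimnames(mu) <- list(paste0("t=", format(object$times, digits = 4)),
                       paste0("PC", seq_len(object$d)))
  mu
}

#' Visualise a local projection of the model
#'
#' Scatter of the projected training-time Gaussian means along the
#' splined mean cycle for one local projection, coloured by time of day.
#'
#' @param x a `clock_model`.
#' @param projection which local projection to plot (default 1).
#' @param dims which two projected dimensions to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clock_model <- function(x, projection = 1, dims = c(1, 2), ...) {
  dn <- x$dense[[projection]]
  cols <- grDevices::hsv(x$grid_times / 24, 0.8, 0.9)
  graphics::plot(dn$mu[, dims[1]], dn$mu[, dims[2]], col = cols, pch = 16,
                 cex = 0.4, xlab = paste0("PC", dims[1]),
                 ylab = paste0("PC", dims[2]),
                 main = sprintf("mean cycle, projection %d", projection),
                 ...)
  mu_k <- x$mvn_knots[[projection]]$mu
  graphics::points(mu_k[, dims[1]], mu_k[, dims[2]], pch = 4, cex = 1.2,
                   col = grDevices::hsv(x$times / 24, 0.8, 0.6))
  invisible(x)
}

#' Serialise / restore a clock model archive
#'
#' The archive is a single self-describing JSON file holding the panel,
#' the normalisation recipe, the projection bases, the knot-level
#' Gaussian parameters (from which the periodic splines and the dense
#' evaluation grid are rebuilt deterministically on load) and the
#' training score summary. Numbers are written at full precision so a
#' save/load round trip reproduces the model exactly.
#'
#' @param model a `clock_model`.
#' @param path file path for the archive.
#' @return `write_clock_model` invisibly returns `path`;
#'   `read_clock_model` returns the restored `clock_model`.
#' @export
write_clock_model <- function(model, path) {
  nt <- length(model$times)
  arch <- list(
    schema = "chronotell-clock-model/1",
    panel = list(genes = model$panel$genes,
                 provenance = model$panel$provenance),
    norm = model$norm,
    recipe = if (!is.null(model$recipe)) {
      as.list(model$recipe$table)  # column-oriented for stable parsing
    },
    d = model$d,
    times = model$times,
    grid_n = model$grid_n,
    lthresh = model$lthresh,
    eta = model$eta,
    eps = model$eps,
    N_s = model$N_s,
    repairs_knots = model$repairs_knots,
    projections = lapply(model$projections, function(p) {
      list(basis = p$basis, evar = p$evar, centre = p$centre)
    }),
    mvn_knots = lapply(model$mvn_knots, function(m) {
      # covariances as knot x upper-triangle-entry matrices: a layout
      # JSON round-trips without shape ambiguity
      ent <- t(vapply(seq_len(nt), function(j) {
        m$sigma[j, , ][cbind(model$entry_index[, 1],
                             model$entry_index[, 2])]
      }, numeric(nrow(model$entry_index))))
      list(mu = m$mu, sigma_entries = ent)
    }),
    training = model$training)
  jsonlite::write_json(arch, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_clock_model
#' @param path file path of an archive written by [write_clock_model()].
#' @export
read_clock_model <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  if (!identical(arch$schema, "chronotell-clock-model/1")) {
    stop("unrecognised model archive schema: ", arch$schema)
  }
  d <- arch$d
  nt <- length(arch$times)
  as_mat <- function(x, nrow) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nrow, byrow = TRUE)
  }
  projections <- lapply(seq_len(nt), function(i) {
    p <- arch$projections[[i]]
    list(basis = as_mat(p$basis, length(arch$panel$genes)),
         evar = p$evar, centre = p$centre)
  })
  idx <- sym_entry_index(d)
  mvn_knots <- lapply(seq_len(nt), function(i) {
    m <- arch$mvn_knots[[i]]
    ent <- as_mat(m$sigma_entries, nt)
    sig <- array(NA_real_, c(nt, d, d))
    for (j in seq_len(nt)) {
      sig[j, , ] <- sym_from_entries(ent[j, ], idx, d)
    }
    list(mu = as_mat(m$mu, nt), sigma = sig)
  })
  recipe <- NULL
  if (!is.null(arch$recipe)) {
    recipe <- structure(
      list(table = data.frame(arch$recipe, stringsAsFactors = FALSE),
           mode = "timecourse"),
      class = "norm_recipe")
  }
  core <- list(panel = gene_panel(arch$panel$genes,
                                  arch$panel$provenance %||% ""),
               norm = arch$norm, recipe = recipe, d = d,
               times = arch$times, grid_n = arch$grid_n,
               lthresh = arch$lthresh, eta = arch$eta, eps = arch$eps,
               N_s = arch$N_s,
               projections = projections, mvn_knots = mvn_knots,
               repairs_knots = arch$repairs_knots)
  model <- model_from_core(core)
  model$training <- arch$training
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
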