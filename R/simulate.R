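#' Configuration for the synthetic clock cohort generator
#'
#' Describes a cohort with the statistical structure the probability
#' model assumes: every gene follows a 24 h cosinor mean (plus an
#' optional second harmonic), every instance can carry a chronotype
#' offset shifting all its gene phases coherently, and the residual
#' noise is correlated across genes through a low-rank factor model
#' plus independent noise -- giving the rapidly decaying residual
#' covariance spectrum that justifies a 3-dimensional projection.
#'
#' Unspecified gene parameters are drawn reproducibly from the seed:
#' amplitudes uniform on `[0.6, 1.4]` log-units, acrophases evenly
#' spread over the day with up to one hour of jitter (an even spread is
#' what makes phase identifiable everywhere), mesors uniform on
#' `[6, 10]`.
#'
#' @param G number of panel genes (default 12).
#' @param N_t number of training timepoints, evenly spaced over 24 h
#'   (default 6).
#' @param N_s number of instances, each sampled at every timepoint
#'   (default 12).
#' @param amplitudes,acrophases,mesors optional per-gene parameter
#'   vectors (length G).
#' @param harmonic2 relative amplitude of the second harmonic
#'   (default 0.2).
#' @param chronotype per-instance internal-clock offsets in hours, in
#'   `(-12, 12]` (default all 0). A positive offset advances the
#'   instance's clock: its expression state is that of a later time, so
#'   its estimated times run ahead of the collection times by the
#'   offset (a positive timing displacement) and its gene acrophases
#'   come earlier.
#' @param gene_offsets optional G x N_s matrix of per-(gene, instance)
#'   clock offsets in hours (default all 0). Unlike `chronotype`, which
#'   shifts all genes of an instance coherently, independent entries
#'   here decouple the gene phases from any common instance shift --
#'   the incoherent regime in which phase-displacement regressions lose
#'   their linearity.
#' @param noise_factors number of shared residual factors (default 2).
#' @param factor_sd SD of the factor loadings (default 0.1).
#' @param noise_sd SD of the independent residual noise (default 0.15).
#' @param seed RNG seed for parameter draws and noise.
#' @return list of class `clock_sim_config`.
#' @export
clock_sim_config <- function(G = 12, N_t = 6, N_s = 12,
                             amplitudes = NULL, acrophases = NULL,
                             mesors = NULL, harmonic2 = 0.2,
                             chronotype = NULL, gene_offsets = NULL,
                             noise_factors = 2,
                             factor_sd = 0.1, noise_sd = 0.15,
                             seed = 1) {
  if (is.null(chronotype)) chronotype <- rep(0, N_s)
  if (length(chronotype) != N_s) stop("chronotype must have length N_s")
  if (any(chronotype <= -12 | chronotype > 12)) {
    stop("chronotype offsets must lie in (-12, 12]")
  }
  if (is.null(gene_offsets)) gene_offsets <- matrix(0, G, N_s)
  gene_offsets <- as.matrix(gene_offsets)
  if (!all(dim(gene_offsets) == c(G, N_s))) {
    stop("gene_offsets must be a G x N_s matrix")
  }
  drawn <- with_seed(seed, {
    list(amplitudes = stats::runif(G, 0.6, 1.4),
         acrophases = (seq(0, 24, length.out = G + 1)[seq_len(G)] +
                         stats::runif(G, -1, 1)) %% 24,
         mesors = stats::runif(G, 6, 10))
  })
  amplitudes <- amplitudes %||% drawn$amplitudes
  acrophases <- acrophases %||% drawn$acrophases
  mesors <- mesors %||% drawn$mesors
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (length(amplitudes) != G || length(acrophases) != G ||
      length(mesors) != G) {
    stop("gene parameter vectors must have length G")
  }
  if (noise_factors < 0 || factor_sd < 0 || noise_sd < 0) {
    stop("invalid residual covariance specification")
  }
  structure(list(G = G, N_t = N_t, N_s = N_s,
                 amplitudes = amplitudes, acrophases = acrophases,
                 mesors = mesors, harmonic2 = harmonic2,
                 chronotype = chronotype, gene_offsets = gene_offsets,
                 noise_factors = noise_factors,
                 factor_sd = factor_sd, noise_sd = noise_sd, seed = seed),
            class = "clock_sim_config")
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic cosinor mean matrix (G x samples). `chronotype` and
# `advance` (scalar or per-gene) shift the *internal time* of the clock
# forward: a sample from an instance advanced by delta carries the
# expression state of time t + delta, so its estimated time runs ahead
# of the collection time by delta (positive timing displacement).
sim_mean_matrix <- function(cfg, sample_times, sample_inst,
                            amplitudes = cfg$amplitudes,
                            acrophases = cfg$acrophases,
                            mesors = cfg$mesors,
                            chronotype = cfg$chronotype,
                            advance = 0) {
  w <- 2 * pi / 24
  n <- length(sample_times)
  advance <- rep_len(advance, cfg$G)
  M <- matrix(NA_real_, cfg$G, n)
  for (s in seq_len(n)) {
    ph <- sample_times[s] + chronotype[sample_inst[s]] +
      cfg$gene_offsets[, sample_inst[s]] + advance - acrophases
    M[, s] <- mesors + amplitudes *
      (cos(w * ph) + cfg$harmonic2 * cos(2 * w * ph))
  }
  M
}

#' Simulate a synthetic training cohort
#'
#' Generates the cohort described by a [clock_sim_config()]: every
#' instance is sampled at every timepoint, the mean structure is the
#' configured cosinor cycle (with chronotype offsets), and the residual
#' is `Lambda z + e` with gene loadings `Lambda` (G x factors), shared
#' factors `z ~ N(0, I)` per sample, and independent noise
#' `e ~ N(0, noise_sd^2)`. Fully reproducible from the seed. The
#' generating configuration and noise draws are attached (attribute
#' `"sim"`) so perturbed variants can be derived from the same
#' realisation.
#'
#' @param cfg a [clock_sim_config()].
#' @return an [expression_set()] with `G` genes and `N_t * N_s` samples.
#' @export
simulate_clock_data <- function(cfg) {
  stopifnot(inherits(cfg, "clock_sim_config"))
  times_grid <- seq(0, 24, length.out = cfg$N_t + 1)[seq_len(cfg$N_t)]
  sample_times <- rep(times_grid, each = cfg$N_s)
  sample_inst <- rep(seq_len(cfg$N_s), times = cfg$N_t)
  n <- length(sample_times)
  draws <- with_seed(cfg$seed + 1, {
    Lambda <- matrix(stats::rnorm(cfg$G * cfg$noise_factors,
                                  sd = cfg$factor_sd),
                     cfg$G, cfg$noise_factors)
    Z <- matrix(stats::rnorm(cfg$noise_factors * n), cfg$noise_factors, n)
    Eps <- matrix(stats::rnorm(cfg$G * n, sd = cfg$noise_sd), cfg$G, n)
    list(Lambda = Lambda, noise = Lambda %*% Z + Eps)
  })
  vals <- sim_mean_matrix(cfg, sample_times, sample_inst) + draws$noise
  gene_ids <- sprintf("gene_%02d", seq_len(cfg$G))
  inst_ids <- sprintf("inst_%02d", seq_len(cfg$N_s))
  rownames(vals) <- gene_ids
  colnames(vals) <- sprintf("s_t%02d_%s", rep(seq_len(cfg$N_t),
                                              each = cfg$N_s),
                            inst_ids[sample_inst])
  es <- expression_set(vals, times = sample_times,
                       instances = inst_ids[sample_inst])
  attr(es, "sim") <- list(cfg = cfg, noise = draws$noise,
                          Lambda = draws$Lambda,
                          sample_times = sample_times,
                          sample_inst = sample_inst)
  es
}

#' Apply a clock-perturbation archetype to a simulated cohort
#'
#' Re-derives the cohort from the same noise realisation but with a
#' perturbed mean structure, emulating the canonical dysfunction
#' archetypes: `phase_shift` advances the clock by `delta` hours (a
#' scalar shifts the whole clock coherently, emulating a chronotype or
#' feeding-induced shift; a length-G vector shifts each gene by its own
#' amount, scrambling the phases incoherently); `amplitude_collapse`
#' multiplies all amplitudes by
#' `rho < 1` (the clock flattens towards its mesor, producing lowML
#' dysfunction); `gene_knockout` replaces one gene by arrhythmic noise
#' around a fixed level; `frozen_clock` pins every sample's mean to the
#' clock state at hour `t_f` regardless of its nominal sampling time (a
#' stopped clock that reliably reports the same wrong time).
#'
#' @param es a simulated [expression_set()] from
#'   [simulate_clock_data()].
#' @param kind one of `"phase_shift"`, `"amplitude_collapse"`,
#'   `"gene_knockout"`, `"frozen_clock"`.
#' @param params list of parameters: `delta` (hours, scalar or length
#'   G) for `phase_shift`; `rho` for `amplitude_collapse`; `gene` (id
#'   or index) and optional `level` for `gene_knockout`; `t_f` (hours)
#'   for `frozen_clock`.
#' @return a perturbed [expression_set()] over the same samples.
#' @export
perturb_clock_data <- function(es, kind, params = list()) {
  sim <- attr(es, "sim")
  if (is.null(sim)) {
    stop("perturbations need a simulated cohort from simulate_clock_data()")
  }
  cfg <- sim$cfg
  vals <- switch(
    kind,
    phase_shift = {
      delta <- params$delta
      if (is.null(delta)) stop("phase_shift needs params$delta")
      sim_mean_matrix(cfg, sim$sample_times, sim$sample_inst,
                      advance = delta) + sim$noise
    },
    amplitude_collapse = {
      rho <- params$rho
      if (is.null(rho)) stop("amplitude_collapse needs params$rho")
      sim_mean_matrix(cfg, sim$sample_times, sim$sample_inst,
                      amplitudes = cfg$amplitudes * rho) + sim$noise
    },
    gene_knockout = {
      g <- params$gene
      if (is.null(g)) stop("gene_knockout needs params$gene")
      if (is.character(g)) g <- match(g, rownames(es$values))
      if (is.na(g)) stop("unknown gene in gene_knockout")
      v <- sim_mean_matrix(cfg, sim$sample_times, sim$sample_inst) +
        sim$noise
      level <- params$level %||% cfg$mesors[g]
      v[g, ] <- level + sim$noise[g, ]
      v
    },
    frozen_clock = {
      t_f <- params$t_f
      if (is.null(t_f)) stop("frozen_clock needs params$t_f")
      sim_mean_matrix(cfg, rep(t_f, length(sim$sample_times)),
                      sim$sample_inst) + sim$noise
    },
    stop("unknown perturbation kind: ", kind))
  dimnames(vals) <- dimnames(es$values)
  out <- expression_set(vals, times = es$times, instances = es$instances)
  attr(out, "sim") <- sim
  attr(out, "perturbation") <- list(kind = kind, params = params)
  out
}

#' Write the pinned worked-example bundle
#'
#' Generates the small fixed-seed cohort used by the documentation
#' walkthrough (12 genes, 6 timepoints, 12 instances at moderate noise,
#' with the last instance carrying a +2 h chronotype offset) and writes
#' it as TSV files plus a JSON manifest recording the seed,
#' configuration and file checksums.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed seed pinned for the bundle (default 1103).
#' @return invisibly, a list with the file paths and the manifest.
#' @export
worked_example_bundle <- function(out_dir, seed = 1103) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- worked_example_config(seed)
  es <- simulate_clock_data(cfg)
  mat_path <- file.path(out_dir, "train_matrix.tsv")
  meta_path <- file.path(out_dir, "train_metadata.tsv")
  write_expression_set(es, mat_path, meta_path)
  manifest <- list(
    seed = seed,
    config = cfg[c("G", "N_t", "N_s", "harmonic2", "chronotype",
                   "noise_factors", "factor_sd", "noise_sd")],
    files = list(train_matrix = unname(tools::md5sum(mat_path)),
                 train_metadata = unname(tools::md5sum(meta_path))))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(matrix = mat_path, metadata = meta_path,
                 manifest_path = man_path, manifest = manifest,
                 expression_set = es))
}

# the pinned worked-example configuration: defaults at moderate noise,
# one instance with a +2 h chronotype
worked_example_config <- function(seed = 1103) {
  clock_sim_config(G = 12, N_t = 6, N_s = 12,
                   chronotype = c(rep(0, 11), 2), seed = seed)
}
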