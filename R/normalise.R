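#' Fit a timecourse normalisation recipe
#'
#' For every (instance, gene) pair in the training set, records the mean
#' (offset) and sample standard deviation (scale, divisor `n - 1`) of that
#' gene's training time series in that instance. Applying the recipe to
#' the training data gives every such series mean 0 and SD 1; the stored
#' offsets and scales are what test data from the same instances must be
#' normalised with (timecourse-matched normalisation).
#'
#' @param es training [expression_set()].
#' @param panel [gene_panel()] or character vector of gene ids.
#' @return An object of class `norm_recipe`: list with `table`
#'   (data.frame instance/gene/offset/scale) and `mode = "timecourse"`.
#' @export
fit_timecourse <- function(es, panel) {
  revs <- extract_revs(es, panel)
  genes <- rownames(revs)
  inst <- unique(es$instances)
  grid <- expand.grid(instance = inst, gene = genes,
                      stringsAsFactors = FALSE)
  off <- numeric(nrow(grid))
  sc <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    y <- revs[grid$gene[k], es$instances == grid$instance[k]]
    if (length(unique(y)) < 2) {
      stop("constant training series for instance '", grid$instance[k],
           "', gene '", grid$gene[k], "': timecourse scale undefined")
    }
    off[k] <- mean(y)
    sc[k] <- stats::sd(y)
  }
  structure(list(table = cbind(grid, offset = off, scale = sc),
                 mode = "timecourse"),
            class = "norm_recipe")
}

#' @export
print.norm_recipe <- function(x, ...) {
  cat("norm_recipe (timecourse):",
      length(unique(x$table$instance)), "instance(s) x",
      length(unique(x$table$gene)), "gene(s)\n")
  invisible(x)
}

#' Apply timecourse-matched normalisation to test data
#'
#' Each value for (instance, gene) is replaced by
#' `(x - offset) / scale` using the offsets and scalings stored when the
#' training data were timecourse-normalised. Test data can therefore only
#' come from instances present in the training set.
#'
#' @param rev_matrix genes x samples matrix with gene ids as rownames.
#' @param instance_labels instance label per column.
#' @param recipe a `norm_recipe` from [fit_timecourse()].
#' @return normalised matrix of the same shape.
#' @export
apply_timecourse_matched <- function(rev_matrix, instance_labels, recipe) {
  stopifnot(inherits(recipe, "norm_recipe"))
  rev_matrix <- as.matrix(rev_matrix)
  genes <- rownames(rev_matrix)
  if (is.null(genes)) stop("rev_matrix must have gene ids as rownames")
  instance_labels <- as.character(instance_labels)
  if (length(instance_labels) != ncol(rev_matrix)) {
    stop("need one instance label per sample column")
  }
  unknown <- setdiff(unique(instance_labels), unique(recipe$table$instance))
  if (length(unknown)) {
    stop("instance(s) not in the training recipe: ",
         paste(unknown, collapse = ", "),
         "; use intergene normalisation for tissues without a training",
         " time series")
  }
  miss_g <- setdiff(genes, unique(recipe$table$gene))
  if (length(miss_g)) {
    stop("gene(s) not in the training recipe: ",
         paste(miss_g, collapse = ", "))
  }
  key <- paste(recipe$table$instance, recipe$table$gene, sep = "\r")
  out <- rev_matrix
  for (j in seq_len(ncol(out))) {
    idx <- match(paste(instance_labels[j], genes, sep = "\r"), key)
    out[, j] <- (rev_matrix[, j] - recipe$table$offset[idx]) /
      recipe$table$scale[idx]
  }
  out
}

#' Intergene normalisation of expression vectors
#'
#' Maps each sample's panel expression vector onto its shape: entry-wise
#' `(g_i - mu) / sigma` where `mu` and `sigma` are the mean and sample SD
#' of the G entries of that vector. The output is invariant to affine
#' rescaling `a * g + b` (`a > 0`) of the input and is idempotent.
#'
#' @param rev numeric vector (one sample) or genes x samples matrix.
#' @return normalised vector/matrix with per-sample mean 0, SD 1.
#' @export
intergene_normalise <- function(rev) {
  norm1 <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("constant expression vector: intergene shape undefined")
    }
    (v - mean(v)) / s
  }
  if (is.matrix(rev)) {
    out <- apply(rev, 2, norm1)
    dimnames(out) <- dimnames(rev)
    out
  } else {
    norm1(rev)
  }
}

#' Normalise panel expression data by mode
#'
#' Dispatches between the three normalisation modes: `"intergene"` (per
#' sample, no recipe needed), `"timecourse"` (timecourse-matched via the
#' training recipe) and `"both"` (timecourse first, then intergene on the
#' timecourse-normalised vectors).
#'
#' @param rev_matrix genes x samples matrix.
#' @param mode one of `"intergene"`, `"timecourse"`, `"both"`.
#' @param instance_labels required for `timecourse`/`both`.
#' @param recipe required for `timecourse`/`both`.
#' @return normalised matrix.
#' @export
normalise_revs <- function(rev_matrix,
                           mode = c("timecourse", "intergene", "both"),
                           instance_labels = NULL, recipe = NULL) {
  mode <- match.arg(mode)
  rev_matrix <- as.matrix(rev_matrix)
  if (mode == "intergene") {
    return(intergene_normalise(rev_matrix))
  }
  if (is.null(recipe)) {
    stop("mode '", mode, "' needs a timecourse recipe; fit one with",
         " fit_timecourse()")
  }
  if (is.null(instance_labels)) {
    stop("mode '", mode, "' needs per-sample instance labels")
  }
  tc <- apply_timecourse_matched(rev_matrix, instance_labels, recipe)
  if (mode == "timecourse") tc else intergene_normalise(tc)
}
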