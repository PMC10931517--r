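#' Expression set: a genes x samples matrix with circadian metadata
#'
#' Container for both training and test transcriptomic data. Rows are genes
#' (uniquely identified), columns are samples; each sample carries a
#' collection time in hours (reduced modulo 24 into `[0, 24)`) and an
#' instance label (the tissue or individual it came from). Samples are
#' grouped into training timepoints by matching their collection times
#' within `timepoint_tol` hours, so samples at time `t` and `t + 24` are
#' treated as replicates of `t`.
#'
#' @param values numeric matrix, genes x samples; rownames are gene ids
#'   (whitespace is stripped), colnames are sample ids.
#' @param times numeric vector of collection times in hours, one per sample.
#' @param instances character vector of instance labels, one per sample.
#' @param timepoint_tol tolerance in hours when grouping sample times into
#'   shared timepoints (default 0.25).
#' @return An object of class `expression_set`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `times`, `instances`,
#'   `timepoint_index` (integer index into `timepoints`) and `timepoints`
#'   (the distinct training times, ascending).
#' @export
expression_set <- function(values, times, instances, timepoint_tol = 0.25) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    stop("expression matrix must have gene ids as rownames")
  }
  gene_ids <- trimws(rownames(values))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  rownames(values) <- gene_ids
  n <- ncol(values)
  if (length(times) != n || length(instances) != n) {
    stop("times and instances must have one entry per sample column")
  }
  if (!is.numeric(times) || anyNA(times)) {
    stop("sample times must be numeric and non-missing")
  }
  times <- as.numeric(times) %% 24
  instances <- as.character(instances)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(n))
  }
  grp <- group_times(times, timepoint_tol)
  structure(
    list(values = values,
         gene_ids = gene_ids,
         sample_ids = colnames(values),
         times = times,
         instances = instances,
         timepoint_index = grp$index,
         timepoints = grp$timepoints),
    class = "expression_set")
}

# Cluster times (circularly, period 24) into timepoints within `tol` hours.
group_times <- function(times, tol = 0.25) {
  ord <- order(times)
  sorted <- times[ord]
  idx <- integer(length(times))
  centres <- numeric(0)
  cur <- NA_real_
  for (k in seq_along(sorted)) {
    t <- sorted[k]
    if (is.na(cur) || abs(t - cur) > tol) {
      centres <- c(centres, t)
      cur <- t
    }
    idx[ord[k]] <- length(centres)
  }
  # merge first and last group if they wrap around midnight
  if (length(centres) > 1) {
    wrap <- (centres[1] + 24) - centres[length(centres)]
    if (wrap <= tol) {
      idx[idx == length(centres)] <- 1L
      centres <- centres[-length(centres)]
    }
  }
  # recompute centres as circular means of member times
  for (g in seq_along(centres)) {
    centres[g] <- circular_mean_hours(times[idx == g])
  }
  list(index = idx, timepoints = centres)
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  timepoints:", paste(format(x$timepoints, digits = 4),
                             collapse = ", "), "\n")
  cat("  instances: ", length(unique(x$instances)), " (",
      paste(utils::head(unique(x$instances), 6), collapse = ", "),
      if (length(unique(x$instances)) > 6) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Read an expression set from delimited text files
#'
#' The matrix file must have a header row of sample ids and a first column
#' of gene ids; the metadata file must have columns `sample_id`, `time` and
#' `instance`. Files ending in `.csv` are read comma-separated, anything
#' else tab-separated. Metadata rows are aligned to the matrix columns by
#' sample id and times are reduced modulo 24.
#'
#' @param matrix_path path to the expression matrix file.
#' @param metadata_path path to the per-sample metadata file.
#' @param timepoint_tol passed to [expression_set()].
#' @return An [expression_set()].
#' @export
read_expression_set <- function(matrix_path, metadata_path,
                                timepoint_tol = 0.25) {
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  mat <- utils::read.table(matrix_path, header = TRUE, sep = sep(matrix_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- trimws(as.character(mat[[1]]))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  vals <- mat[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[non_num], collapse = ", "))
  }
  vals <- as.matrix(vals)
  rownames(vals) <- gene_ids
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = sep(metadata_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "instance")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(vals), as.character(meta$sample_id))
  if (length(missing)) {
    stop("sample(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), as.character(meta$sample_id)), ]
  expression_set(vals, times = meta$time, instances = meta$instance,
                 timepoint_tol = timepoint_tol)
}

#' Write an expression set to delimited text files
#'
#' Inverse of [read_expression_set()]: finite values round-trip exactly
#' (full double precision is written).
#'
#' @param es an [expression_set()].
#' @param matrix_path,metadata_path output paths; `.csv` selects commas.
#' @return Invisibly, `es`.
#' @export
write_expression_set <- function(es, matrix_path, metadata_path) {
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = es$gene_ids,
                   format_full(es$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = sep(matrix_path),
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = es$sample_ids,
                     time = format_full(es$times),
                     instance = es$instances,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = sep(metadata_path),
                     quote = FALSE, row.names = FALSE)
  invisible(es)
}

# format doubles so that read.table recovers them bit-identically
format_full <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) formatC(col, digits = 17, format = "g"))
    dimnames(out) <- dimnames(x)
    out
  } else {
    formatC(x, digits = 17, format = "g")
  }
}

#' Define a rhythmic gene panel
#'
#' The ordered panel of clock-representative genes whose expression vector
#' (one value per panel gene) is the unit the probability model works on.
#' At least 4 genes are required so the default projection dimension 3 is
#' strictly smaller than the panel size.
#'
#' @param genes ordered character vector of gene ids.
#' @param provenance free-text note on how the panel was chosen.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(genes, provenance = "") {
  genes <- trimws(as.character(genes))
  if (length(genes) < 4) {
    stop("a gene panel needs at least 4 genes")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene(s) in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(genes = genes, provenance = provenance),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene_panel with", length(x$genes), "genes:",
      paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) "..." else "", "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Extract the panel-ordered expression matrix
#'
#' Returns the G x N matrix of expression values restricted to the panel
#' genes, rows in panel order, columns untouched. This is a pure row
#' permutation/selection of the input.
#'
#' @param es an [expression_set()].
#' @param panel a [gene_panel()] or character vector of gene ids.
#' @return numeric matrix (panel genes x samples).
#' @export
extract_revs <- function(es, panel) {
  genes <- if (inherits(panel, "gene_panel")) panel$genes else trimws(panel)
  missing <- setdiff(genes, es$gene_ids)
  if (length(missing)) {
    stop("panel gene(s) not present in expression set: ",
         paste(missing, collapse = ", "))
  }
  m <- es$values[genes, , drop = FALSE]
  if (anyNA(m)) {
    stop("missing values in panel genes")
  }
  m
}

#' Rank candidate genes by rhythmicity and cross-instance synchronicity
#'
#' For every candidate gene a cosinor model (24 h cosine) is fitted to the
#' pooled data and to each instance separately. Genes are ranked by the
#' pooled rhythmicity p-value (ascending) and then by the dispersion of
#' the per-instance acrophases (root-mean-square circular deviation from
#' their circular mean, in hours, ascending) so that strongly rhythmic,
#' well-synchronised genes come first. A gene with fewer than 4 distinct
#' sample times in some instance is flagged unrankable rather than
#' dropped.
#'
#' @param es an [expression_set()].
#' @param candidate_genes character vector of gene ids to rank (default:
#'   all genes in `es`).
#' @return data.frame of class `rhythmicity_ranking` with columns `gene`,
#'   `mesor`, `amplitude`, `acrophase`, `p_rhythm`, `phase_dispersion`,
#'   `unrankable`; rows sorted by the ranking.
#' @export
rank_rhythmicity <- function(es, candidate_genes = es$gene_ids) {
  candidate_genes <- trimws(candidate_genes)
  missing <- setdiff(candidate_genes, es$gene_ids)
  if (length(missing)) {
    stop("candidate gene(s) not in expression set: ",
         paste(missing, collapse = ", "))
  }
  inst <- unique(es$instances)
  rows <- lapply(candidate_genes, function(g) {
    y <- es$values[g, ]
    ok <- all(vapply(inst, function(j) {
      length(unique(es$times[es$instances == j])) >= 4
    }, logical(1)))
    if (!ok) {
      return(data.frame(gene = g, mesor = NA_real_, amplitude = NA_real_,
                        acrophase = NA_real_, p_rhythm = NA_real_,
                        phase_dispersion = NA_real_, unrankable = TRUE,
                        stringsAsFactors = FALSE))
    }
    pooled <- cosinor_fit(es$times, y)
    phases <- vapply(inst, function(j) {
      sel <- es$instances == j
      cosinor_fit(es$times[sel], y[sel])$acrophase
    }, numeric(1))
    data.frame(gene = g, mesor = pooled$mesor, amplitude = pooled$amplitude,
               acrophase = pooled$acrophase, p_rhythm = pooled$p_rhythm,
               phase_dispersion = circular_dispersion_hours(phases),
               unrankable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$unrankable, out$p_rhythm, out$phase_dispersion), ]
  rownames(out) <- NULL
  class(out) <- c("rhythmicity_ranking", "data.frame")
  out
}
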