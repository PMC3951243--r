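# Expression containers and the lagged regression design.
#
# Time indexing convention: 1-based within each experiment; row t of the
# design corresponds to the target's expression at time t, with regressor
# columns holding expressions at times t-1 .. t-D of the same experiment.

#' Multi-experiment expression time-series container
#'
#' Bundles one expression matrix per experiment (genes in rows, ordered
#' time-points in columns). Experiments may have different numbers of
#' time-points; the gene set and gene order must be identical across
#' experiments. Time-points are treated as uniformly spaced steps;
#' `sampling_period` is informational only.
#'
#' @param experiments list of numeric matrices, each `N x M_j` with `M_j >= 2`
#'   columns. Row names, when present, must agree with `gene_ids`.
#' @param gene_ids character vector of `N >= 2` gene names; defaults to the
#'   row names of the first experiment.
#' @param sampling_period positive scalar, the real time between consecutive
#'   columns.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(experiments, gene_ids = NULL,
                               sampling_period = 1) {
  if (!is.list(experiments) || length(experiments) < 1L)
    stop_caspian("caspian_invalid_dataset",
                 "experiments must be a non-empty list of matrices")
  experiments <- lapply(experiments, as.matrix)
  if (is.null(gene_ids)) gene_ids <- rownames(experiments[[1]])
  if (is.null(gene_ids))
    stop_caspian("caspian_invalid_dataset",
                 "gene_ids missing and first experiment has no row names")
  gene_ids <- as.character(gene_ids)
  N <- length(gene_ids)
  if (N < 2L)
    stop_caspian("caspian_invalid_dataset", "at least 2 genes are required")
  if (anyDuplicated(gene_ids))
    stop_caspian("caspian_duplicate_gene", sprintf(
      "duplicated gene id(s): %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  for (j in seq_along(experiments)) {
    X <- experiments[[j]]
    if (nrow(X) != N)
      stop_caspian("caspian_invalid_dataset", sprintf(
        "experiment %d has %d rows; expected %d genes", j, nrow(X), N))
    if (ncol(X) < 2L)
      stop_caspian("caspian_invalid_dataset", sprintf(
        "experiment %d has fewer than 2 time-points", j))
    if (!all(is.finite(X)))
      stop_caspian("caspian_nonfinite_values", sprintf(
        "experiment %d contains missing or non-finite values", j))
    if (!is.null(rownames(X)) && !identical(rownames(X), gene_ids))
      stop_caspian("caspian_invalid_dataset", sprintf(
        "experiment %d row names disagree with gene_ids", j))
    rownames(experiments[[j]]) <- gene_ids
  }
  if (!is.numeric(sampling_period) || length(sampling_period) != 1L ||
      sampling_period <= 0)
    stop_caspian("caspian_invalid_dataset",
                 "sampling_period must be a positive scalar")
  structure(
    list(gene_ids = gene_ids, experiments = experiments,
         sampling_period = sampling_period),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", length(x$gene_ids), " genes, ",
      length(x$experiments), " experiment(s) with ",
      paste(vapply(x$experiments, ncol, 0L), collapse = "/"),
      " time-points\n", sep = "")
  invisible(x)
}

#' Restrict a dataset to a subset of genes
#'
#' @param data an `expression_dataset`.
#' @param genes character vector of gene ids to keep (at least 2).
#' @return An `expression_dataset` over `genes`, in the given order.
#' @export
subset_genes <- function(data, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, data$gene_ids)
  if (length(missing))
    stop_caspian("caspian_unknown_gene", sprintf(
      "unknown gene(s): %s", paste(missing, collapse = ", ")))
  expression_dataset(
    lapply(data$experiments, function(X) X[genes, , drop = FALSE]),
    gene_ids = genes, sampling_period = data$sampling_period
  )
}

#' Center and unit-normalize an expression profile
#'
#' Subtracts the mean and rescales to unit Euclidean norm. This is the
#' normalization applied to every stacked profile (each lagged regressor
#' column and the target vector) before sparse recovery, removing per-gene
#' offset and scale so that correlation-based column selection is meaningful.
#'
#' @param v numeric vector with at least 2 entries and nonzero variance.
#' @return A vector with mean 0 and Euclidean norm 1.
#' @examples
#' normalize_profile(c(1, 2, 3)) # -1/sqrt(2), 0, 1/sqrt(2)
#' @export
normalize_profile <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L || !all(is.finite(v)))
    stop_caspian("caspian_invalid_profile",
                 "profile must be finite with at least 2 entries")
  centered <- v - mean(v)
  nrm <- sqrt(sum(centered^2))
  if (nrm == 0)
    stop_caspian("caspian_constant_profile",
                 "profile has zero variance and cannot be normalized")
  centered / nrm
}

#' Build the lagged regression design for one target gene
#'
#' Constructs the measurement vector `y` and sensing matrix `Phi` for the
#' target gene. Experiments with fewer than `D + 1` time-points are dropped.
#' Per retained experiment `j`, `y` stacks the target's expressions at times
#' `D+1 .. M_j`, and for every other gene `g` and lag `d` in `1..D` one column
#' stacks `g`'s expressions at times `D+1-d .. M_j-d`. After stacking, every
#' column and `y` itself are centered and unit-normalized
#' ([normalize_profile()]); an unnormalized all-ones intercept column is then
#' appended to capture steady-state offsets. Constant columns cannot be
#' normalized and are dropped with a warning.
#'
#' The target gene's own lagged profiles are deliberately excluded: a gene's
#' autocorrelation would otherwise mask its true regulators, and selecting it
#' would not evidence self-regulation.
#'
#' @param data an [expression_dataset()].
#' @param target gene id of the regression target.
#' @param lags maximum time-lag `D >= 1`, in sampling steps.
#' @return A `lagged_design`: `target`, `y` (length `M = sum(M_j - D)`),
#'   `Phi` (`M x ((N-1)*D + 1)` when no column is dropped), `labels`
#'   (data frame mapping columns to `(gene, lag)`, intercept flagged),
#'   `row_provenance` (experiment and time index per row), and `dropped`
#'   (labels of constant columns removed).
#' @export
build_lagged_design <- function(data, target, lags = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  target <- as.character(target)
  if (!target %in% data$gene_ids)
    stop_caspian("caspian_unknown_gene", sprintf("unknown gene: %s", target))
  D <- as.integer(lags)
  if (length(D) != 1L || is.na(D) || D < 1L)
    stop_caspian("caspian_invalid_lags", "lags must be a positive integer")

  M_j <- vapply(data$experiments, ncol, 0L)
  keep_exp <- which(M_j >= D + 1L)
  if (!length(keep_exp))
    stop_caspian("caspian_no_usable_experiment", sprintf(
      "no experiment has at least %d time-points (D = %d)", D + 1L, D))

  others <- setdiff(data$gene_ids, target)
  y_raw <- numeric(0)
  prov_exp <- integer(0)
  prov_time <- integer(0)
  # columns ordered gene-major then lag: (g1,1)..(g1,D),(g2,1)..
  cols <- matrix(0, nrow = sum(M_j[keep_exp] - D),
                 ncol = length(others) * D)
  lab_gene <- rep(others, each = D)
  lab_lag <- rep(seq_len(D), times = length(others))

  row0 <- 0L
  for (j in keep_exp) {
    X <- data$experiments[[j]]
    tt <- (D + 1L):M_j[j]
    rows <- row0 + seq_along(tt)
    y_raw <- c(y_raw, X[target, tt])
    prov_exp <- c(prov_exp, rep.int(j, length(tt)))
    prov_time <- c(prov_time, tt)
    for (ci in seq_along(lab_gene)) {
      cols[rows, ci] <- X[lab_gene[ci], tt - lab_lag[ci]]
    }
    row0 <- row0 + length(tt)
  }

  y <- tryCatch(normalize_profile(y_raw), caspian_constant_profile = function(e)
    stop_caspian("caspian_constant_profile", sprintf(
      "target gene %s has a constant stacked profile", target)))

  keep_col <- rep(TRUE, ncol(cols))
  for (ci in seq_len(ncol(cols))) {
    centered <- cols[, ci] - mean(cols[, ci])
    nrm <- sqrt(sum(centered^2))
    if (nrm == 0) keep_col[ci] <- FALSE else cols[, ci] <- centered / nrm
  }
  dropped <- character(0)
  if (!all(keep_col)) {
    dropped <- sprintf("%s(lag %d)", lab_gene[!keep_col], lab_lag[!keep_col])
    warn_caspian("caspian_constant_profile", sprintf(
      "dropping constant lagged profile column(s): %s",
      paste(dropped, collapse = ", ")))
    cols <- cols[, keep_col, drop = FALSE]
    lab_gene <- lab_gene[keep_col]
    lab_lag <- lab_lag[keep_col]
  }

  Phi <- cbind(cols, 1)
  labels <- data.frame(
    gene = c(lab_gene, NA_character_),
    lag = c(lab_lag, NA_integer_),
    intercept = c(rep(FALSE, length(lab_gene)), TRUE),
    stringsAsFactors = FALSE
  )
  structure(
    list(target = target, y = y, Phi = Phi, labels = labels,
         row_provenance = data.frame(experiment = prov_exp, time = prov_time),
         dropped = dropped),
    class = "lagged_design"
  )
}

#' @export
print.lagged_design <- function(x, ...) {
  cat("<lagged_design> target ", x$target, ": ", length(x$y), " rows x ",
      ncol(x$Phi), " columns (incl. intercept)\n", sep = "")
  invisible(x)
}

#' Map selected design columns back to regulator genes
#'
#' @param design a `lagged_design`.
#' @param support a `support_set` or an integer vector of column indices.
#' @return Character vector of the distinct genes whose lagged columns appear
#'   in the support; the intercept column is silently excluded.
#' @export
map_columns_to_genes <- function(design, support) {
  idx <- if (inherits(support, "support_set")) support$indices
         else as.integer(support)
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(design$labels)))
    stop_caspian("caspian_index_out_of_range", sprintf(
      "column index outside [1, %d]", nrow(design$labels)))
  genes <- design$labels$gene[idx]
  unique(genes[!design$labels$intercept[idx]])
}
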