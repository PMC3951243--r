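# Edge-level scoring against ground truth, and multiplicity ratios over
# randomized gene-panel runs.

#' Confusion counts between an inferred and a true network
#'
#' Counts over the universe of ordered gene pairs (u, v), u != v (self-loops
#' are excluded: the method cannot infer them by construction). Edge signs
#' are ignored; sign agreement is reported separately as
#' `sign_match_rate` over the true positives whose truth sign is nonzero.
#'
#' @param inferred,truth `directed_network`s over the same node set.
#' @return A `confusion_counts` list: `TP`, `FP`, `TN`, `FN` (summing to
#'   `N*(N-1)`) and `sign_match_rate` (NA when there are no signed TPs).
#' @export
confusion <- function(inferred, truth) {
  stopifnot(inherits(inferred, "directed_network"),
            inherits(truth, "directed_network"))
  if (!setequal(inferred$nodes, truth$nodes))
    stop_caspian("caspian_node_mismatch",
                 "inferred and truth networks have different node sets")
  N <- length(truth$nodes)
  inf_keys <- edge_keys(inferred)
  tru_keys <- edge_keys(truth)
  TP <- sum(inf_keys %in% tru_keys)
  FP <- length(inf_keys) - TP
  FN <- length(tru_keys) - TP
  TN <- N * (N - 1L) - TP - FP - FN

  sign_match_rate <- NA_real_
  tp_keys <- intersect(inf_keys, tru_keys)
  if (length(tp_keys)) {
    si <- inferred$edges$sign[match(tp_keys, inf_keys)]
    st <- truth$edges$sign[match(tp_keys, tru_keys)]
    comparable <- st != 0
    if (any(comparable))
      sign_match_rate <- mean(si[comparable] == st[comparable])
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sign_match_rate = sign_match_rate),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$TP, " FP =", x$FP, " TN =", x$TN, " FN =", x$FN, "\n")
  invisible(x)
}

#' Sensitivity, precision, accuracy and F-measure from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`,
#' `F = 2*precision*sensitivity/(precision+sensitivity)`. Zero-denominator
#' cases yield `NA` (an explicit undefined marker), never NaN.
#'
#' @param counts a [confusion()] result, or a list with TP/FP/TN/FN.
#' @return A `metrics_report` list with the four measures.
#' @export
network_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0))
    stop_caspian("caspian_invalid_counts", "confusion counts must be >= 0")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(TP, TP + FN)
  prec <- rat(TP, TP + FP)
  acc <- rat(TP + TN, TP + TN + FP + FN)
  f <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  structure(list(sensitivity = sens, precision = prec, accuracy = acc,
                 f_measure = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.4f  precision %.4f  accuracy %.4f  F %.4f\n",
    x$sensitivity, x$precision, x$accuracy, x$f_measure))
  invisible(x)
}

#' Multiplicity ratio of edges across repeated runs
#'
#' For each directed edge appearing in at least one run, the fraction of runs
#' that produced it. The denominator is always the total number of runs, even
#' under the random-panel protocol where some runs do not contain an edge's
#' endpoints; an edge recovered by every run therefore has MR = 1 and serves
#' as a high-confidence call.
#'
#' @param runs non-empty list of `directed_network`s.
#' @return Data frame `regulator`, `target`, `mr`, sorted by decreasing `mr`.
#' @export
multiplicity_ratio <- function(runs) {
  if (!length(runs))
    stop_caspian("caspian_invalid_runs", "need at least one run")
  keys <- unlist(lapply(runs, edge_keys))
  if (!length(keys))
    return(data.frame(regulator = character(0), target = character(0),
                      mr = numeric(0), stringsAsFactors = FALSE))
  tab <- table(keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    regulator = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    mr = as.numeric(tab) / length(runs),
    stringsAsFactors = FALSE
  )
  out[order(-out$mr, out$regulator, out$target), , drop = FALSE]
}

#' Repeated inference on randomized gene panels
#'
#' The subsampled-panel protocol behind multiplicity ratios: each run infers
#' a network on the core genes plus a fresh uniform draw of non-core genes
#' (panel size fixed), and only edges among core genes are retained. Feeding
#' the run list to [multiplicity_ratio()] gives per-edge confidence scores.
#'
#' @param data an [expression_dataset()].
#' @param core_genes gene ids always included; reported edges are among them.
#' @param panel_size total genes per run, `>= length(core_genes)`.
#' @param n_runs number of randomized runs.
#' @inheritParams caspian_target
#' @param seed master RNG seed; the whole run list is deterministic given it.
#' @return List of `directed_network`s restricted to core-gene edges.
#' @export
random_panel_runs <- function(data, core_genes, panel_size, n_runs,
                              k = 5L, lags = 1L, alpha = 0.05, seed) {
  stopifnot(inherits(data, "expression_dataset"))
  core_genes <- as.character(core_genes)
  missing <- setdiff(core_genes, data$gene_ids)
  if (length(missing))
    stop_caspian("caspian_unknown_gene", sprintf(
      "unknown core gene(s): %s", paste(missing, collapse = ", ")))
  noncore <- setdiff(data$gene_ids, core_genes)
  n_extra <- panel_size - length(core_genes)
  if (n_extra < 0 || n_extra > length(noncore))
    stop_caspian("caspian_invalid_simconfig",
                 "panel_size incompatible with core/non-core gene counts")
  set.seed(as.integer(seed))
  lapply(seq_len(n_runs), function(run) {
    panel <- c(core_genes, if (n_extra) sample(noncore, n_extra))
    net <- caspian_network(subset_genes(data, panel),
                           k = k, lags = lags, alpha = alpha)
    keep <- net$edges$regulator %in% core_genes &
      net$edges$target %in% core_genes
    directed_network(core_genes, net$edges[keep, , drop = FALSE])
  })
}
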