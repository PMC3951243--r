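# Plain-text readers and writers: grouped-TSV expression tables, TSV/SIF
# edge lists, and the annotated inference-result table.
#
# Expression format: one header line "gene<TAB>E1:T1<TAB>E1:T2...<TAB>E2:T1..."
# with columns grouped by experiment and time-ordered within each group, then
# one row per gene. Experiments may have different lengths.

#' Read a grouped-TSV expression table
#'
#' @param path file path.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    stop_caspian("caspian_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_caspian("caspian_malformed_header", "expression file too short")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "gene" || length(header) < 2L)
    stop_caspian("caspian_malformed_header",
                 "header must start with 'gene' followed by E<j>:T<t> columns")
  m <- regmatches(header[-1],
                  regexec("^E([0-9]+):T([0-9]+)$", header[-1]))
  if (any(vapply(m, length, 0L) != 3L))
    stop_caspian("caspian_malformed_header",
                 "expression columns must be named E<j>:T<t>")
  exp_id <- as.integer(vapply(m, `[`, "", 2L))
  t_id <- as.integer(vapply(m, `[`, "", 3L))
  n_exp <- max(exp_id)
  for (j in seq_len(n_exp)) {
    tj <- t_id[exp_id == j]
    if (!length(tj) || !identical(tj, seq_along(tj)))
      stop_caspian("caspian_malformed_header", sprintf(
        "experiment %d columns must be contiguous and numbered T1..T%d",
        j, length(tj)))
  }
  if (is.unsorted(exp_id))
    stop_caspian("caspian_malformed_header",
                 "columns must be grouped by experiment in order")

  body <- fields[-1]
  ncols <- length(header)
  bad <- which(vapply(body, length, 0L) != ncols)
  if (length(bad))
    stop_caspian("caspian_ragged_row", sprintf(
      "row %d has %d fields; expected %d",
      bad[1] + 1L, length(body[[bad[1]]]), ncols))
  gene_ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop_caspian("caspian_duplicate_gene", sprintf(
      "duplicated gene id: %s", gene_ids[duplicated(gene_ids)][1]))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(ncols - 1L)))
  vals <- t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_caspian("caspian_non_numeric_cell", sprintf(
      "non-numeric value at gene %s, column %s",
      gene_ids[bad[1]], header[bad[2] + 1L]))
  }
  experiments <- lapply(seq_len(n_exp), function(j) {
    X <- vals[, exp_id == j, drop = FALSE]
    rownames(X) <- gene_ids
    X
  })
  expression_dataset(experiments, gene_ids = gene_ids)
}

#' Write a grouped-TSV expression table
#'
#' @param data an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  header <- c("gene", unlist(lapply(seq_along(data$experiments), function(j)
    sprintf("E%d:T%d", j, seq_len(ncol(data$experiments[[j]]))))))
  mat <- do.call(cbind, data$experiments)
  rows <- vapply(seq_along(data$gene_ids), function(i)
    paste(c(data$gene_ids[i],
            format(mat[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

sif_sign <- function(word) {
  switch(tolower(word),
         "activates" = , "activation" = , "+" = 1L,
         "inhibits" = , "represses" = , "repression" = , "-" = -1L,
         0L)
}

sif_word <- function(sign) {
  if (is.na(sign) || sign == 0L) "regulates"
  else if (sign > 0) "activates" else "inhibits"
}

#' Read a directed edge list (TSV or SIF)
#'
#' TSV dialect: two tab-separated columns `regulator<TAB>target` (sign 0).
#' SIF dialect: `regulator<TAB>interaction<TAB>target`, where the interaction
#' word `activates` maps to sign +1, `inhibits`/`represses` to -1 and
#' anything else to 0.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param nodes optional node universe; defaults to the genes seen in edges.
#' @return A [directed_network()]; pass it to [scaffold()] for use as a
#'   prior (self-loops are rejected there).
#' @export
read_edges <- function(path, dialect = c("tsv", "sif"), nodes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_caspian("caspian_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  want <- if (dialect == "tsv") 2L else 3L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != want)
  if (length(bad))
    stop_caspian("caspian_ragged_row", sprintf(
      "edge line %d has %d fields; expected %d",
      bad[1], length(fields[[bad[1]]]), want))
  edges <- if (!length(fields)) NULL else if (dialect == "tsv") {
    data.frame(regulator = vapply(fields, `[`, "", 1L),
               target = vapply(fields, `[`, "", 2L),
               sign = 0L, stringsAsFactors = FALSE)
  } else {
    data.frame(regulator = vapply(fields, `[`, "", 1L),
               target = vapply(fields, `[`, "", 3L),
               sign = vapply(fields, function(f) sif_sign(f[2]), 0L),
               stringsAsFactors = FALSE)
  }
  if (is.null(nodes))
    nodes <- unique(c(edges$regulator, edges$target))
  directed_network(nodes, edges)
}

#' Write a network as a TSV or SIF edge list
#'
#' @param net a `directed_network`.
#' @param path output file path.
#' @param dialect `"tsv"` (regulator, target), `"sif"` (regulator,
#'   interaction word, target) or `"table"` (full annotated table with sign,
#'   score and provenance columns).
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path, dialect = c("tsv", "sif", "table")) {
  stopifnot(inherits(net, "directed_network"))
  dialect <- match.arg(dialect)
  e <- net$edges
  lines <- switch(dialect,
    tsv = paste(e$regulator, e$target, sep = "\t"),
    sif = paste(e$regulator, vapply(e$sign, sif_word, ""), e$target,
                sep = "\t"),
    table = c(paste(c("regulator", "target", "sign", "score", "provenance"),
                    collapse = "\t"),
              if (nrow(e)) paste(e$regulator, e$target, e$sign,
                                 format(e$score, digits = 6, trim = TRUE),
                                 e$provenance, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}
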