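# Light edge-list container for directed, signed networks.

#' Directed signed network
#'
#' @param nodes character vector of gene ids.
#' @param edges data frame with columns `regulator`, `target` and optionally
#'   `sign` (-1, 0, +1), `score` (edge F-statistic or weight) and
#'   `provenance` (`"inferred"` or `"scaffold"`). Self-loops are rejected.
#' @return A `directed_network` object.
#' @export
directed_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop_caspian("caspian_invalid_network", "duplicated node ids")
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        sign = integer(0), score = numeric(0),
                        provenance = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    if (is.null(edges$sign)) edges$sign <- 0L
    if (is.null(edges$score)) edges$score <- NA_real_
    if (is.null(edges$provenance)) edges$provenance <- "inferred"
    bad <- setdiff(union(edges$regulator, edges$target), nodes)
    if (length(bad))
      stop_caspian("caspian_invalid_network", sprintf(
        "edge endpoint(s) not in node set: %s", paste(bad, collapse = ", ")))
    if (any(edges$regulator == edges$target))
      stop_caspian("caspian_self_loop", "self-loop edges are not allowed")
    if (anyDuplicated(paste(edges$regulator, edges$target, sep = "\r")))
      stop_caspian("caspian_invalid_network", "duplicated edges")
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edge(s)\n", sep = "")
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) character(0)
  else paste(net$edges$regulator, net$edges$target, sep = "\r")
}

#' Scaffold of trusted prior edges
#'
#' A scaffold collects directed edges that are considered experimentally
#' established. During inference their influence on each target is regressed
#' out before sparse recovery, and they are always emitted in the result
#' (provenance `"scaffold"`).
#'
#' @param edges data frame with columns `regulator` and `target`, or a
#'   `directed_network`.
#' @return A `scaffold` object with a `known_parents` map (target ->
#'   character vector of regulators).
#' @export
scaffold <- function(edges) {
  if (inherits(edges, "directed_network")) edges <- edges$edges
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    return(structure(list(known_parents = list()), class = "scaffold"))
  }
  reg <- as.character(edges$regulator)
  tgt <- as.character(edges$target)
  if (any(reg == tgt))
    stop_caspian("caspian_self_loop", sprintf(
      "scaffold contains self-loop(s) on: %s",
      paste(unique(reg[reg == tgt]), collapse = ", ")))
  kp <- split(reg, tgt)
  kp <- lapply(kp, unique)
  structure(list(known_parents = kp), class = "scaffold")
}
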