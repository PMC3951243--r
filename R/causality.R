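# Granger-causality pruning of List-SP supports, and the end-to-end
# inference drivers (per-target, whole-network, and scaffold-prior variant).

# RSS below this (on unit-norm y) is treated as a numerically perfect fit,
# where the F-statistic is undefined; see granger_tests().
PERFECT_FIT_RSS <- 1e-10

#' Nested-model Granger F-statistic
#'
#' `F = ((RSS_r - RSS_u) / (p_u - p_r)) / (RSS_u / (n - p_u))`, the classical
#' statistic comparing a restricted regression (`p_r` parameters, residual sum
#' of squares `RSS_r`) against a nested unrestricted one (`p_u` parameters,
#' `RSS_u`) on `n` observations. Under the null that the extra `p_u - p_r`
#' coefficients are zero it follows an F distribution with `(p_u - p_r,
#' n - p_u)` degrees of freedom. Negative numerators (possible only through
#' round-off, since nested least squares guarantees `RSS_r >= RSS_u`) are
#' clamped to zero.
#'
#' @param rss_restricted,rss_unrestricted nonnegative residual sums of squares.
#' @param p_r,p_u parameter counts of the nested models, `p_u > p_r >= 0`.
#' @param n number of observations, `n > p_u`.
#' @return The F value (0 when the numerator clamps).
#' @export
f_statistic <- function(rss_restricted, rss_unrestricted, p_r, p_u, n) {
  if (p_u <= p_r || p_r < 0)
    stop_caspian("caspian_invalid_dof", sprintf(
      "need p_u > p_r >= 0 (got p_r = %s, p_u = %s)", p_r, p_u))
  if (n <= p_u)
    stop_caspian("caspian_invalid_dof", sprintf(
      "need n > p_u (got n = %s, p_u = %s)", n, p_u))
  if (rss_unrestricted == 0)
    stop_caspian("caspian_zero_unrestricted_rss",
                 "unrestricted model fits perfectly; F is undefined")
  num <- max(rss_restricted - rss_unrestricted, 0) / (p_u - p_r)
  num / (rss_unrestricted / (n - p_u))
}

# Core of the pruning stage, shared by granger_prune() and the scaffold
# variant (which tests against a residualized y). One joint F-test per
# candidate gene: all of that gene's lag-columns present in the support are
# removed together in the restricted model (df1 = number removed).
#
# Degenerate perfect-fit case (RSS_u ~ 0 on unit-norm y, typical for
# noiseless data): the F-statistic is undefined, so a candidate is accepted
# iff removing its columns raises the RSS above PERFECT_FIT_RSS, reported
# with an Inf/0 sentinel so that rejected_null == (f_statistic >
# critical_value) still holds.
granger_tests <- function(y, Phi, labels, indices, alpha,
                          bonferroni = FALSE, target = NULL) {
  if (alpha <= 0 || alpha >= 1)
    stop_caspian("caspian_invalid_alpha", "alpha must lie in (0, 1)")
  empty <- data.frame(gene = character(0), f_statistic = numeric(0),
                      df1 = integer(0), df2 = integer(0),
                      critical_value = numeric(0), rejected_null = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(indices)) return(empty)
  cand <- unique(labels$gene[indices][!labels$intercept[indices]])
  if (!length(cand)) return(empty)

  n <- length(y)
  p_u <- length(indices)
  if (n <= p_u)
    stop_caspian("caspian_untestable", sprintf(
      "support size %d >= %d observations%s; F-test has no residual degrees of freedom",
      p_u, n, if (is.null(target)) "" else sprintf(" for target %s", target)))
  alpha_eff <- if (bonferroni) alpha / length(cand) else alpha
  fit_u <- least_squares_fit(y, Phi[, indices, drop = FALSE])
  rss_u <- rss_of(fit_u)

  res <- lapply(cand, function(g) {
    rem <- indices[labels$gene[indices] %in% g & !labels$intercept[indices]]
    ridx <- setdiff(indices, rem)
    rss_r <- if (length(ridx)) {
      rss_of(least_squares_fit(y, Phi[, ridx, drop = FALSE]))
    } else {
      sum(y^2)
    }
    df1 <- length(rem)
    df2 <- n - p_u
    crit <- stats::qf(1 - alpha_eff, df1, df2)
    if (rss_u < PERFECT_FIT_RSS) {
      rej <- rss_r > PERFECT_FIT_RSS
      f <- if (rej) Inf else 0
    } else {
      f <- f_statistic(rss_r, rss_u, p_u - df1, p_u, n)
      rej <- f > crit
    }
    data.frame(gene = g, f_statistic = f, df1 = df1, df2 = df2,
               critical_value = crit, rejected_null = rej,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Granger F-test pruning of a recovered support
#'
#' Tests every candidate gene in the support for conditional Granger
#' causality on the target. The unrestricted model regresses `y` on all
#' support columns; per candidate gene, the restricted model removes all of
#' that gene's lag-columns jointly. A gene is kept (`rejected_null`) when its
#' F-statistic exceeds the upper-`alpha` quantile of the F distribution with
#' `(columns removed, n - |support|)` degrees of freedom. The intercept stays
#' in both models and is never tested.
#'
#' @param design a [build_lagged_design()] result.
#' @param support a `support_set` from [list_sp()] (or [subspace_pursuit()]).
#' @param alpha significance level in (0, 1).
#' @param bonferroni when TRUE, divides `alpha` by the number of candidate
#'   genes tested for this target.
#' @return Data frame with one row per candidate gene: `gene`, `f_statistic`,
#'   `df1`, `df2`, `critical_value`, `rejected_null`.
#' @export
granger_prune <- function(design, support, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(design, "lagged_design"))
  idx <- if (inherits(support, "support_set")) support$indices
         else as.integer(support)
  granger_tests(design$y, design$Phi, design$labels, idx, alpha,
                bonferroni = bonferroni, target = design$target)
}

# Sign of a regulator: sign of the sum of its lag-column coefficients in the
# unrestricted fit on the support (0 if |sum| < 1e-12).
regulator_signs <- function(labels, indices, coefficients) {
  genes <- labels$gene[indices]
  keep <- !labels$intercept[indices]
  sums <- tapply(coefficients[keep], genes[keep], sum)
  s <- ifelse(abs(sums) < 1e-12, 0L, ifelse(sums > 0, 1L, -1L))
  stats::setNames(as.integer(s), names(sums))
}

#' Infer the regulators of one target gene
#'
#' Runs the full per-target pipeline: [build_lagged_design()] to form the
#' lagged regression, [list_sp()] to recover a candidate support with
#' sparsity levels up to `k`, and [granger_prune()] to keep only candidates
#' passing the conditional Granger F-test at level `alpha`. Each accepted
#' regulator carries the sign of the sum of its lag-column coefficients in
#' the unrestricted least-squares fit.
#'
#' @param data an [expression_dataset()].
#' @param target the target gene id.
#' @param k sparsity bound (maximum in-degree proxy); an upper bound on the
#'   expected in-degree suffices, since the F-test prunes excess candidates.
#' @param lags maximum time-lag `D`.
#' @param alpha F-test significance level.
#' @param bonferroni per-target Bonferroni correction flag.
#' @return Data frame of accepted regulators: `regulator`, `sign`,
#'   `f_statistic`, `df1`, `df2`, `critical_value`.
#' @export
caspian_target <- function(data, target, k = 5L, lags = 1L, alpha = 0.05,
                           bonferroni = FALSE) {
  design <- build_lagged_design(data, target, lags)
  k_eff <- as.integer(k)
  support <- list_sp(design$y, design$Phi, k_eff)
  tests <- granger_prune(design, support, alpha, bonferroni = bonferroni)
  acc <- tests[tests$rejected_null, , drop = FALSE]
  signs <- regulator_signs(design$labels, support$indices, support$coefficients)
  data.frame(
    regulator = acc$gene,
    sign = if (nrow(acc)) unname(signs[acc$gene]) else integer(0),
    f_statistic = acc$f_statistic,
    df1 = acc$df1, df2 = acc$df2, critical_value = acc$critical_value,
    stringsAsFactors = FALSE
  )
}

#' Infer a whole directed network
#'
#' Applies [caspian_target()] to every gene in turn and unions the results
#' into a [directed_network()]. Per-edge `score` is the F-statistic of the
#' accepting test. Targets whose design or test stage fails (e.g. constant
#' profiles, too few observations) contribute no in-edges and are reported in
#' the `skipped` attribute as target -> condition message.
#'
#' @inheritParams caspian_target
#' @return A `directed_network`; `attr(net, "skipped")` names skipped targets.
#' @export
caspian_network <- function(data, k = 5L, lags = 1L, alpha = 0.05,
                            bonferroni = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  edges <- list()
  skipped <- character(0)
  for (g in data$gene_ids) {
    res <- tryCatch(
      caspian_target(data, g, k = k, lags = lags, alpha = alpha,
                     bonferroni = bonferroni),
      caspianError = function(e) e)
    if (inherits(res, "error")) {
      skipped[g] <- conditionMessage(res)
    } else if (nrow(res)) {
      edges[[g]] <- data.frame(regulator = res$regulator, target = g,
                               sign = res$sign, score = res$f_statistic,
                               provenance = "inferred",
                               stringsAsFactors = FALSE)
    }
  }
  net <- directed_network(data$gene_ids, do.call(rbind, edges))
  attr(net, "skipped") <- skipped
  net
}

#' Raw List-SP network (no Granger pruning)
#'
#' The support-recovery stage alone: every gene appearing in a target's
#' List-SP support becomes an in-edge. Useful as the unpruned baseline when
#' quantifying how much the Granger F-test improves precision.
#'
#' @inheritParams caspian_target
#' @return A `directed_network` with `score` = |sum of lag coefficients|.
#' @export
listsp_network <- function(data, k = 5L, lags = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  edges <- list()
  skipped <- character(0)
  for (g in data$gene_ids) {
    res <- tryCatch({
      design <- build_lagged_design(data, g, lags)
      support <- list_sp(design$y, design$Phi, as.integer(k))
      regs <- map_columns_to_genes(design, support)
      signs <- regulator_signs(design$labels, support$indices,
                               support$coefficients)
      keep <- !design$labels$intercept[support$indices]
      coefsum <- tapply(support$coefficients[keep],
                        design$labels$gene[support$indices][keep], sum)
      data.frame(regulator = regs, target = g,
                 sign = unname(signs[regs]),
                 score = abs(unname(coefsum[regs])),
                 provenance = "inferred", stringsAsFactors = FALSE)
    }, caspianError = function(e) e)
    if (inherits(res, "error")) skipped[g] <- conditionMessage(res)
    else if (nrow(res)) edges[[g]] <- res
  }
  net <- directed_network(data$gene_ids, do.call(rbind, edges))
  attr(net, "skipped") <- skipped
  net
}

#' Network inference given a scaffold of trusted edges
#'
#' For each target gene, the influence of its known scaffold parents is
#' partialled out before inference: the target profile is residualized
#' (`y' = y - Phi_K Phi_K^+ y`, with `Phi_K^+` the Moore-Penrose
#' pseudo-inverse) and the remaining genes' lagged columns are projected off
#' the span of the known parents' columns as well (and re-normalized), so
#' that the reduced regression is exactly the full regression with the known
#' parents' coefficients concentrated out. List-SP and the Granger F-test
#' then run on the residualized problem. Columns falling entirely inside the
#' known parents' span are dropped for that target. Scaffold edges are
#' emitted unconditionally (they are trusted priors), signed by their
#' least-squares coefficients on the original `y`; additional edges are
#' inferred from the residual and marked with provenance `"inferred"`.
#'
#' With an empty scaffold this reduces exactly to [caspian_network()].
#'
#' @inheritParams caspian_target
#' @param prior a [scaffold()] (or an edge data frame coercible to one); all
#'   scaffold genes must exist in the dataset.
#' @return A `directed_network` whose edges carry provenance
#'   `"scaffold"` or `"inferred"`.
#' @export
caspian_with_scaffold <- function(data, prior, k = 5L, lags = 1L,
                                  alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!inherits(prior, "scaffold")) prior <- scaffold(prior)
  sc_genes <- unique(c(names(prior$known_parents),
                       unlist(prior$known_parents, use.names = FALSE)))
  unknown <- setdiff(sc_genes, data$gene_ids)
  if (length(unknown))
    stop_caspian("caspian_unknown_gene", sprintf(
      "scaffold gene(s) not in dataset: %s", paste(unknown, collapse = ", ")))

  edges <- list()
  skipped <- character(0)
  for (g in data$gene_ids) {
    res <- tryCatch({
      design <- build_lagged_design(data, g, lags)
      K <- prior$known_parents[[g]]
      if (length(K)) {
        kidx <- which(design$labels$gene %in% K & !design$labels$intercept)
        Phi_K <- design$Phi[, kidx, drop = FALSE]
        fit_K <- least_squares_fit(design$y, Phi_K)
        sc_signs <- regulator_signs(design$labels, kidx, fit_K$coefficients)
        sc_edges <- data.frame(regulator = K, target = g,
                               sign = unname(sc_signs[K]),
                               score = NA_real_, provenance = "scaffold",
                               stringsAsFactors = FALSE)
        y2 <- fit_K$residual
        rest <- setdiff(seq_len(ncol(design$Phi)), kidx)
        Phi2 <- design$Phi[, rest, drop = FALSE]
        labels2 <- design$labels[rest, , drop = FALSE]
        # Frisch-Waugh: project remaining columns off span(Phi_K) so the
        # reduced regression equals the full one with K concentrated out.
        sv <- svd(Phi_K)
        basis <- sv$u[, sv$d > 1e-10 * sv$d[1], drop = FALSE]
        if (ncol(basis)) {
          proj <- Phi2 - basis %*% crossprod(basis, Phi2)
          norms <- sqrt(colSums(proj^2))
          # intercept is mean-orthogonal to the centered K columns; keep as is
          renorm <- !labels2$intercept & norms > 1e-8
          proj[, renorm] <- sweep(proj[, renorm, drop = FALSE], 2,
                                  norms[renorm], "/")
          proj[, labels2$intercept] <- Phi2[, labels2$intercept]
          keep_cols <- labels2$intercept | norms > 1e-8
          Phi2 <- proj[, keep_cols, drop = FALSE]
          labels2 <- labels2[keep_cols, , drop = FALSE]
        }
      } else {
        sc_edges <- NULL
        y2 <- design$y
        Phi2 <- design$Phi
        labels2 <- design$labels
      }
      # partialling out known parents may leave fewer columns than k; the
      # in-degree bound shrinks with the problem rather than erroring
      k_eff <- if (length(K)) min(as.integer(k), nrow(Phi2), ncol(Phi2))
               else as.integer(k)
      support <- list_sp(y2, Phi2, k_eff)
      tests <- granger_tests(y2, Phi2, labels2, support$indices, alpha,
                             bonferroni = bonferroni, target = g)
      acc <- tests[tests$rejected_null, , drop = FALSE]
      inf_edges <- NULL
      if (nrow(acc)) {
        signs <- regulator_signs(labels2, support$indices,
                                 support$coefficients)
        inf_edges <- data.frame(regulator = acc$gene, target = g,
                                sign = unname(signs[acc$gene]),
                                score = acc$f_statistic,
                                provenance = "inferred",
                                stringsAsFactors = FALSE)
      }
      rbind(sc_edges, inf_edges)
    }, caspianError = function(e) e)
    if (inherits(res, "error")) {
      skipped[g] <- conditionMessage(res)
      # trusted priors are emitted even when inference fails for this target
      K <- prior$known_parents[[g]]
      if (length(K))
        edges[[g]] <- data.frame(regulator = K, target = g, sign = 0L,
                                 score = NA_real_, provenance = "scaffold",
                                 stringsAsFactors = FALSE)
    } else if (!is.null(res) && nrow(res)) {
      edges[[g]] <- res
    }
  }
  net <- directed_network(data$gene_ids, do.call(rbind, edges))
  attr(net, "skipped") <- skipped
  net
}
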