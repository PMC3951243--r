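# Greedy sparse support recovery over an arbitrary measurement vector y and
# sensing matrix Phi. The expression-profile layer (build_lagged_design)
# produces that pair from time-series data; nothing here knows about genes.

new_support_set <- function(indices, coefficients, residual_norm,
                            per_level = NULL) {
  structure(
    list(
      indices = as.integer(indices),
      coefficients = as.numeric(coefficients),
      residual_norm = as.numeric(residual_norm),
      per_level = per_level
    ),
    class = "support_set"
  )
}

#' @export
print.support_set <- function(x, ...) {
  cat("<support_set> ", length(x$indices), " column(s): ",
      paste(x$indices, collapse = ", "),
      "; residual norm ", format(x$residual_norm, digits = 6), "\n", sep = "")
  invisible(x)
}

# Shared input validation for SP / List-SP.
check_sensing_inputs <- function(y, Phi) {
  if (!is.numeric(y) || length(y) < 1L || !all(is.finite(y)))
    stop_caspian("caspian_degenerate_input",
                 "measurement vector y must be numeric, non-empty and finite")
  if (!is.matrix(Phi) || !all(is.finite(Phi)))
    stop_caspian("caspian_degenerate_matrix",
                 "sensing matrix contains non-finite entries or is not a matrix")
  if (nrow(Phi) != length(y))
    stop_caspian("caspian_shape_mismatch", sprintf(
      "sensing matrix has %d rows but y has length %d", nrow(Phi), length(y)))
  if (any(colSums(Phi^2) == 0))
    stop_caspian("caspian_degenerate_matrix",
                 "sensing matrix contains an all-zero column")
  invisible(TRUE)
}

# Indices of the s largest values of v; ties broken by lowest index
# (deterministic output for symmetric inputs).
top_s_indices <- function(v, s) {
  order(-v, seq_along(v))[seq_len(s)]
}

#' Minimum-norm least-squares fit
#'
#' Projects `y` onto the column space of `Phi_S` via the Moore-Penrose
#' pseudo-inverse, computed by SVD with singular values below
#' `1e-10 * max(singular value)` treated as zero. A rank-deficient `Phi_S`
#' therefore yields the minimum-norm coefficient vector instead of failing,
#' which matters when duplicate or collinear lagged profiles end up in one
#' support.
#'
#' @param y numeric measurement vector.
#' @param Phi_S numeric matrix with `length(y)` rows and at least one column.
#' @return A list with `coefficients` (one per column of `Phi_S`), `fitted`
#'   and `residual`; the residual is orthogonal to the column space of
#'   `Phi_S` up to numerical tolerance.
#' @examples
#' Phi <- cbind(c(1, 0, 0), c(0, 1, 0))
#' least_squares_fit(c(5, 2, 1), Phi)$coefficients
#' @export
least_squares_fit <- function(y, Phi_S) {
  Phi_S <- as.matrix(Phi_S)
  y <- as.numeric(y)
  if (nrow(Phi_S) != length(y))
    stop_caspian("caspian_shape_mismatch", sprintf(
      "Phi_S has %d rows but y has length %d", nrow(Phi_S), length(y)))
  if (ncol(Phi_S) < 1L)
    stop_caspian("caspian_shape_mismatch", "Phi_S must have at least one column")
  sv <- svd(Phi_S)
  keep <- sv$d > 1e-10 * sv$d[1]
  coef <- if (any(keep)) {
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
  } else {
    rep(0, ncol(Phi_S))
  }
  fitted <- drop(Phi_S %*% coef)
  list(coefficients = coef, fitted = fitted, residual = y - fitted)
}

rss_of <- function(fit) sum(fit$residual^2)

#' Subspace Pursuit for a fixed sparsity level
#'
#' Greedy recovery of an `s`-column support explaining `y` from the columns of
#' `Phi`. The support is initialized with the `s` columns most correlated with
#' `y`; each iteration adds the `s` columns most correlated with the current
#' residual, solves least squares on the enlarged (at most `2s`) set, keeps
#' the `s` columns with the largest coefficient magnitudes, and re-solves.
#' Iteration stops when the residual norm fails to strictly decrease or after
#' `max_iter` iterations; across iterations the retained residual norm is
#' non-increasing.
#'
#' Correlation and coefficient-magnitude ties are broken toward the lowest
#' column index, making the output deterministic.
#'
#' @param y numeric measurement vector of length `M`.
#' @param Phi numeric `M x P` sensing matrix; no all-zero or non-finite
#'   columns.
#' @param s target sparsity level, `1 <= s <= min(M, P)`.
#' @param max_iter iteration cap (default 100).
#' @return A `support_set`: `indices` (exactly `s` column indices, sorted),
#'   `coefficients` (least-squares fit on those columns) and `residual_norm`.
#' @seealso [list_sp()] for the union over sparsity levels `1..k`.
#' @export
subspace_pursuit <- function(y, Phi, s, max_iter = 100L) {
  check_sensing_inputs(y, Phi)
  M <- nrow(Phi)
  P <- ncol(Phi)
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L || s > min(M, P))
    stop_caspian("caspian_invalid_sparsity", sprintf(
      "sparsity s = %s must lie in [1, min(M = %d, P = %d)]",
      as.character(s), M, P))

  S <- sort(top_s_indices(abs(drop(crossprod(Phi, y))), s))
  fit <- least_squares_fit(y, Phi[, S, drop = FALSE])
  best_rnorm <- sqrt(rss_of(fit))

  for (iter in seq_len(max_iter)) {
    cand <- top_s_indices(abs(drop(crossprod(Phi, fit$residual))), s)
    T_set <- sort(union(S, cand))
    fit_T <- least_squares_fit(y, Phi[, T_set, drop = FALSE])
    keep <- T_set[top_s_indices(abs(fit_T$coefficients), s)]
    S_new <- sort(keep)
    fit_new <- least_squares_fit(y, Phi[, S_new, drop = FALSE])
    rnorm_new <- sqrt(rss_of(fit_new))
    if (rnorm_new < best_rnorm) {
      S <- S_new
      fit <- fit_new
      best_rnorm <- rnorm_new
    } else {
      break
    }
  }
  new_support_set(S, fit$coefficients, best_rnorm)
}

#' List Subspace Pursuit: union of SP supports over sparsity levels 1..k
#'
#' Runs [subspace_pursuit()] for every sparsity level `s = 1..k` and returns
#' the union of the recovered supports, with coefficients from the
#' least-squares fit of `y` on the union. Unioning trades extra false
#' positives (removed downstream by the Granger F-test) for fewer false
#' negatives when the true sparsity is unknown: supports found at low
#' sparsity levels are not always nested in those found at higher levels.
#'
#' @inheritParams subspace_pursuit
#' @param k maximum sparsity level (in-degree bound), `1 <= k <= min(M, P)`.
#'   A loose upper bound on the expected in-degree suffices.
#' @return A `support_set` whose `indices` contain the support returned by
#'   `subspace_pursuit(y, Phi, s)` for every `s <= k`; `per_level` holds the
#'   individual level supports. The residual norm is non-increasing in `k`.
#' @export
list_sp <- function(y, Phi, k, max_iter = 100L) {
  check_sensing_inputs(y, Phi)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > min(nrow(Phi), ncol(Phi)))
    stop_caspian("caspian_invalid_sparsity", sprintf(
      "k = %s must lie in [1, min(M = %d, P = %d)]",
      as.character(k), nrow(Phi), ncol(Phi)))
  per_level <- vector("list", k)
  U <- integer(0)
  for (s in seq_len(k)) {
    sp <- subspace_pursuit(y, Phi, s, max_iter = max_iter)
    per_level[[s]] <- sp$indices
    U <- union(U, sp$indices)
  }
  U <- sort(U)
  fit <- least_squares_fit(y, Phi[, U, drop = FALSE])
  new_support_set(U, fit$coefficients, sqrt(rss_of(fit)), per_level = per_level)
}
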