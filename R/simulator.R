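# Synthetic ground-truth networks and expression time courses.
#
# Dynamics model: a stable linear first-order recursion
#   x(t) = A x(t-1) + b
# with the spectral radius of |A| rescaled to 0.9 so every trajectory
# converges geometrically to the fixed point (I - A)^-1 b = steady_state.
# Measurement noise (white Gaussian, variance a stated fraction of the mean
# squared signal) is added to the observed values, not to the dynamics.

#' Generate a random ground-truth regulatory network
#'
#' Degree-controlled random topology: each gene's candidate parents are drawn
#' by independent Bernoulli(`edge_prob`) trials over the other genes, then
#' uniformly subsampled down to `max_in_degree` when exceeded. Edge weights
#' are uniform on `[-high, -low] U [low, high]`; the full weight matrix is
#' rescaled so the spectral radius of its entrywise absolute value is 0.9
#' (guaranteeing stable, steady-state-convergent dynamics). An optional
#' hub-skewed preset boosts one gene's out-degree, mimicking a master
#' regulator.
#'
#' @param N number of genes (>= 2).
#' @param max_in_degree maximum regulators per gene, `1 <= max_in_degree < N`.
#' @param edge_prob per-pair parent probability in (0, 1).
#' @param weight_range magnitudes `(low, high)` of edge weights before
#'   rescaling.
#' @param seed integer RNG seed (required; generation is fully deterministic
#'   given it).
#' @param hub when TRUE, gene 1 is additionally wired as a parent of a
#'   random half of the other genes (in-degree caps still apply).
#' @return A `synthetic_truth`: `adjacency` (`N x N`, entry `(i, j)` = weight
#'   of edge j -> i), `steady_state`, `max_in_degree`, `gene_ids`, `seed`.
#' @export
generate_network <- function(N, max_in_degree, edge_prob,
                             weight_range = c(0.5, 1), seed,
                             hub = FALSE) {
  N <- as.integer(N)
  max_in_degree <- as.integer(max_in_degree)
  if (N < 2L || max_in_degree < 1L || max_in_degree >= N)
    stop_caspian("caspian_invalid_simconfig",
                 "need N >= 2 and 1 <= max_in_degree < N")
  if (edge_prob < 0 || edge_prob >= 1)
    stop_caspian("caspian_invalid_simconfig", "edge_prob must lie in [0, 1)")
  if (length(weight_range) != 2L || weight_range[1] <= 0 ||
      weight_range[2] < weight_range[1])
    stop_caspian("caspian_invalid_simconfig",
                 "weight_range must be 0 < low <= high")
  set.seed(as.integer(seed))

  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    cand <- setdiff(seq_len(N), i)
    parents <- cand[stats::runif(N - 1L) < edge_prob]
    if (hub && i != 1L && !(1L %in% parents) && stats::runif(1) < 0.5)
      parents <- c(1L, parents)
    if (length(parents) > max_in_degree)
      parents <- sort(sample(parents, max_in_degree))
    if (length(parents)) {
      w <- stats::runif(length(parents), weight_range[1], weight_range[2]) *
        sample(c(-1, 1), length(parents), replace = TRUE)
      A[i, parents] <- w
    }
  }
  if (any(A != 0)) {
    rho <- max(abs(eigen(abs(A), only.values = TRUE)$values))
    if (rho > 0) A <- A * (0.9 / rho)
  }
  steady_state <- stats::runif(N, 0.5, 1.5)
  structure(
    list(adjacency = A, max_in_degree = max_in_degree,
         steady_state = steady_state, gene_ids = paste0("G", seq_len(N)),
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Ground-truth edges as a directed network
#'
#' @param truth a `synthetic_truth`.
#' @return A [directed_network()] with one signed edge per nonzero
#'   off-diagonal adjacency entry (regulator j -> target i for entry (i, j)).
#' @export
truth_network <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  nz <- which(truth$adjacency != 0, arr.ind = TRUE)
  edges <- NULL
  if (nrow(nz)) {
    w <- truth$adjacency[nz]
    edges <- data.frame(
      regulator = truth$gene_ids[nz[, 2]],
      target = truth$gene_ids[nz[, 1]],
      sign = ifelse(w > 0, 1L, -1L),
      score = abs(w),
      provenance = "truth",
      stringsAsFactors = FALSE
    )
  }
  directed_network(truth$gene_ids, edges)
}

#' Simulate expression time courses from a ground-truth network
#'
#' Each experiment starts from an independent uniform [0, 1] initial state
#' per gene and follows the deterministic recursion `x(t) = A x(t-1) + b`,
#' with `b` chosen so the fixed point equals the truth's `steady_state`.
#' After all clean trajectories are generated, white Gaussian measurement
#' noise with variance `noise_power_ratio` times the mean squared clean
#' signal (over every gene, time-point and experiment) is added entrywise.
#'
#' @param truth a [generate_network()] result.
#' @param n_experiments number of independent experiments `E`.
#' @param timepoints per-experiment lengths `M_j` (scalar recycled to `E`).
#' @param noise_power_ratio noise variance as a fraction of mean signal
#'   power; 0 gives noiseless data.
#' @param seed integer RNG seed.
#' @return An [expression_dataset()] with genes `G1..GN`.
#' @export
simulate_expression <- function(truth, n_experiments = 3L, timepoints = 21L,
                                noise_power_ratio = 0, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  E <- as.integer(n_experiments)
  M_j <- rep_len(as.integer(timepoints), E)
  if (E < 1L || any(M_j < 2L))
    stop_caspian("caspian_invalid_simconfig",
                 "need >= 1 experiment with >= 2 time-points each")
  if (noise_power_ratio < 0)
    stop_caspian("caspian_invalid_simconfig",
                 "noise_power_ratio must be nonnegative")
  set.seed(as.integer(seed))
  A <- truth$adjacency
  N <- nrow(A)
  b <- drop((diag(N) - A) %*% truth$steady_state)

  clean <- vector("list", E)
  for (e in seq_len(E)) {
    X <- matrix(0, N, M_j[e])
    X[, 1] <- stats::runif(N, 0, 1)
    for (t in 2:M_j[e]) {
      X[, t] <- drop(A %*% X[, t - 1]) + b
      if (any(abs(X[, t]) > 1e6))
        stop_caspian("caspian_unstable_dynamics",
                     "trajectory diverged; adjacency is not stable")
    }
    clean[[e]] <- X
  }
  if (noise_power_ratio > 0) {
    power <- mean(unlist(clean)^2)
    sigma <- sqrt(noise_power_ratio * power)
    clean <- lapply(clean, function(X)
      X + matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X)))
  }
  clean <- lapply(clean, function(X) {
    rownames(X) <- truth$gene_ids
    X
  })
  expression_dataset(clean, gene_ids = truth$gene_ids)
}

#' Subsample the time-points of a dataset
#'
#' Uniform mode keeps every `round(1 / keep_fraction)`-th time-point of each
#' experiment (a coarser but regular sampling grid); nonuniform mode keeps a
#' uniformly random subset of size `round(keep_fraction * M_j)` per
#' experiment, preserving time order. Downstream profile construction treats
#' the kept points as consecutive steps, so nonuniform subsampling distorts
#' the effective lag structure -- exactly the irregular-sampling regime this
#' operation exists to emulate.
#'
#' @param data an [expression_dataset()].
#' @param keep_fraction fraction of points to keep, in (0, 1].
#' @param mode `"uniform"` or `"nonuniform"`.
#' @param seed RNG seed (used by nonuniform mode).
#' @return An [expression_dataset()] with shortened experiments.
#' @export
subsample_timepoints <- function(data, keep_fraction,
                                 mode = c("uniform", "nonuniform"),
                                 seed = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  mode <- match.arg(mode)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_caspian("caspian_invalid_simconfig",
                 "keep_fraction must lie in (0, 1]")
  if (keep_fraction == 1) return(data)
  if (mode == "nonuniform" && !is.null(seed)) set.seed(as.integer(seed))
  kept <- lapply(data$experiments, function(X) {
    M <- ncol(X)
    idx <- if (mode == "uniform") {
      seq(1L, M, by = max(1L, round(1 / keep_fraction)))
    } else {
      sort(sample(M, round(keep_fraction * M)))
    }
    if (length(idx) < 2L)
      stop_caspian("caspian_too_few_points",
                   "subsampling would leave fewer than 2 time-points")
    X[, idx, drop = FALSE]
  })
  expression_dataset(kept, gene_ids = data$gene_ids,
                     sampling_period = data$sampling_period)
}
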