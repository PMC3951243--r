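# Fixture builders shared across test files. Everything is generated in code
# under explicit seeds; no data files are read.

# M x P matrix with i.i.d. standard normal entries and unit-norm columns.
unit_norm_gaussian <- function(M, P, seed) {
  set.seed(seed)
  Phi <- matrix(rnorm(M * P), M, P)
  sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
}

# Noiseless s-sparse instance: y = Phi[, support] %*% coefs.
sparse_instance <- function(M, P, s, seed, coef_dist = rnorm) {
  Phi <- unit_norm_gaussian(M, P, seed)
  support <- sort(sample(P, s))
  coefs <- coef_dist(s)
  list(Phi = Phi, support = support, coefs = coefs,
       y = drop(Phi[, support, drop = FALSE] %*% coefs))
}

# Independent oracle: exhaustive least-squares search over all s-subsets,
# using QR projections (a different numerical path than the package's SVD
# pseudo-inverse).
exhaustive_support_oracle <- function(y, Phi, s) {
  subs <- utils::combn(ncol(Phi), s)
  rss <- apply(subs, 2, function(ss)
    sum(qr.resid(qr(Phi[, ss, drop = FALSE]), y)^2))
  sort(subs[, which.min(rss)])
}

# Expression dataset driven by an explicit weighted adjacency (entry (i, j)
# = weight of j -> i): regulated genes follow deterministic linear lag-1
# dynamics, parentless genes are i.i.d. uniform exogenous inputs (persistent
# excitation, so hand-built sparse topologies stay identifiable). Optional
# i.i.d. Gaussian measurement noise on top.
var1_dataset <- function(A, n_experiments = 3, timepoints = 21,
                         noise_sd = 0, seed = 1,
                         steady_state = NULL) {
  N <- nrow(A)
  truth <- manual_truth(A, steady_state = steady_state)
  set.seed(seed)
  b <- drop((diag(N) - A) %*% truth$steady_state)
  exo <- rowSums(A != 0) == 0
  exps <- lapply(seq_len(n_experiments), function(e) {
    X <- matrix(0, N, timepoints)
    X[, 1] <- runif(N)
    for (t in 2:timepoints) {
      X[, t] <- drop(A %*% X[, t - 1]) + b
      X[exo, t] <- runif(sum(exo))
    }
    if (noise_sd > 0) X <- X + matrix(rnorm(length(X), 0, noise_sd), N)
    rownames(X) <- truth$gene_ids
    X
  })
  list(data = expression_dataset(exps, truth$gene_ids), truth = truth)
}

# Wrap a hand-written adjacency as a synthetic_truth object.
manual_truth <- function(A, steady_state = NULL) {
  N <- nrow(A)
  if (is.null(steady_state)) steady_state <- rep(1, N)
  structure(
    list(adjacency = A, max_in_degree = max(rowSums(A != 0)),
         steady_state = steady_state, gene_ids = paste0("G", seq_len(N)),
         seed = NA_integer_),
    class = "synthetic_truth"
  )
}

edge_set <- function(net) {
  if (!nrow(net$edges)) character(0)
  else sort(paste(net$edges$regulator, net$edges$target, sep = "->"))
}
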