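# Chain topology used by several blocks: G1 -> G2 -> G3 (and extra genes).
chain_adjacency <- function(N, w = 0.6) {
  A <- matrix(0, N, N)
  A[2, 1] <- w
  A[3, 2] <- -w
  A
}

test_that("the nested-model F statistic follows its defining arithmetic", {
  expect_equal(f_statistic(10, 5, 2, 4, 20), 8.0)
  expect_equal(f_statistic(5, 5, 2, 4, 20), 0.0)
  expect_equal(f_statistic(4.9, 5, 2, 4, 20), 0.0) # round-off clamps to 0
  expect_error(f_statistic(10, 5, 4, 4, 20), class = "caspian_invalid_dof")
  expect_error(f_statistic(10, 5, 2, 4, 4), class = "caspian_invalid_dof")
  expect_error(f_statistic(10, 0, 2, 4, 20),
               class = "caspian_zero_unrestricted_rss")
})

test_that("Granger pruning separates a real lag-1 driver from a bystander", {
  # target C driven only by A; B independent; mild noise keeps RSS_u > 0
  set.seed(31)
  M <- 40
  A <- runif(M); B <- runif(M)
  C <- c(runif(1), 0.8 * A[-M]) + rnorm(M, 0, 0.02)
  data <- expression_dataset(list(rbind(A = A, B = B, C = C)), c("A", "B", "C"))
  d <- build_lagged_design(data, "C", lags = 1)
  sup <- which(!d$labels$intercept) # both candidate columns (A,1), (B,1)
  res <- granger_prune(d, sup, alpha = 0.05)
  res <- res[order(res$gene), ]
  expect_identical(res$gene, c("A", "B"))
  expect_true(res$rejected_null[res$gene == "A"])
  expect_false(res$rejected_null[res$gene == "B"])
  # decision rule is exactly the quantile comparison
  expect_identical(res$rejected_null, res$f_statistic > res$critical_value)
  # RSS values agree with a direct regression oracle
  rss_u <- sum(qr.resid(qr(d$Phi[, sup, drop = FALSE]), d$y)^2)
  ia <- which(d$labels$gene == "A")
  rss_r <- sum(qr.resid(qr(d$Phi[, setdiff(sup, ia), drop = FALSE]), d$y)^2)
  f_oracle <- ((rss_r - rss_u) / 1) / (rss_u / (length(d$y) - length(sup)))
  expect_equal(res$f_statistic[res$gene == "A"], f_oracle, tolerance = 1e-8)
})

test_that("a regulator duplicated by an identical gene cannot be individually significant", {
  set.seed(32)
  M <- 30
  A <- runif(M)
  D <- A # exact copy
  C <- c(runif(1), 0.7 * A[-M]) + rnorm(M, 0, 0.05)
  data <- expression_dataset(list(rbind(A = A, D = D, C = C)), c("A", "D", "C"))
  d <- build_lagged_design(data, "C", lags = 1)
  res <- granger_prune(d, which(!d$labels$intercept), alpha = 0.05)
  expect_true(all(res$f_statistic < 1e-6)) # removal changes nothing
  expect_false(any(res$rejected_null))
})

test_that("support exceeding the observation count is an untestable configuration", {
  data <- make_dataset <- expression_dataset(
    list(matrix(runif(12), 3, 4, dimnames = list(c("A", "B", "C"), NULL))))
  d <- build_lagged_design(data, "A", lags = 1)
  expect_error(granger_prune(d, seq_len(ncol(d$Phi)), alpha = 0.05),
               class = "caspian_untestable")
})

test_that("per-target inference recovers signed parents from noiseless dynamics", {
  # 5 genes; G5 has parents G1 (+0.8) and G2 (-0.6)
  A <- matrix(0, 5, 5)
  A[5, 1] <- 0.8
  A[5, 2] <- -0.6
  fx <- var1_dataset(A, n_experiments = 3, timepoints = 15, seed = 41)
  res <- caspian_target(fx$data, "G5", k = 4, lags = 1, alpha = 0.01)
  res <- res[order(res$regulator), ]
  expect_identical(res$regulator, c("G1", "G2"))
  expect_identical(res$sign, c(1L, -1L))
})

test_that("alpha close to 1 accepts every supported candidate; outputs nest in the support", {
  set.seed(42)
  fx <- var1_dataset(chain_adjacency(5), timepoints = 15,
                     noise_sd = 0.05, seed = 43)
  d <- build_lagged_design(fx$data, "G2", lags = 1)
  sup <- list_sp(d$y, d$Phi, 4)
  res <- caspian_target(fx$data, "G2", k = 4, lags = 1, alpha = 1 - 1e-9)
  expect_setequal(res$regulator, map_columns_to_genes(d, sup))
  # nesting at ordinary alpha
  res2 <- caspian_target(fx$data, "G2", k = 4, lags = 1, alpha = 0.05)
  expect_true(all(res2$regulator %in% map_columns_to_genes(d, sup)))
})

test_that("edge sets are monotone in alpha for fixed data and k", {
  fx <- var1_dataset(chain_adjacency(6), timepoints = 18,
                     noise_sd = 0.1, seed = 44)
  nets <- lapply(c(0.001, 0.01, 0.05, 0.2), function(a)
    edge_set(caspian_network(fx$data, k = 4, lags = 1, alpha = a)))
  for (i in seq_len(length(nets) - 1))
    expect_true(all(nets[[i]] %in% nets[[i + 1]]))
})

test_that("whole-network inference finds a chain without shortcutting it", {
  fx <- var1_dataset(chain_adjacency(5), timepoints = 20, seed = 45)
  net <- caspian_network(fx$data, k = 4, lags = 1, alpha = 0.01)
  found <- edge_set(net)
  expect_true(all(c("G1->G2", "G2->G3") %in% found))
  expect_false("G1->G3" %in% found) # indirect path screened out
})

test_that("independent genes yield an empty or near-empty network at strict alpha", {
  set.seed(46)
  X <- matrix(runif(2 * 30), 2, 30, dimnames = list(c("A", "B"), NULL))
  data <- expression_dataset(list(X))
  net <- caspian_network(data, k = 2, lags = 1, alpha = 0.001)
  expect_lte(nrow(net$edges), 1)
})

test_that("inference is invariant to positive rescaling of any gene", {
  fx <- var1_dataset(chain_adjacency(5), timepoints = 15,
                     noise_sd = 0.05, seed = 47)
  scaled <- lapply(fx$data$experiments, function(X) {
    X["G2", ] <- 7 * X["G2", ]
    X
  })
  data2 <- expression_dataset(scaled, fx$data$gene_ids)
  n1 <- caspian_network(fx$data, k = 4, lags = 1, alpha = 0.05)
  n2 <- caspian_network(data2, k = 4, lags = 1, alpha = 0.05)
  expect_identical(edge_set(n1), edge_set(n2))
})

test_that("scaffold priors reduce to plain inference when empty and absorb known parents", {
  A <- matrix(0, 5, 5)
  A[5, 1] <- 0.8
  A[5, 2] <- -0.6
  A[3, 2] <- 0.7
  fx <- var1_dataset(A, timepoints = 15, seed = 48)

  # empty scaffold: identical edges
  plain <- caspian_network(fx$data, k = 4, lags = 1, alpha = 0.01)
  empty <- caspian_with_scaffold(fx$data, scaffold(data.frame()),
                                 k = 4, lags = 1, alpha = 0.01)
  expect_identical(plain$edges, empty$edges)

  # all true parents of G5 known: no additional inferred in-edges for G5
  sc_all <- scaffold(data.frame(regulator = c("G1", "G2"),
                                target = c("G5", "G5")))
  net <- caspian_with_scaffold(fx$data, sc_all, k = 4, lags = 1, alpha = 0.01)
  in5 <- net$edges[net$edges$target == "G5", ]
  expect_setequal(in5$regulator, c("G1", "G2"))
  expect_true(all(in5$provenance == "scaffold"))
  expect_identical(sort(in5$sign), c(-1L, 1L))

  # one of two parents known: the other is recovered from the residual
  sc_one <- scaffold(data.frame(regulator = "G1", target = "G5"))
  net1 <- caspian_with_scaffold(fx$data, sc_one, k = 4, lags = 1, alpha = 0.01)
  in5 <- net1$edges[net1$edges$target == "G5", ]
  expect_true("G2" %in% in5$regulator[in5$provenance == "inferred"])
  expect_true("G1" %in% in5$regulator[in5$provenance == "scaffold"])

  # unknown scaffold gene is named in the error
  expect_error(
    caspian_with_scaffold(fx$data, scaffold(data.frame(regulator = "GX",
                                                       target = "G5")),
                          k = 4, lags = 1, alpha = 0.01),
    regexp = "GX")
  expect_error(scaffold(data.frame(regulator = "A", target = "A")),
               class = "caspian_self_loop")
})

test_that("a wrong scaffold edge is emitted by construction", {
  fx <- var1_dataset(chain_adjacency(5), timepoints = 15, seed = 49)
  wrong <- scaffold(data.frame(regulator = "G4", target = "G5"))
  net <- caspian_with_scaffold(fx$data, wrong, k = 4, lags = 1, alpha = 0.01)
  expect_true("G4->G5" %in% edge_set(net))
})

test_that("Bonferroni option only ever removes edges", {
  fx <- var1_dataset(chain_adjacency(6), timepoints = 18,
                     noise_sd = 0.1, seed = 50)
  plain <- edge_set(caspian_network(fx$data, k = 4, lags = 1, alpha = 0.05))
  bonf <- edge_set(caspian_network(fx$data, k = 4, lags = 1, alpha = 0.05,
                                   bonferroni = TRUE))
  expect_true(all(bonf %in% plain))
})
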