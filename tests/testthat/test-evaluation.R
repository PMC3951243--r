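net_of <- function(nodes, ...) {
  e <- list(...)
  edges <- if (length(e))
    data.frame(regulator = vapply(e, `[`, "", 1L),
               target = vapply(e, `[`, "", 2L), stringsAsFactors = FALSE)
  directed_network(nodes, edges)
}

test_that("confusion counts partition the ordered-pair universe", {
  nodes <- paste0("G", 1:5)
  truth <- net_of(nodes, c("G1", "G2"), c("G2", "G3"), c("G3", "G4"),
                  c("G4", "G5"), c("G5", "G1"))

  c1 <- confusion(truth, truth)
  expect_identical(c(c1$TP, c1$FP, c1$FN, c1$TN), c(5L, 0L, 0L, 15L))

  c2 <- confusion(net_of(nodes), truth)
  expect_identical(c(c2$TP, c2$FP, c2$FN), c(0L, 0L, 5L))

  # complement of truth within the 20-pair universe
  all_pairs <- expand.grid(regulator = nodes, target = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
  keys <- paste(all_pairs$regulator, all_pairs$target)
  tkeys <- paste(truth$edges$regulator, truth$edges$target)
  comp <- directed_network(nodes, all_pairs[!(keys %in% tkeys), ])
  c3 <- confusion(comp, truth)
  expect_identical(c(c3$TP, c3$FP), c(0L, 15L))

  expect_identical(c3$TP + c3$FP + c3$TN + c3$FN, 20L)
  expect_error(confusion(net_of(c("A", "B")), truth),
               class = "caspian_node_mismatch")
})

test_that("metrics reproduce their defining ratios with undefined markers", {
  m <- network_metrics(list(TP = 3, FP = 1, FN = 2, TN = 14))
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f_measure, 2 * 0.75 * 0.6 / (0.75 + 0.6))

  m0 <- network_metrics(list(TP = 0, FP = 0, FN = 3, TN = 17))
  expect_true(is.na(m0$precision)) # explicit undefined marker
  expect_identical(m0$sensitivity, 0)

  mp <- network_metrics(list(TP = 5, FP = 0, FN = 0, TN = 15))
  expect_true(all(unlist(mp) == 1))
})

test_that("metrics are invariant to gene relabeling", {
  nodes <- paste0("G", 1:4)
  truth <- net_of(nodes, c("G1", "G2"), c("G3", "G4"))
  inferred <- net_of(nodes, c("G1", "G2"), c("G2", "G3"))
  perm <- c(G1 = "X4", G2 = "X2", G3 = "X3", G4 = "X1")
  relabel <- function(net) {
    e <- net$edges
    e$regulator <- unname(perm[e$regulator])
    e$target <- unname(perm[e$target])
    directed_network(unname(perm[net$nodes]), e)
  }
  m1 <- network_metrics(confusion(inferred, truth))
  m2 <- network_metrics(confusion(relabel(inferred), relabel(truth)))
  expect_identical(m1, m2)
})

test_that("multiplicity ratios divide by the total number of runs", {
  nodes <- c("A", "B", "C")
  withE <- net_of(nodes, c("A", "B"))
  without <- net_of(nodes)
  runs <- c(rep(list(withE), 7), rep(list(without), 3))
  mr <- multiplicity_ratio(runs)
  expect_identical(nrow(mr), 1L)
  expect_equal(mr$mr, 0.7)

  one <- multiplicity_ratio(list(net_of(nodes, c("A", "B"), c("B", "C"))))
  expect_true(all(one$mr == 1))

  expect_false("C" %in% multiplicity_ratio(runs)$regulator) # absent edge absent
  expect_error(multiplicity_ratio(list()), class = "caspian_invalid_runs")
})

test_that("random panel runs are seeded, core-restricted and full-panel-consistent", {
  tr <- generate_network(12, 2, 0.2, seed = 60)
  ds <- simulate_expression(tr, 2, 15, 0, seed = 61)
  core <- paste0("G", 1:4)

  # single run over the full gene set equals plain inference on core edges
  runs <- random_panel_runs(ds, core, panel_size = 12, n_runs = 1,
                            k = 3, lags = 1, alpha = 0.01, seed = 62)
  full <- caspian_network(ds, k = 3, lags = 1, alpha = 0.01)
  keep <- full$edges$regulator %in% core & full$edges$target %in% core
  expect_identical(edge_set(runs[[1]]),
                   edge_set(directed_network(core, full$edges[keep, ])))

  # fixed master seed reproduces the whole run list
  r1 <- random_panel_runs(ds, core, 8, 4, k = 3, alpha = 0.05, seed = 63)
  r2 <- random_panel_runs(ds, core, 8, 4, k = 3, alpha = 0.05, seed = 63)
  expect_identical(lapply(r1, edge_set), lapply(r2, edge_set))
  expect_true(all(unlist(lapply(r1, function(n)
    c(n$edges$regulator, n$edges$target))) %in% core))

  expect_error(random_panel_runs(ds, core, 2, 1, seed = 1),
               class = "caspian_invalid_simconfig")
})

test_that("true core edges accumulate higher multiplicity ratios than non-edges", {
  tr <- generate_network(30, 2, 0.1, seed = 64)
  ds <- simulate_expression(tr, 3, 15, 0, seed = 65)
  tn <- truth_network(tr)
  core <- paste0("G", 1:6)
  runs <- random_panel_runs(ds, core, panel_size = 15, n_runs = 6,
                            k = 4, lags = 1, alpha = 0.01, seed = 66)
  mr <- multiplicity_ratio(runs)
  key <- paste(mr$regulator, mr$target, sep = "->")
  tkey <- paste(tn$edges$regulator, tn$edges$target, sep = "->")
  is_true_edge <- key %in% tkey
  expect_true(any(is_true_edge) && !all(is_true_edge))
  expect_gt(mean(mr$mr[is_true_edge]), mean(mr$mr[!is_true_edge]))
})
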