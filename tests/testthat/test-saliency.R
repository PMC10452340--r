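test_that("input gradients of a linear surrogate equal |C| exactly", {
  g <- randomGraph(5, 3, seed = 1)
  set.seed(2)
  C1 <- matrix(rnorm(15), 5, 3)
  C0 <- matrix(rnorm(15), 5, 3)
  lin <- LinearGraphModel(list(C0, C1))
  W1 <- inputGradients(lin, g, classIndex = 1L)
  expect_equal(unname(W1), abs(C1), ignore_attr = TRUE)
  expect_identical(attr(W1, "class_index"), 1L)

  # a channel the score ignores has an all-zero gradient column
  C1z <- C1; C1z[, 2] <- 0
  Wz <- inputGradients(LinearGraphModel(list(C0, C1z)), g, 1L)
  expect_true(all(Wz[, 2] == 0))

  expect_error(inputGradients(lin, g, classIndex = 2L), "out of range")
})

test_that("autodiff input gradients agree with finite differences", {
  g <- randomGraph(6, 4, seed = 13)
  model <- initGraphModel(smallConfig(seed = 13), channelNames(g))
  W <- inputGradients(model, g, classIndex = 0L)
  fd <- fdInputGradients(model, g, classIndex = 0L)
  expect_lt(max(abs(W - fd) / pmax(fd, 1e-6)), 1e-4)
})

test_that("unweighted saliency is the row-wise channel maximum", {
  W <- rbind(c(1, 2), c(3, 4))
  expect_equal(unname(unweightedNodeSaliency(W)), c(2, 4))
  expect_equal(unname(unweightedNodeSaliency(matrix(c(5, 1), 2, 1))),
               c(5, 1))
  expect_equal(unname(unweightedNodeSaliency(matrix(0, 3, 2))), rep(0, 3))
  expect_error(unweightedNodeSaliency(matrix(0, 0, 2)), "nonempty")
})

test_that("Gram matrix holds channel inner products and is symmetric PSD", {
  expect_equal(gramMatrix(diag(2)), diag(2))
  expect_equal(gramMatrix(rbind(c(1, 2), c(3, 4))),
               rbind(c(10, 14), c(14, 20)))
  set.seed(42)
  for (i in 1:20) {
    W <- matrix(runif(8 * 4), 8, 4)
    G <- gramMatrix(W)
    # brute-force inner products
    Gref <- matrix(0, 4, 4)
    for (k in 1:4) for (l in 1:4) Gref[k, l] <- sum(W[, k] * W[, l])
    expect_equal(G, Gref, tolerance = 1e-12)
    expect_equal(G, t(G))
    expect_gt(min(eigen(G, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("channel strengths are column means of the Gram matrix", {
  expect_equal(channelStrengths(rbind(c(10, 14), c(14, 20))), c(12, 17))
  expect_equal(channelStrengths(diag(3)), rep(1 / 3, 3))
  expect_equal(channelStrengths(matrix(1, 2, 2)), c(1, 1))
})

test_that("channel weights follow the IDF-style log ratio", {
  cfg <- saliencyConfig()
  # equal channels approach log K
  for (c0 in c(0.5, 1, 7)) {
    t4 <- channelWeights(rep(c0, 4), cfg)
    expect_equal(t4, rep(t4[1], 4))
    expect_equal(t4[1], log((4e-8 + 4 * c0^2) / (1e-8 + c0^2)),
                 tolerance = 1e-12)
  }
  # hand-evaluated case
  expect_equal(channelWeights(c(4, 1, 1), cfg),
               c(log(18 / 16), log(18), log(18)), tolerance = 1e-6)
  # degenerate single channel
  expect_equal(channelWeights(5, cfg), 0)
  expect_error(channelWeights(c(1, -1), cfg), "nonnegative")
})

test_that("stronger channels get strictly smaller weights", {
  cfg <- saliencyConfig()
  grid <- seq(0.1, 10, length.out = 120)
  t1 <- vapply(grid, function(v)
    channelWeights(c(v, 1, 1), cfg)[1], numeric(1))
  expect_true(all(diff(t1) < 0))
})

test_that("node saliency is the exact matrix product W T", {
  expect_equal(unname(nodeSaliency(diag(2), c(2, 3))), c(2, 3))
  expect_equal(unname(nodeSaliency(rbind(c(1, 2), c(3, 4)), c(0.5, 0.25))),
               c(1.0, 2.5))
  expect_equal(unname(nodeSaliency(rbind(c(1, 2), c(3, 4)), c(0, 0))),
               c(0, 0))
  expect_error(nodeSaliency(diag(2), c(1, 2, 3)), "does not match")
})

test_that("explain() on a linear surrogate matches the chained closed form", {
  g <- randomGraph(6, 3, seed = 5)
  set.seed(6)
  C1 <- matrix(rnorm(18), 6, 3)
  lin <- LinearGraphModel(list(-C1, C1))
  ex <- explainGraph(lin, g, classIndex = 1L)
  W <- abs(C1)
  G <- t(W) %*% W
  V <- colSums(G) / 3
  T_ <- log((3e-8 + sum(V^2)) / (1e-8 + V^2))
  M <- drop(W %*% T_)
  expect_equal(unname(saliencyScores(ex)), W, tolerance = 1e-8)
  expect_equal(unname(channelWeightVector(ex)), T_, tolerance = 1e-8)
  expect_equal(unname(nodeSaliencyMap(ex)), M, tolerance = 1e-8)
})

test_that("explanations are equivariant in nodes and channels", {
  g <- randomGraph(7, 4, seed = 8)
  model <- initGraphModel(smallConfig(seed = 8), channelNames(g))
  ex <- explainGraph(model, g)

  set.seed(18)
  perm <- sample(nNodes(g))
  exp_ <- explainGraph(model, permuteGraph(g, perm))
  expect_equal(unname(exp_@M), unname(ex@M[perm]), tolerance = 1e-12)
  expect_equal(unname(exp_@W), unname(ex@W[perm, ]), tolerance = 1e-12)
  expect_equal(exp_@T, ex@T, tolerance = 1e-12)

  # permuting channels permutes T and W columns and leaves M unchanged
  cperm <- c(3, 1, 4, 2)
  gC <- CellDrugGraph(nodeIds(g), adjacency(g),
                      features(g)[, cperm], channelNames(g)[cperm],
                      responseLabel(g), tissueGroup(g))
  modelC <- model
  modelC@params$Win <- model@params$Win[cperm, , drop = FALSE]
  modelC@channelNames <- channelNames(g)[cperm]
  exC <- explainGraph(modelC, gC)
  expect_equal(exC@T, ex@T[cperm], tolerance = 1e-12)
  expect_equal(unname(exC@M), unname(ex@M), tolerance = 1e-12)
})

test_that("scaling W rescales M through the documented weight transform", {
  set.seed(30)
  W <- matrix(runif(20, 0.2, 2), 5, 4)
  cfg <- saliencyConfig()
  c0 <- 10
  pipe <- function(W) {
    T_ <- channelWeights(channelStrengths(gramMatrix(W)), cfg)
    list(T = T_, M = nodeSaliency(W, T_))
  }
  base <- pipe(W)
  scaled <- pipe(c0 * W)
  # at epsilon = 1e-8 the weights are scale-invariant to ~1e-6 ...
  expect_equal(scaled$T, base$T, tolerance = 1e-6)
  # ... so the map scales by c up to the same tolerance
  expect_equal(scaled$M, c0 * base$M, tolerance = 1e-5)
})

test_that("importance aggregation rescales per graph and averages per group", {
  m1 <- c(a = 0, b = 2)
  m2 <- c(a = 2, b = 0)
  rep <- aggregateImportance(list(m1, m2), c("x", "x"))
  df <- importanceScores(rep)
  expect_equal(df$score, c(0.5, 0.5))

  # identical maps reproduce the scaled map
  rep2 <- aggregateImportance(list(m1, m1, m1), rep("x", 3))
  expect_equal(importanceScores(rep2)$score, c(0, 1))

  # all-zero maps stay zero
  rep0 <- aggregateImportance(list(c(a = 0, b = 0)), "x")
  expect_equal(importanceScores(rep0)$score, c(0, 0))

  expect_error(aggregateImportance(list(m1, c(z = 1, w = 2)), c("x", "x")),
               "share the same node ids")
  expect_error(aggregateImportance(list(m1), c("x", "y")), "tag each map")
})

test_that("rankings clamp k, sort descending and break ties by node id", {
  rep <- new("ImportanceReport",
             scores = data.frame(group = "g",
                                 node_id = c("nB", "nA", "nC"),
                                 score = c(0.5, 0.5, 0.9)))
  top <- topRanked(rep, 2)
  expect_equal(top$node_id, c("nC", "nA"))
  full <- topRanked(rep, 10)
  expect_equal(nrow(full), 3L)
  expect_equal(full$node_id, c("nC", "nA", "nB"))
})

test_that("kinase restriction filters then re-ranks without changing scores", {
  rep <- new("ImportanceReport",
             scores = data.frame(group = "g",
                                 node_id = c("a", "b"),
                                 score = c(0.9, 0.5)))
  r1 <- restrictToKinases(rep, c("a", "b"))
  expect_equal(importanceScores(r1), importanceScores(rep))
  r2 <- restrictToKinases(rep, "b")
  top <- topRanked(r2, 1)
  expect_equal(top$node_id, "b")
  expect_equal(top$score, 0.5)
  expect_error(restrictToKinases(rep, "zz"), "no report nodes")
})

test_that("cohortImportance produces per-group kinase rankings", {
  co <- generateCohort(tinyCohortConfig(seed = 31))
  cfg <- modelConfig(embed_dim = 8, n_blocks = 1, set2set_steps = 2,
                     fc_layers = 8, learning_rate = 1e-2, epochs = 40,
                     seed = 31)
  model <- trainModel(co$graphs, cfg)
  rep <- cohortImportance(model, co$graphs,
                          kinaseIds = co$truth$kinaseIds)
  df <- importanceScores(rep)
  expect_setequal(unique(df$group), c("a", "b"))
  expect_true(all(df$node_id %in% co$truth$kinaseIds))
  expect_true(all(df$score >= 0 & df$score <= 1))
})
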