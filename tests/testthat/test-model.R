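test_that("node embedding is a per-node linear map of the features", {
  g <- makeGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4)), k = 3)
  cfg <- smallConfig(embed_dim = 3L)
  model <- initGraphModel(cfg, channelNames(g))

  # identity-like parameters reproduce the feature rows (D = K)
  model@params$Win <- diag(3)
  model@params$bin <- numeric(3)
  expect_equal(unname(embedNodes(model, g)), unname(features(g)))

  # zero features with zero bias give zero embeddings
  g0 <- makeGraph(4, rbind(c(1, 2)), X = matrix(0, 4, 3))
  expect_true(all(embedNodes(model, g0) == 0))

  # embedding is a function of the node's own row only
  X <- features(g); X[2, ] <- X[1, ]
  g2 <- makeGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4)), X = X)
  E <- embedNodes(model, g2)
  expect_identical(E[1, ], E[2, ])

  # channel-count mismatch is a configuration error
  expect_error(embedNodes(model, makeGraph(4, rbind(c(1, 2)), k = 2)),
               "channels")
})

test_that("attention block reduces to the self-transform without edges", {
  g <- makeGraph(5, matrix(numeric(0), 0, 2), k = 2)
  cfg <- smallConfig(seed = 7)
  model <- initGraphModel(cfg, channelNames(g))
  H <- embedNodes(model, g)
  out <- attentionBlock(model, g, H, block = 1L)
  # every neighbourhood is the self-loop alone: update is elu(Z_i + b)
  Z <- H %*% model@params$blk1_W
  expected <- graphSaliency:::.elu(Z + rep(model@params$blk1_b, each = 5))
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("attention over identical-leaf star graphs is uniform on leaves", {
  # star: node 1 is the hub, 4 leaves with identical embeddings
  edges <- cbind(rep(1, 4), 2:5)
  g <- makeGraph(5, edges, k = 2)
  cfg <- smallConfig(seed = 2)
  model <- initGraphModel(cfg, channelNames(g))
  H <- matrix(0.3, 5, cfg$embed_dim)
  H[1, ] <- rnorm(cfg$embed_dim)          # hub differs; leaves identical
  Z <- H %*% model@params$blk1_W
  s <- drop(Z %*% model@params$blk1_as)
  d <- drop(Z %*% model@params$blk1_ad)
  Et <- graphSaliency:::.lrelu(outer(s, d, "+"))
  mask <- graphSaliency:::.graphMask(g)
  Alpha <- graphSaliency:::.rowSoftmaxMasked(Et, mask)
  leafW <- Alpha[1, 2:5]
  expect_true(max(leafW) - min(leafW) < 1e-14)
  expect_equal(sum(Alpha[1, ]), 1)
})

test_that("a path-graph centre node matches the hand-computed update", {
  g <- makeGraph(3, rbind(c(1, 2), c(2, 3)), k = 2,
                 X = matrix(c(0.1, 0.5, -0.3, 0.2, -0.1, 0.4), 3, 2))
  cfg <- modelConfig(embed_dim = 2, n_blocks = 1, set2set_steps = 1,
                     fc_layers = 2, seed = 1)
  model <- initGraphModel(cfg, channelNames(g))
  W <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  as_ <- c(0.4, -0.1); ad_ <- c(0.2, 0.6); b <- c(0.05, -0.05)
  model@params$blk1_W <- W
  model@params$blk1_as <- as_
  model@params$blk1_ad <- ad_
  model@params$blk1_b <- b

  H <- features(g)                        # use features as embeddings
  out <- attentionBlock(model, g, H, 1L)

  # hand evaluation for the centre node (neighbourhood = {1, 2, 3})
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  Z <- H %*% W
  sc <- vapply(1:3, function(j)
    lrelu(sum(Z[2, ] * as_) + sum(Z[j, ] * ad_)), numeric(1))
  al <- exp(sc - max(sc)); al <- al / sum(al)
  expected <- elu(al[1] * Z[1, ] + al[2] * Z[2, ] + al[3] * Z[3, ] + b)
  expect_equal(unname(out[2, ]), unname(expected), tolerance = 1e-12)
})

test_that("Set2Set readout is permutation invariant with length 2D", {
  cfg <- smallConfig(seed = 4)
  model <- initGraphModel(cfg, paste0("c", 1:3))
  E <- matrix(rnorm(6 * cfg$embed_dim), 6)
  r1 <- set2setReadout(model, E)
  expect_length(r1, 2L * cfg$embed_dim)
  perm <- c(4, 1, 6, 2, 5, 3)
  r2 <- set2setReadout(model, E[perm, , drop = FALSE])
  expect_equal(r1, r2, tolerance = 1e-12)

  # single node: a deterministic function of that node alone
  r3 <- set2setReadout(model, E[3, , drop = FALSE])
  r4 <- set2setReadout(model, E[3, , drop = FALSE])
  expect_identical(r3, r4)

  # equal embeddings: the read vector equals the common row
  Eq <- matrix(rep(E[1, ], each = 4), 4)
  rq <- set2setReadout(model, Eq)
  expect_equal(rq[(cfg$embed_dim + 1):(2 * cfg$embed_dim)], E[1, ],
               tolerance = 1e-12)

  expect_error(set2setReadout(model, E[0, , drop = FALSE]), "at least one")
})

test_that("predictions are normalized, deterministic, ties go to class 0", {
  g <- randomGraph(7, 4, seed = 11)
  model <- initGraphModel(smallConfig(seed = 5), channelNames(g))
  out <- predictGraph(model, g)
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-9)
  expect_true(all(out$class_probs >= 0))
  expect_identical(out$predicted_class,
                   which.max(out$class_scores) - 1L)
  out2 <- predictGraph(model, g)
  expect_identical(out, out2)

  # exactly tied class scores resolve to class 0
  C <- matrix(1, nNodes(g), nChannels(g))
  lin <- LinearGraphModel(list(C, C))
  expect_identical(predictGraph(lin, g)$predicted_class, 0L)
})

test_that("the forward pass names the stage that produced non-finite values", {
  g <- randomGraph(5, 3, seed = 2)
  model <- initGraphModel(smallConfig(seed = 2), channelNames(g))
  model@params$Win[1, 1] <- Inf
  expect_error(predictGraph(model, g), "node embedding")
  model2 <- initGraphModel(smallConfig(seed = 2), channelNames(g))
  model2@params$blk2_b[] <- NaN
  expect_error(predictGraph(model2, g), "attention block 2")
})

test_that("class scores are permutation invariant and node tensors equivariant", {
  for (seed in 1:4) {
    g <- randomGraph(8, 3, seed = seed)
    model <- initGraphModel(smallConfig(seed = seed), channelNames(g))
    set.seed(seed + 100)
    perm <- sample(nNodes(g))
    gp <- permuteGraph(g, perm)
    expect_equal(predictGraph(model, g)$class_scores,
                 predictGraph(model, gp)$class_scores, tolerance = 1e-12)
    E1 <- embedNodes(model, g)
    expect_equal(unname(embedNodes(model, gp)), unname(E1[perm, ]),
                 tolerance = 1e-12)
  }
})

test_that("information travels at most one hop per attention block", {
  # path graph: distance between the two ends exceeds n_blocks
  n <- 8
  g <- makeGraph(n, cbind(1:(n - 1), 2:n), k = 2)
  b <- 2L
  cfg <- smallConfig(n_blocks = b)
  model <- initGraphModel(cfg, channelNames(g))
  X2 <- features(g); X2[1, ] <- X2[1, ] + 5
  g2 <- makeGraph(n, cbind(1:(n - 1), 2:n), X = X2)
  mask <- graphSaliency:::.graphMask(g)
  H1 <- graphSaliency:::.forwardGraph(model@params, model@config,
                                      features(g), mask,
                                      cache = TRUE)$cache$Hfinal
  H2 <- graphSaliency:::.forwardGraph(model@params, model@config,
                                      features(g2), mask,
                                      cache = TRUE)$cache$Hfinal
  D <- bfsDistances(adjacency(g))
  far <- which(D[1, ] > b)
  near <- which(D[1, ] <= b)
  expect_identical(H1[far, ], H2[far, ])       # bitwise: no influence path
  expect_false(isTRUE(all.equal(H1[near, ], H2[near, ])))
})

test_that("analytic parameter gradients match central finite differences", {
  g <- randomGraph(6, 3, seed = 9)
  model <- initGraphModel(smallConfig(seed = 9, n_blocks = 2L),
                          channelNames(g))
  params <- model@params
  cfg <- model@config
  mask <- graphSaliency:::.graphMask(g)
  X <- features(g)
  lossAt <- function(p) {
    s <- graphSaliency:::.forwardGraph(p, cfg, X, mask)$scores
    -log(graphSaliency:::.softmaxVec(s)[2])
  }
  fw <- graphSaliency:::.forwardGraph(params, cfg, X, mask, cache = TRUE)
  probs <- graphSaliency:::.softmaxVec(fw$scores)
  ds <- probs; ds[2] <- ds[2] - 1
  bw <- graphSaliency:::.backwardGraph(params, cfg, fw$cache, ds)
  h <- 1e-5
  set.seed(1)
  for (nm in names(params)) {
    idx <- sample.int(length(params[[nm]]), min(3, length(params[[nm]])))
    for (ii in idx) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - h
      fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      expect_equal(bw$grads[[nm]][ii], fd, tolerance = 1e-4,
                   label = paste("grad", nm, ii))
    }
  }
})

test_that("training fits a separable synthetic cohort and is reproducible", {
  co <- generateCohort(tinyCohortConfig(seed = 21))
  cfg <- modelConfig(embed_dim = 8, n_blocks = 1, set2set_steps = 2,
                     fc_layers = 8, learning_rate = 1e-2, epochs = 60,
                     seed = 21)
  model <- trainModel(co$graphs, cfg)
  trace <- lossTrace(model)
  expect_length(trace, 60L)
  expect_lt(trace[60], trace[1])
  acc <- mean(vapply(co$graphs, function(g)
    predictGraph(model, g)$predicted_class == responseLabel(g), logical(1)))
  expect_identical(acc, 1)

  # bit-identical retrain under the same seed
  model2 <- trainModel(co$graphs, cfg)
  expect_identical(lossTrace(model2), trace)

  # zero learning rate freezes the parameters
  cfg0 <- modelConfig(embed_dim = 8, n_blocks = 1, set2set_steps = 2,
                      fc_layers = 8, learning_rate = 0, epochs = 5,
                      seed = 21)
  m0 <- trainModel(co$graphs[1:6], cfg0)
  expect_true(all(abs(diff(lossTrace(m0))) == 0))
})

test_that("training refuses a single-class dataset", {
  co <- generateCohort(tinyCohortConfig(seed = 21))
  pos <- Filter(function(g) responseLabel(g) == 1L, co$graphs)
  expect_error(trainModel(pos, smallConfig()), "both classes")
  expect_error(trainModel(list(), smallConfig()), "empty")
})
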