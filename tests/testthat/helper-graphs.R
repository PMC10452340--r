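# shared fixtures: all built in code, deterministic per seed

# small graph from an explicit edge list
makeGraph <- function(n, edges, X = NULL, k = 2, label = 0L, group = "g",
                      channels = paste0("ch", seq_len(if (is.null(X)) k
                                                      else ncol(X)))) {
  ids <- sprintf("N%02d", seq_len(n))
  if (is.null(X)) X <- matrix(seq_len(n * k) / (n * k), n, k)
  colnames(X) <- channels
  el <- if (length(edges)) cbind(ids[edges[, 1]], ids[edges[, 2]])
        else matrix(character(0), 0, 2)
  CellDrugGraph(ids, el, X, channels, label, group)
}

# random connected graph: spanning-tree chain plus extra random edges
randomGraph <- function(n = 6, k = 4, seed = 1, label = 1L, group = "g") {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1),
                             integer(1)))
  extra <- max(0L, n - 3L)
  if (extra > 0) {
    more <- t(replicate(extra, sort(sample.int(n, 2))))
    edges <- rbind(edges, more)
  }
  X <- matrix(rnorm(n * k), n, k)
  g <- makeGraph(n, edges, X, label = label, group = group)
  g
}

smallConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(embed_dim = 5L, n_blocks = 2L, set2set_steps = 2L,
                   fc_layers = 6L, seed = seed)
  do.call(modelConfig, utils::modifyList(defaults, args))
}

# apply a node permutation to a graph
permuteGraph <- function(g, perm) {
  CellDrugGraph(nodeIds(g)[perm], adjacency(g)[perm, perm, drop = FALSE],
                features(g)[perm, , drop = FALSE], channelNames(g),
                responseLabel(g), tissueGroup(g))
}

# independent finite-difference oracle for |dS_class/dX|
fdInputGradients <- function(model, g, classIndex, h = 1e-4) {
  X0 <- features(g)
  score <- function(X) {
    g2 <- CellDrugGraph(nodeIds(g), adjacency(g), X, channelNames(g),
                        responseLabel(g), tissueGroup(g))
    predictGraph(model, g2)$class_scores[classIndex + 1L]
  }
  fd <- X0 * 0
  for (i in seq_len(nrow(X0)))
    for (j in seq_len(ncol(X0))) {
      Xp <- X0; Xp[i, j] <- Xp[i, j] + h
      Xm <- X0; Xm[i, j] <- Xm[i, j] - h
      fd[i, j] <- (score(Xp) - score(Xm)) / (2 * h)
    }
  abs(fd)
}

# graph distance matrix by breadth-first search (test-local, no igraph)
bfsDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] > 0 & dist > dist[v] + 1)
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# tiny cohort configs used across tests (kept small for speed)
tinyCohortConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_nodes = 24L, attachment_m = 2L, n_kinases = 6L,
                   n_drivers = 2L, n_graphs_per_group = 10L,
                   groups = c("a", "b"), seed = seed)
  do.call(syntheticConfig, utils::modifyList(defaults, args))
}
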