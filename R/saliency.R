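# Channel-weighted gradient saliency.
#
# Pipeline: absolute input gradients of the class score (W, N x K) ->
# Gram matrix of channel columns (G = W'W) -> channel strengths
# (V = column means of G) -> IDF-style channel weights
# t_k = log((K*eps + sum_l v_l^r) / (eps + v_k^r)) -> node saliency M = W T.
# Strong channels (large aggregate gradient energy) are down-weighted,
# analogously to how inverse document frequency down-weights ubiquitous
# terms, so that informative but lower-magnitude channels still contribute
# to the node-level map.

#' Saliency configuration
#'
#' @param r power-scaling exponent applied to channel strengths (default 2).
#' @param epsilon small stabilizer added inside the log ratio
#'   (default 1e-8).
#' @return config list of class \code{saliencyConfig}.
#' @export
saliencyConfig <- function(r = 2, epsilon = 1e-8) {
  if (r <= 0) .vstop("r must be > 0")
  if (epsilon <= 0) .vstop("epsilon must be > 0")
  structure(list(r = as.numeric(r), epsilon = as.numeric(epsilon)),
            class = "saliencyConfig")
}

#' Gradient of the class score with respect to the node features
#'
#' Differentiates the pre-softmax score of one class through the full
#' forward pass (all attention blocks, readout and head), holding the
#' adjacency fixed, and returns per-node per-channel gradient magnitudes
#' (absolute values).
#'
#' @param model a \linkS4class{GraphModel} or \linkS4class{LinearGraphModel}.
#' @param graph a \linkS4class{CellDrugGraph}.
#' @param classIndex class (0 or 1) whose score is differentiated; defaults
#'   to the model's predicted class for this graph.
#' @return N x K matrix W of absolute gradients, with node/channel dimnames
#'   and attribute \code{class_index}.
#' @export
setGeneric("inputGradients", function(model, graph, classIndex = NULL)
  standardGeneric("inputGradients"))

#' @rdname inputGradients
#' @export
setMethod("inputGradients", signature("GraphModel", "CellDrugGraph"),
  function(model, graph, classIndex = NULL) {
    X <- graph@features
    fw <- .forwardGraph(model@params, model@config, X, .graphMask(graph),
                        cache = TRUE, checks = TRUE)
    classIndex <- .resolveClass(classIndex, fw$scores)
    dscores <- numeric(length(fw$scores))
    dscores[classIndex + 1L] <- 1
    bw <- .backwardGraph(model@params, model@config, fw$cache, dscores,
                         wantParams = FALSE, wantInput = TRUE)
    if (!all(is.finite(bw$dX)))
      stop("non-finite input gradient", call. = FALSE)
    W <- abs(bw$dX)
    dimnames(W) <- dimnames(X)
    attr(W, "class_index") <- classIndex
    W
  })

#' @rdname inputGradients
#' @export
setMethod("inputGradients", signature("LinearGraphModel", "CellDrugGraph"),
  function(model, graph, classIndex = NULL) {
    X <- graph@features
    scores <- vapply(model@coef, function(C) sum(C * X), numeric(1))
    classIndex <- .resolveClass(classIndex, scores)
    W <- abs(model@coef[[classIndex + 1L]])
    dimnames(W) <- dimnames(X)
    attr(W, "class_index") <- classIndex
    W
  })

#' @keywords internal
.resolveClass <- function(classIndex, scores) {
  if (is.null(classIndex))
    return(which.max(scores) - 1L)
  classIndex <- as.integer(classIndex)
  if (classIndex < 0L || classIndex >= length(scores))
    .vstop("classIndex out of range [0, ", length(scores) - 1L, "]")
  classIndex
}

#' Unweighted max-channel node saliency
#'
#' The image-style baseline: each node's saliency is the maximum gradient
#' magnitude across channels, ignoring channel importance.
#'
#' @param W N x K matrix of gradient magnitudes.
#' @return numeric length-N vector (named if W has rownames).
#' @export
unweightedNodeSaliency <- function(W) {
  W <- .checkW(W)
  stats::setNames(apply(W, 1L, max), rownames(W))
}

#' Gram matrix of channel saliency columns
#'
#' \code{G[k, l]} is the inner product between the saliency score columns of
#' channels k and l; it measures channel correlation and aggregate strength.
#' G is symmetric positive semidefinite by construction.
#'
#' @param W N x K matrix of gradient magnitudes.
#' @return K x K matrix.
#' @export
gramMatrix <- function(W) {
  W <- .checkW(W)
  crossprod(W)
}

#' Channel strengths
#'
#' Column-wise average of the Gram matrix: \code{V[k]} is the average
#' strength of channel k relative to the other channels.
#'
#' @param G K x K Gram matrix.
#' @return numeric length-K vector.
#' @export
channelStrengths <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    .vstop("G must be a square matrix")
  colMeans(G)
}

#' IDF-style channel weights
#'
#' \deqn{t_k = \log\frac{K\epsilon + \sum_l v_l^r}{\epsilon + v_k^r}}
#' with natural log: channels whose aggregate saliency strength dominates
#' are down-weighted, mirroring inverse document frequency. For K equal
#' channels every weight approaches \eqn{\log K}; a single channel gets
#' weight 0.
#'
#' @param V nonnegative channel strengths (length K).
#' @param config a \code{\link{saliencyConfig}} supplying the power-scaling
#'   exponent \code{r} and stabilizer \code{epsilon}.
#' @return numeric length-K weight vector T.
#' @export
channelWeights <- function(V, config = saliencyConfig()) {
  if (!is.numeric(V) || length(V) < 1L) .vstop("V must be nonempty numeric")
  if (any(V < 0))
    .vstop("channel strengths must be nonnegative ",
           "(gradient magnitudes cannot be negative)")
  K <- length(V)
  p <- V^config$r
  log((K * config$epsilon + sum(p)) / (config$epsilon + p))
}

#' Channel-weighted node saliency map
#'
#' The final map is the exact matrix product M = W T.
#'
#' @param W N x K gradient-magnitude matrix.
#' @param T length-K channel weight vector.
#' @return numeric length-N vector (named if W has rownames).
#' @export
nodeSaliency <- function(W, T) {
  W <- .checkW(W)
  if (ncol(W) != length(T))
    .vstop("length of T (", length(T), ") does not match K = ", ncol(W))
  stats::setNames(drop(W %*% T), rownames(W))
}

#' @keywords internal
.checkW <- function(W) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1L)
  if (nrow(W) == 0L || ncol(W) == 0L) .vstop("W must be nonempty")
  if (!all(is.finite(W))) .vstop("W must be finite")
  W
}

#' Explain a graph prediction
#'
#' End-to-end channel-weighted saliency: input gradients of the predicted
#' (or requested) class, Gram-matrix channel correlation, channel strengths,
#' IDF-style channel weights, and the final node saliency map. Fully
#' deterministic.
#'
#' @param model a \linkS4class{GraphModel} or \linkS4class{LinearGraphModel}.
#' @param graph a \linkS4class{CellDrugGraph}.
#' @param config a \code{\link{saliencyConfig}}.
#' @param classIndex class to differentiate; default: predicted class.
#' @return A \linkS4class{SaliencyExplanation}.
#' @examples
#' cfg <- syntheticConfig(n_nodes = 30, n_graphs_per_group = 6,
#'                        groups = "t1", seed = 7)
#' cohort <- generateCohort(cfg)
#' model <- trainModel(cohort$graphs,
#'                     modelConfig(embed_dim = 8, n_blocks = 2,
#'                                 set2set_steps = 2, fc_layers = 8,
#'                                 epochs = 10))
#' explainGraph(model, cohort$graphs[[1]])
#' @export
explainGraph <- function(model, graph, config = saliencyConfig(),
                         classIndex = NULL) {
  W <- inputGradients(model, graph, classIndex)
  G <- gramMatrix(W)
  V <- channelStrengths(G)
  T <- channelWeights(V, config)
  M <- nodeSaliency(W, T)
  cls <- attr(W, "class_index")
  attr(W, "class_index") <- NULL
  new("SaliencyExplanation", W = W, G = G, V = unname(V), T = unname(T),
      M = unname(M), classIndex = cls,
      nodeIds = nodeIds(graph), channelNames = channelNames(graph))
}

# ---------------------------------------------------------------------------
# aggregation across graphs and groups
# ---------------------------------------------------------------------------

#' Aggregate node saliency maps per group
#'
#' Each map is scaled to [0, 1] by dividing by its maximum (an all-zero map
#' stays zero), then maps are averaged within each group. Rankings derived
#' from the report are descending by score with lexicographic node-id
#' tie-breaking.
#'
#' @param maps list of node saliency maps: \linkS4class{SaliencyExplanation}
#'   objects or named numeric vectors. All maps must share node ids.
#' @param groups character vector of group tags, one per map.
#' @param normalize divide each map by its maximum before averaging
#'   (default TRUE).
#' @return An \linkS4class{ImportanceReport}.
#' @export
aggregateImportance <- function(maps, groups, normalize = TRUE) {
  if (length(maps) == 0L) .vstop("no maps supplied")
  if (length(groups) != length(maps))
    .vstop("groups must tag each map")
  vecs <- lapply(maps, function(m) {
    if (is(m, "SaliencyExplanation")) nodeSaliencyMap(m)
    else if (is.numeric(m) && !is.null(names(m))) m
    else .vstop("maps must be SaliencyExplanation or named numeric vectors")
  })
  ids <- names(vecs[[1L]])
  ok <- vapply(vecs, function(v) identical(names(v), ids), logical(1))
  if (!all(ok)) .vstop("all maps must share the same node ids")
  if (normalize)
    vecs <- lapply(vecs, function(v) {
      mx <- max(v)
      if (mx > 0) v / mx else v
    })
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(sort(unique(groups)), function(gp) {
    sel <- vecs[groups == gp]
    if (length(sel) == 0L) .vstop("empty group: ", gp)
    avg <- Reduce(`+`, sel) / length(sel)
    data.frame(group = gp, node_id = ids, score = unname(avg),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  new("ImportanceReport", scores = out)
}

#' Top-ranked nodes per group
#'
#' @param report an \linkS4class{ImportanceReport}.
#' @param k number of nodes per group (clamped to the number available).
#' @return data.frame (group, rank, node_id, score), groups in sorted order,
#'   within group descending by score, ties lexicographic by node id.
#' @export
topRanked <- function(report, k = 5L) {
  if (k <= 0L) .vstop("k must be positive")
  df <- report@scores
  out <- do.call(rbind, lapply(split(df, df$group), function(d) {
    d <- d[order(-d$score, d$node_id), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d[, c("group", "rank", "node_id", "score")]
  }))
  rownames(out) <- NULL
  out
}

#' Per-cancer-type kinase importance for a cohort
#'
#' The full importance workflow: explain every graph, keep the graphs the
#' model predicts responsive (class 1), aggregate the saliency maps per
#' group (\code{\link{aggregateImportance}}), and optionally restrict to
#' kinase nodes. Restricting to predicted-responsive graphs matters:
#' in predicted-ineffective graphs the class-0 gradient highlights the
#' kinases whose activation \emph{would have made} the drug work —
#' counterfactual saliency that is informative per graph but dilutes a
#' per-cancer-type ranking of actual response drivers.
#'
#' @param model a trained \linkS4class{GraphModel}.
#' @param graphs list of \linkS4class{CellDrugGraph}.
#' @param config a \code{\link{saliencyConfig}}.
#' @param responsiveOnly aggregate only graphs predicted responsive
#'   (default TRUE; groups with no responsive prediction fall back to all
#'   of their graphs).
#' @param kinaseIds optional node subset to restrict the report to.
#' @param weighted use the channel-weighted map (default); FALSE gives the
#'   unweighted max-channel baseline.
#' @return An \linkS4class{ImportanceReport}.
#' @export
cohortImportance <- function(model, graphs, config = saliencyConfig(),
                             responsiveOnly = TRUE, kinaseIds = NULL,
                             weighted = TRUE) {
  if (length(graphs) == 0L) .vstop("no graphs supplied")
  ex <- lapply(graphs, explainGraph, model = model, config = config)
  maps <- if (weighted) lapply(ex, nodeSaliencyMap)
          else lapply(ex, function(e)
            unweightedNodeSaliency(saliencyScores(e)))
  grp <- vapply(graphs, tissueGroup, character(1))
  keep <- rep(TRUE, length(graphs))
  if (responsiveOnly) {
    pred <- vapply(ex, function(e) e@classIndex, integer(1))
    keep <- pred == 1L
    # a group in which no graph is predicted responsive keeps all graphs
    for (gp in unique(grp))
      if (!any(keep & grp == gp)) keep[grp == gp] <- TRUE
  }
  rep <- aggregateImportance(maps[keep], grp[keep])
  if (!is.null(kinaseIds)) rep <- restrictToKinases(rep, kinaseIds)
  rep
}

#' Restrict an importance report to kinase nodes
#'
#' Filters the report to the given node set; scores are unchanged and
#' rankings are recomputed on the restricted set.
#'
#' @param report an \linkS4class{ImportanceReport}.
#' @param kinaseIds character vector of node ids to keep.
#' @return A filtered \linkS4class{ImportanceReport}.
#' @export
restrictToKinases <- function(report, kinaseIds) {
  df <- report@scores
  keep <- df$node_id %in% kinaseIds
  if (!any(keep))
    .vstop("no report nodes in the supplied kinase set")
  new("ImportanceReport", scores = df[keep, , drop = FALSE])
}
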