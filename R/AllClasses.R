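#' @import methods
NULL

# ---------------------------------------------------------------------------
# CellDrugGraph: one cell-line--drug instance
# ---------------------------------------------------------------------------

#' CellDrugGraph: a multi-channel graph instance
#'
#' Container for a single cell-line--drug graph: a shared undirected topology
#' over N nodes (typically genes on a protein--protein interaction network),
#' an N x K node-feature matrix whose columns are data channels (e.g. gene
#' expression, kinase flag, drug binding affinity, disease association), a
#' binary response label, and a categorical group tag (typically the tissue
#' of origin of the cell line).
#'
#' @slot nodeIds character vector of unique, stable node identifiers.
#' @slot adjacency symmetric 0/1 numeric matrix with zero diagonal.
#' @slot features numeric N x K matrix, one row per node, one column per
#'   channel; must be finite.
#' @slot channelNames character vector of K unique channel names.
#' @slot label integer, 0 or 1 (drug response class).
#' @slot group character scalar tissue/group tag.
#'
#' @aliases CellDrugGraph-class
#' @exportClass CellDrugGraph
setClass("CellDrugGraph",
  representation(
    nodeIds      = "character",
    adjacency    = "matrix",
    features     = "matrix",
    channelNames = "character",
    label        = "integer",
    group        = "character"
  )
)

setValidity("CellDrugGraph", function(object) {
  msg <- character(0)
  n <- length(object@nodeIds)
  A <- object@adjacency
  X <- object@features
  if (anyDuplicated(object@nodeIds))
    msg <- c(msg, "nodeIds must be unique")
  if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency must be an n x n numeric matrix")
  else {
    if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0))
      msg <- c(msg, "adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1)))
      msg <- c(msg, "adjacency entries must be 0/1")
  }
  if (!is.numeric(X) || nrow(X) != n)
    msg <- c(msg, "features must have one row per node")
  if (!all(is.finite(X)))
    msg <- c(msg, "features must be finite")
  k <- length(object@channelNames)
  if (k < 2)
    msg <- c(msg, "at least 2 channels are required")
  if (ncol(X) != k)
    msg <- c(msg, "features must have one column per channel")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(object@label) != 1L || !(object@label %in% c(0L, 1L)))
    msg <- c(msg, "label must be a single 0/1 integer")
  if (length(object@group) != 1L)
    msg <- c(msg, "group must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CellDrugGraph
#'
#' @param nodeIds character vector of node identifiers.
#' @param adjacency symmetric 0/1 matrix (zero diagonal) or a 2-column
#'   edge matrix/data.frame of node ids (undirected; expanded internally).
#' @param features numeric matrix (nodes x channels).
#' @param channelNames channel names; defaults to \code{colnames(features)}.
#' @param label response class, 0 or 1.
#' @param group tissue/group tag.
#' @return A validated \linkS4class{CellDrugGraph}.
#' @examples
#' g <- CellDrugGraph(
#'   nodeIds   = c("A", "B", "C"),
#'   adjacency = rbind(c("A", "B"), c("B", "C")),
#'   features  = matrix(rnorm(6), 3, 2,
#'                      dimnames = list(NULL, c("expression", "affinity"))),
#'   label = 1, group = "breast")
#' nNodes(g)
#' @export
CellDrugGraph <- function(nodeIds, adjacency, features,
                          channelNames = colnames(features),
                          label = 0L, group = "all") {
  nodeIds <- as.character(nodeIds)
  n <- length(nodeIds)
  if (!is.matrix(adjacency) || ncol(adjacency) != n || nrow(adjacency) != n ||
      !is.numeric(adjacency)) {
    # edge-list form
    el <- as.matrix(adjacency)
    if (ncol(el) != 2L)
      .vstop("adjacency must be an n x n matrix or a 2-column edge list")
    A <- matrix(0, n, n, dimnames = list(nodeIds, nodeIds))
    if (nrow(el) > 0) {
      i <- match(el[, 1L], nodeIds)
      j <- match(el[, 2L], nodeIds)
      if (anyNA(i) || anyNA(j))
        .vstop("edge list references unknown node id: ",
               paste(unique(c(el[, 1L][is.na(i)], el[, 2L][is.na(j)])),
                     collapse = ", "))
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
    }
    diag(A) <- 0
    adjacency <- A
  }
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  storage.mode(adjacency) <- "double"
  if (is.null(channelNames))
    channelNames <- paste0("channel", seq_len(ncol(features)))
  dimnames(adjacency) <- list(nodeIds, nodeIds)
  dimnames(features) <- list(nodeIds, channelNames)
  new("CellDrugGraph", nodeIds = nodeIds, adjacency = adjacency,
      features = features, channelNames = as.character(channelNames),
      label = as.integer(label), group = as.character(group))
}

# ---------------------------------------------------------------------------
# GraphModel: reference attention-propagation classifier
# ---------------------------------------------------------------------------

#' GraphModel: attention-propagation graph classifier
#'
#' Holds the parameters and configuration of the reference classifier:
#' a linear node embedding, \code{n_blocks} attention-propagation blocks,
#' a Set2Set readout and a fully connected head ending in two class scores.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config a \code{\link{modelConfig}} list.
#' @slot channelNames channel names the model was dimensioned for; fixes the
#'   channel ordering at explain time.
#' @slot lossTrace numeric vector of per-epoch training losses (empty for an
#'   untrained model).
#' @slot formatVersion serialization format version string.
#'
#' @aliases GraphModel-class
#' @exportClass GraphModel
setClass("GraphModel",
  representation(
    params        = "list",
    config        = "list",
    channelNames  = "character",
    lossTrace     = "numeric",
    formatVersion = "character"
  )
)

# ---------------------------------------------------------------------------
# LinearGraphModel: analytic surrogate for closed-form saliency checks
# ---------------------------------------------------------------------------

#' LinearGraphModel: analytically differentiable surrogate classifier
#'
#' A model whose class-c score is the elementwise inner product
#' S_c = sum_{i,k} C_c[i,k] * X[i,k] between a fixed coefficient matrix and
#' the node-feature matrix. Its input gradient is available in closed form
#' (dS_c/dX = C_c), which makes it the natural surrogate for verifying the
#' saliency pipeline end to end.
#'
#' @slot coef list of per-class coefficient matrices (N x K), one per class.
#'
#' @aliases LinearGraphModel-class
#' @exportClass LinearGraphModel
setClass("LinearGraphModel", representation(coef = "list"))

setValidity("LinearGraphModel", function(object) {
  if (length(object@coef) < 2L)
    return("need one coefficient matrix per class (>= 2 classes)")
  d <- dim(object@coef[[1L]])
  ok <- vapply(object@coef, function(m)
    is.matrix(m) && is.numeric(m) && identical(dim(m), d), logical(1))
  if (!all(ok)) return("coefficient matrices must share dimensions")
  TRUE
})

#' @param coef list of per-class N x K coefficient matrices.
#' @return A \linkS4class{LinearGraphModel}.
#' @rdname LinearGraphModel-class
#' @export
LinearGraphModel <- function(coef) new("LinearGraphModel", coef = coef)

# ---------------------------------------------------------------------------
# SaliencyExplanation: full output of the channel-weighted saliency pipeline
# ---------------------------------------------------------------------------

#' SaliencyExplanation: channel-weighted saliency of one graph
#'
#' Result of \code{\link{explainGraph}}: the per-node per-channel gradient
#' magnitudes W, the Gram matrix G of channel correlations, the channel
#' strengths V (column means of G), the IDF-style channel weights T, and the
#' final node saliency map M = W T.
#'
#' @slot W numeric N x K matrix of absolute input gradients.
#' @slot G numeric K x K Gram matrix.
#' @slot V numeric length-K channel strengths.
#' @slot T numeric length-K channel weights.
#' @slot M numeric length-N node saliency map.
#' @slot classIndex integer class whose score was differentiated (0-based).
#' @slot nodeIds,channelNames identifiers carried through from the graph.
#'
#' @aliases SaliencyExplanation-class
#' @exportClass SaliencyExplanation
setClass("SaliencyExplanation",
  representation(
    W = "matrix", G = "matrix", V = "numeric", T = "numeric", M = "numeric",
    classIndex = "integer", nodeIds = "character", channelNames = "character"
  )
)

# ---------------------------------------------------------------------------
# ImportanceReport: per-group aggregated node importance
# ---------------------------------------------------------------------------

#' ImportanceReport: per-group node importance ranking
#'
#' Aggregation of node saliency maps over groups (e.g. cancer types): each
#' map is scaled to [0, 1] by its maximum and maps within a group are
#' averaged. Rankings are descending by score with lexicographic node-id
#' tie-breaking.
#'
#' @slot scores data.frame with columns \code{group}, \code{node_id},
#'   \code{score} (score in [0, 1]).
#'
#' @aliases ImportanceReport-class
#' @exportClass ImportanceReport
setClass("ImportanceReport", representation(scores = "data.frame"))

setValidity("ImportanceReport", function(object) {
  df <- object@scores
  if (!all(c("group", "node_id", "score") %in% names(df)))
    return("scores needs columns group, node_id, score")
  if (nrow(df) && (any(df$score < -1e-12) || any(df$score > 1 + 1e-12)))
    return("scores must lie in [0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("responseLabel", function(x) standardGeneric("responseLabel"))
#' @export
setGeneric("tissueGroup", function(x) standardGeneric("tissueGroup"))
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @export
setGeneric("nodeSaliencyMap", function(x) standardGeneric("nodeSaliencyMap"))
#' @export
setGeneric("saliencyScores", function(x) standardGeneric("saliencyScores"))
#' @export
setGeneric("channelWeightVector",
           function(x) standardGeneric("channelWeightVector"))
#' @export
setGeneric("importanceScores",
           function(x) standardGeneric("importanceScores"))

#' @describeIn CellDrugGraph-class node identifiers.
#' @param x object.
#' @export
setMethod("nodeIds", "CellDrugGraph", function(x) x@nodeIds)
#' @describeIn CellDrugGraph-class adjacency matrix.
#' @export
setMethod("adjacency", "CellDrugGraph", function(x) x@adjacency)
#' @describeIn CellDrugGraph-class node-feature matrix.
#' @export
setMethod("features", "CellDrugGraph", function(x) x@features)
#' @describeIn CellDrugGraph-class channel names.
#' @export
setMethod("channelNames", "CellDrugGraph", function(x) x@channelNames)
#' @describeIn CellDrugGraph-class binary response label.
#' @export
setMethod("responseLabel", "CellDrugGraph", function(x) x@label)
#' @describeIn CellDrugGraph-class tissue/group tag.
#' @export
setMethod("tissueGroup", "CellDrugGraph", function(x) x@group)
#' @describeIn CellDrugGraph-class number of nodes.
#' @export
setMethod("nNodes", "CellDrugGraph", function(x) length(x@nodeIds))
#' @describeIn CellDrugGraph-class number of channels.
#' @export
setMethod("nChannels", "CellDrugGraph", function(x) length(x@channelNames))

#' @describeIn GraphModel-class per-epoch training loss trace.
#' @param x object.
#' @export
setMethod("lossTrace", "GraphModel", function(x) x@lossTrace)
#' @describeIn GraphModel-class channel names the model expects.
#' @export
setMethod("channelNames", "GraphModel", function(x) x@channelNames)

#' @describeIn SaliencyExplanation-class final node saliency map M.
#' @param x object.
#' @export
setMethod("nodeSaliencyMap", "SaliencyExplanation", function(x) {
  stats::setNames(x@M, x@nodeIds)
})
#' @describeIn SaliencyExplanation-class gradient-magnitude matrix W.
#' @export
setMethod("saliencyScores", "SaliencyExplanation", function(x) x@W)
#' @describeIn SaliencyExplanation-class channel weight vector T.
#' @export
setMethod("channelWeightVector", "SaliencyExplanation", function(x) {
  stats::setNames(x@T, x@channelNames)
})

#' @describeIn ImportanceReport-class score table (group, node_id, score).
#' @param x object.
#' @export
setMethod("importanceScores", "ImportanceReport", function(x) x@scores)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "CellDrugGraph", function(object) {
  cat("CellDrugGraph:", length(object@nodeIds), "nodes,",
      sum(object@adjacency) / 2, "edges,",
      length(object@channelNames), "channels\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat("  label:", object@label, " group:", object@group, "\n")
})

setMethod("show", "GraphModel", function(object) {
  cfg <- object@config
  cat("GraphModel: embed_dim", cfg$embed_dim, "| blocks", cfg$n_blocks,
      "| set2set steps", cfg$set2set_steps,
      "| fc [", paste(cfg$fc_layers, collapse = ", "), "]\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (length(object@lossTrace))
    cat("  trained:", length(object@lossTrace), "epochs, final loss",
        signif(utils::tail(object@lossTrace, 1), 4), "\n")
  else cat("  untrained (random initialization)\n")
})

setMethod("show", "SaliencyExplanation", function(object) {
  cat("SaliencyExplanation:", length(object@M), "nodes,",
      length(object@T), "channels (class", object@classIndex, ")\n")
  cat("  channel weights:",
      paste(sprintf("%s=%.4g", object@channelNames, object@T),
            collapse = ", "), "\n")
  top <- order(-object@M, object@nodeIds)[seq_len(min(5, length(object@M)))]
  cat("  top nodes:",
      paste(sprintf("%s (%.4g)", object@nodeIds[top], object@M[top]),
            collapse = ", "), "\n")
})

setMethod("show", "ImportanceReport", function(object) {
  df <- object@scores
  cat("ImportanceReport:", length(unique(df$group)), "group(s),",
      length(unique(df$node_id)), "nodes\n")
})
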