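# Reference attention-propagation classifier.
#
# Architecture: linear per-node embedding -> n_blocks GAT-style attention
# propagation blocks (neighbourhood softmax over self + neighbours,
# LeakyReLU scoring, ELU update) -> Set2Set readout (attention over nodes
# driven by a tanh recurrence on the query, output length 2D) -> fully
# connected head with ELU hidden layers and a linear 2-class output.
# LeakyReLU/ELU keep class-score gradients crisp on converged models, which
# matters because input gradients are the attribution signal.
#
# The forward pass caches every intermediate so that reverse-mode gradients
# with respect to both the parameters (training) and the node features
# (saliency) are computed analytically; finite differences serve as an
# independent oracle in the test suite.

#' Model configuration
#'
#' @param embed_dim node embedding dimension D.
#' @param n_blocks number of attention-propagation iterations; information
#'   travels at most \code{n_blocks} hops.
#' @param set2set_steps processing steps of the Set2Set readout.
#' @param fc_layers integer vector of hidden widths of the fully connected
#'   head (the final 2-class layer is implicit).
#' @param n_classes number of classes; fixed at 2.
#' @param seed integer seed for parameter initialization.
#' @param learning_rate Adam step size used by \code{\link{trainModel}}.
#' @param epochs number of full-batch training epochs.
#' @return A validated config list of class \code{modelConfig}.
#' @export
modelConfig <- function(embed_dim = 32L, n_blocks = 5L, set2set_steps = 3L,
                        fc_layers = c(64L, 16L), n_classes = 2L, seed = 1L,
                        learning_rate = 1e-3, epochs = 200L) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              n_blocks = as.integer(n_blocks),
              set2set_steps = as.integer(set2set_steps),
              fc_layers = as.integer(fc_layers),
              n_classes = as.integer(n_classes),
              seed = as.integer(seed),
              learning_rate = as.numeric(learning_rate),
              epochs = as.integer(epochs))
  dims <- c(cfg$embed_dim, cfg$n_blocks, cfg$set2set_steps, cfg$fc_layers,
            cfg$epochs)
  if (any(dims <= 0L))
    .vstop("all model dimensions and epoch counts must be positive")
  if (cfg$n_classes != 2L)
    .vstop("only binary classification (n_classes = 2) is supported")
  if (cfg$learning_rate < 0) .vstop("learning_rate must be >= 0")
  class(cfg) <- "modelConfig"
  cfg
}

# parameter names for a given config
#' @keywords internal
.paramTemplate <- function(cfg, K) {
  D <- cfg$embed_dim
  widths <- c(2L * D, cfg$fc_layers, cfg$n_classes)
  shapes <- list(Win = c(K, D), bin = D)
  for (t in seq_len(cfg$n_blocks)) {
    shapes[[paste0("blk", t, "_W")]]  <- c(D, D)
    shapes[[paste0("blk", t, "_as")]] <- D
    shapes[[paste0("blk", t, "_ad")]] <- D
    shapes[[paste0("blk", t, "_b")]]  <- D
  }
  shapes$s2s_Wq <- c(2L * D, D)
  shapes$s2s_bq <- D
  for (l in seq_len(length(widths) - 1L)) {
    shapes[[paste0("fc", l, "_W")]] <- c(widths[l], widths[l + 1L])
    shapes[[paste0("fc", l, "_b")]] <- widths[l + 1L]
  }
  shapes
}

#' Initialize an untrained GraphModel
#'
#' Weights are drawn from centred normals with sd 1/sqrt(fan-in)
#' (Glorot-style); biases start at zero. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param channelNames channel names the model is dimensioned for (fixes K
#'   and the expected feature-column order).
#' @return A \linkS4class{GraphModel}.
#' @export
initGraphModel <- function(config, channelNames) {
  stopifnot(inherits(config, "modelConfig"))
  K <- length(channelNames)
  if (K < 2L) .vstop("at least 2 channels are required")
  shapes <- .paramTemplate(config, K)
  set.seed(config$seed)
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (length(sh) == 2L) {
      if (grepl("_b$|^bin$|_bq$", nm)) # never happens; matrices are weights
        return(matrix(0, sh[1], sh[2]))
      matrix(stats::rnorm(prod(sh), sd = sqrt(1 / sh[1])), sh[1], sh[2])
    } else {
      if (grepl("_as$|_ad$", nm))
        stats::rnorm(sh, sd = sqrt(1 / sh))
      else numeric(sh)                 # biases start at zero
    }
  })
  names(params) <- names(shapes)
  new("GraphModel", params = params, config = unclass(config),
      channelNames = as.character(channelNames), lossTrace = numeric(0),
      formatVersion = "1.0")
}

# neighbourhood mask: self + neighbours
#' @keywords internal
.graphMask <- function(graph) {
  A <- graph@adjacency
  (A + diag(nrow(A))) > 0
}

# full forward pass; with cache = TRUE returns all intermediates needed by
# .backwardGraph
#' @keywords internal
.forwardGraph <- function(params, cfg, X, mask, cache = FALSE,
                          checks = FALSE) {
  N <- nrow(X)
  D <- cfg$embed_dim
  B <- cfg$n_blocks
  S <- cfg$set2set_steps

  if (ncol(X) != nrow(params$Win))
    .vstop("feature dimension K = ", ncol(X),
           " does not match model input dimension ", nrow(params$Win))

  H <- X %*% params$Win + rep(params$bin, each = N)
  if (checks) .assertFinite(H, "node embedding")
  blockCache <- if (cache) vector("list", B)
  maskAdd <- .maskAdd(mask)

  for (t in seq_len(B)) {
    W  <- params[[paste0("blk", t, "_W")]]
    as_ <- params[[paste0("blk", t, "_as")]]
    ad_ <- params[[paste0("blk", t, "_ad")]]
    b  <- params[[paste0("blk", t, "_b")]]
    Z  <- H %*% W
    s  <- drop(Z %*% as_)
    d  <- drop(Z %*% ad_)
    Et <- .lrelu(matrix(s, N, N) + rep(d, each = N)) # score(i,j): s_i + d_j
    Alpha <- .rowSoftmax(Et + maskAdd)
    Hn <- .elu(Alpha %*% Z + rep(b, each = N))
    if (checks) .assertFinite(Hn, paste0("attention block ", t))
    if (cache)
      blockCache[[t]] <- list(Hin = H, Z = Z, Et = Et, Alpha = Alpha,
                              Hout = Hn)
    H <- Hn
  }

  qstar <- numeric(2L * D)
  stepCache <- if (cache) vector("list", S)
  for (s2 in seq_len(S)) {
    q <- tanh(drop(qstar %*% params$s2s_Wq) + params$s2s_bq)
    e <- drop(H %*% q)
    a <- .softmaxVec(e)
    r <- drop(crossprod(H, a))
    if (cache)
      stepCache[[s2]] <- list(qstar_prev = qstar, q = q, a = a)
    qstar <- c(q, r)
  }
  if (checks) .assertFinite(qstar, "set2set readout")

  L <- length(cfg$fc_layers) + 1L
  h <- qstar
  fcH <- if (cache) vector("list", L + 1L)
  if (cache) fcH[[1L]] <- h
  for (l in seq_len(L)) {
    z <- drop(h %*% params[[paste0("fc", l, "_W")]]) +
      params[[paste0("fc", l, "_b")]]
    h <- if (l < L) .elu(z) else z
    if (cache) fcH[[l + 1L]] <- h
  }
  if (checks) .assertFinite(h, "fully connected head")

  scores <- h
  if (!cache) return(list(scores = scores))
  list(scores = scores,
       cache = list(X = X, mask = mask, blocks = blockCache,
                    steps = stepCache, Hfinal = H, fcH = fcH, N = N, D = D))
}

# reverse-mode gradients of sum(dscores * scores) w.r.t. parameters and/or
# the input feature matrix
#' @keywords internal
.backwardGraph <- function(params, cfg, cc, dscores,
                           wantParams = TRUE, wantInput = FALSE) {
  N <- cc$N; D <- cc$D
  B <- cfg$n_blocks
  S <- cfg$set2set_steps
  L <- length(cfg$fc_layers) + 1L
  g <- if (wantParams) list()

  # fully connected head
  dh <- dscores
  for (l in rev(seq_len(L))) {
    hin  <- cc$fcH[[l]]
    hout <- cc$fcH[[l + 1L]]
    dz <- if (l < L) dh * .eluGradFromOut(hout) else dh
    if (wantParams) {
      g[[paste0("fc", l, "_W")]] <- tcrossprod(hin, dz)
      g[[paste0("fc", l, "_b")]] <- dz
    }
    dh <- drop(params[[paste0("fc", l, "_W")]] %*% dz)
  }

  # set2set readout
  H <- cc$Hfinal
  dH <- matrix(0, N, D)
  dqstar <- dh
  Wq <- params$s2s_Wq
  if (wantParams) {
    g$s2s_Wq <- matrix(0, 2L * D, D)
    g$s2s_bq <- numeric(D)
  }
  for (s2 in rev(seq_len(S))) {
    st <- cc$steps[[s2]]
    q <- st$q; a <- st$a
    dq <- dqstar[seq_len(D)]
    dr <- dqstar[D + seq_len(D)]
    da <- drop(H %*% dr)
    dH <- dH + tcrossprod(a, dr)
    de <- a * (da - sum(a * da))
    dH <- dH + tcrossprod(de, q)
    dq <- dq + drop(crossprod(H, de))
    dpre <- dq * (1 - q^2)
    if (wantParams) {
      g$s2s_Wq <- g$s2s_Wq + tcrossprod(st$qstar_prev, dpre)
      g$s2s_bq <- g$s2s_bq + dpre
    }
    dqstar <- drop(Wq %*% dpre)
  }

  # attention blocks
  for (t in rev(seq_len(B))) {
    bc <- cc$blocks[[t]]
    W   <- params[[paste0("blk", t, "_W")]]
    as_ <- params[[paste0("blk", t, "_as")]]
    ad_ <- params[[paste0("blk", t, "_ad")]]
    dP <- dH * .eluGradFromOut(bc$Hout)
    dZ <- crossprod(bc$Alpha, dP)
    dAlpha <- tcrossprod(dP, bc$Z)
    rs <- rowSums(bc$Alpha * dAlpha)
    dEt <- bc$Alpha * (dAlpha - rs)     # rs recycles down columns: row shift
    dEraw <- dEt * .lreluGradFromOut(bc$Et)
    ds <- rowSums(dEraw)
    dd <- colSums(dEraw)
    dZ <- dZ + tcrossprod(ds, as_) + tcrossprod(dd, ad_)
    if (wantParams) {
      g[[paste0("blk", t, "_b")]]  <- colSums(dP)
      g[[paste0("blk", t, "_as")]] <- drop(crossprod(bc$Z, ds))
      g[[paste0("blk", t, "_ad")]] <- drop(crossprod(bc$Z, dd))
      g[[paste0("blk", t, "_W")]]  <- crossprod(bc$Hin, dZ)
    }
    dH <- tcrossprod(dZ, W)
  }

  # linear embedding
  out <- list()
  if (wantParams) {
    g$Win <- crossprod(cc$X, dH)
    g$bin <- colSums(dH)
    out$grads <- g
  }
  if (wantInput)
    out$dX <- tcrossprod(dH, params$Win)
  out
}

# ---------------------------------------------------------------------------
# exported stage-level operations
# ---------------------------------------------------------------------------

#' Per-node linear embedding
#'
#' Maps each node's K-channel feature row to a D-dimensional embedding with
#' the model's input layer. Depends only on the node's own features;
#' topology enters through the subsequent attention blocks.
#'
#' @param model a \linkS4class{GraphModel}.
#' @param graph a \linkS4class{CellDrugGraph}.
#' @return N x D embedding matrix.
#' @export
embedNodes <- function(model, graph) {
  X <- graph@features
  if (ncol(X) != nrow(model@params$Win))
    .vstop("graph has ", ncol(X), " channels but model expects ",
           nrow(model@params$Win))
  X %*% model@params$Win + rep(model@params$bin, each = nrow(X))
}

#' One attention-propagation block
#'
#' Updates node embeddings by aggregating each node's neighbourhood
#' (self-loop added internally; the stored adjacency keeps a zero diagonal)
#' with softmax-normalized attention coefficients.
#'
#' @param model a \linkS4class{GraphModel}.
#' @param graph a \linkS4class{CellDrugGraph} supplying the topology.
#' @param embeddings N x D matrix of current node embeddings.
#' @param block which block's parameters to use (1-based).
#' @return N x D updated embedding matrix.
#' @export
attentionBlock <- function(model, graph, embeddings, block = 1L) {
  N <- nNodes(graph)
  D <- model@config$embed_dim
  if (!is.matrix(embeddings) || nrow(embeddings) != N ||
      ncol(embeddings) != D)
    .vstop("embeddings must be an N x D matrix conforming to graph/model")
  if (block < 1L || block > model@config$n_blocks)
    .vstop("block index out of range")
  W   <- model@params[[paste0("blk", block, "_W")]]
  as_ <- model@params[[paste0("blk", block, "_as")]]
  ad_ <- model@params[[paste0("blk", block, "_ad")]]
  b   <- model@params[[paste0("blk", block, "_b")]]
  mask <- .graphMask(graph)
  Z <- embeddings %*% W
  Et <- .lrelu(outer(drop(Z %*% as_), drop(Z %*% ad_), "+"))
  Alpha <- .rowSoftmaxMasked(Et, mask)
  .elu(Alpha %*% Z + rep(b, each = N))
}

#' Set2Set graph readout
#'
#' Permutation-invariant attention readout over node embeddings: a
#' recurrently updated query attends over the node set for a fixed number of
#' processing steps; the output concatenates the final query and read
#' vectors (length 2D).
#'
#' @param model a \linkS4class{GraphModel}.
#' @param embeddings N x D node embedding matrix, N >= 1.
#' @param steps number of processing steps.
#' @return numeric vector of length 2D.
#' @export
set2setReadout <- function(model, embeddings,
                           steps = model@config$set2set_steps) {
  if (!is.matrix(embeddings) || nrow(embeddings) < 1L)
    .vstop("embeddings must be a matrix with at least one row")
  D <- model@config$embed_dim
  if (ncol(embeddings) != D) .vstop("embeddings must have D columns")
  qstar <- numeric(2L * D)
  for (s2 in seq_len(steps)) {
    q <- tanh(drop(qstar %*% model@params$s2s_Wq) + model@params$s2s_bq)
    a <- .softmaxVec(drop(embeddings %*% q))
    qstar <- c(q, drop(crossprod(embeddings, a)))
  }
  qstar
}

# ---------------------------------------------------------------------------
# prediction
# ---------------------------------------------------------------------------

#' Predict the response class of a graph
#'
#' Runs the full forward pass (embedding, attention propagation, Set2Set
#' readout, fully connected head). Deterministic: repeated calls agree
#' bit-for-bit.
#'
#' @param model a \linkS4class{GraphModel} or \linkS4class{LinearGraphModel}.
#' @param graph a \linkS4class{CellDrugGraph}.
#' @return list with \code{class_scores} (length-2 pre-softmax scores),
#'   \code{class_probs} (softmax, sums to 1), and \code{predicted_class}
#'   (0 or 1; ties resolve to 0).
#' @export
setGeneric("predictGraph",
           function(model, graph) standardGeneric("predictGraph"))

#' @rdname predictGraph
#' @export
setMethod("predictGraph", signature("GraphModel", "CellDrugGraph"),
  function(model, graph) {
    if (!identical(channelNames(graph), model@channelNames))
      .vstop("graph channels (", paste(channelNames(graph), collapse = ","),
             ") do not match model channels (",
             paste(model@channelNames, collapse = ","), ")")
    fw <- .forwardGraph(model@params, model@config, graph@features,
                        .graphMask(graph), checks = TRUE)
    .modelOutput(fw$scores)
  })

#' @rdname predictGraph
#' @export
setMethod("predictGraph", signature("LinearGraphModel", "CellDrugGraph"),
  function(model, graph) {
    X <- graph@features
    scores <- vapply(model@coef, function(C) {
      if (!identical(dim(C), dim(X)))
        .vstop("coefficient matrix does not conform to graph features")
      sum(C * X)
    }, numeric(1))
    .modelOutput(scores)
  })

#' @keywords internal
.modelOutput <- function(scores) {
  probs <- .softmaxVec(scores)
  list(class_scores = unname(scores),
       class_probs = unname(probs),
       predicted_class = which.max(scores) - 1L)
}

# ---------------------------------------------------------------------------
# training
# ---------------------------------------------------------------------------

#' Train the reference classifier
#'
#' Full-batch Adam on the mean cross-entropy of the dataset. All randomness
#' (parameter initialization) flows from \code{config$seed}, so runs are
#' bit-identical on the same build.
#'
#' @param graphs list of \linkS4class{CellDrugGraph} with both classes
#'   present.
#' @param config a \code{\link{modelConfig}}.
#' @param verbose print the loss every 25 epochs.
#' @return A trained \linkS4class{GraphModel}; the per-epoch loss trace is
#'   available via \code{\link{lossTrace}}.
#' @export
trainModel <- function(graphs, config = modelConfig(), verbose = FALSE) {
  if (length(graphs) == 0L) .vstop("dataset is empty")
  labels <- vapply(graphs, function(g) g@label, integer(1))
  if (length(unique(labels)) < 2L)
    .vstop("training requires both classes present in the dataset")
  chn <- channelNames(graphs[[1L]])
  ok <- vapply(graphs, function(g) identical(channelNames(g), chn),
               logical(1))
  if (!all(ok)) .vstop("all graphs must share channel names and order")

  model <- initGraphModel(config, chn)
  params <- model@params
  cfg <- model@config
  Xs <- lapply(graphs, function(g) g@features)
  masks <- lapply(graphs, .graphMask)
  n <- length(graphs)

  # Adam state
  mState <- lapply(params, function(p) p * 0)
  vState <- mState
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- cfg$learning_rate

  trace <- numeric(cfg$epochs)
  pnames <- names(params)
  for (epoch in seq_len(cfg$epochs)) {
    grads <- lapply(params, function(p) p * 0)
    loss <- 0
    for (i in seq_len(n)) {
      fw <- .forwardGraph(params, cfg, Xs[[i]], masks[[i]], cache = TRUE)
      probs <- .softmaxVec(fw$scores)
      y <- labels[i] + 1L
      loss <- loss - log(max(probs[y], 1e-300))
      dscores <- probs
      dscores[y] <- dscores[y] - 1
      bw <- .backwardGraph(params, cfg, fw$cache, dscores,
                           wantParams = TRUE, wantInput = FALSE)
      for (nm in pnames)
        grads[[nm]] <- grads[[nm]] + bw$grads[[nm]]
    }
    loss <- loss / n
    if (!is.finite(loss))
      .vstop("training diverged (non-finite loss) at epoch ", epoch)
    trace[epoch] <- loss
    corr1 <- 1 - b1^epoch
    corr2 <- 1 - b2^epoch
    for (nm in pnames) {
      gm <- grads[[nm]] / n
      mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * gm
      vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * gm * gm
      params[[nm]] <- params[[nm]] -
        lr * (mState[[nm]] / corr1) / (sqrt(vState[[nm]] / corr2) + aeps)
    }
    if (verbose && (epoch %% 25L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  loss %.5f", epoch, loss))
  }
  model@params <- params
  model@lossTrace <- trace
  model
}
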