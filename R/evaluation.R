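# Tissue-grouped cross-validation, ROC/AUC and planted-driver recovery.

#' ROC curve and AUC
#'
#' Rank-based (Mann--Whitney) AUC: the probability that a uniformly random
#' positive outscores a uniformly random negative, with ties counted 1/2.
#' The returned curve is the standard threshold sweep from (0, 0) to (1, 1),
#' monotone nondecreasing in both coordinates.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary 0/1 labels, both classes present.
#' @return list with \code{auc} and \code{curve} (data.frame fpr, tpr).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    .vstop("scores and labels must have equal length")
  if (!all(labels %in% c(0L, 1L))) .vstop("labels must be 0/1")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    .vstop("both classes must be present to compute AUC")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # collapse tied thresholds so the curve is a function of the threshold
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tpr <- cumsum(lab == 1L)[keep] / nPos
  fpr <- cumsum(lab == 0L)[keep] / nNeg
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Leave-one-group-out cross-validation
#'
#' Each tissue group in turn forms the validation set while a model is
#' trained on the remaining groups, testing cross-tissue generalization.
#' The per-fold model seed is \code{config$seed + fold index}, so folds are
#' reproducible but not coupled. Groups whose validation set contains a
#' single class have undefined AUC; they are excluded from the group mean
#' with a warning.
#'
#' @param graphs list of \linkS4class{CellDrugGraph} (>= 2 groups).
#' @param config a \code{\link{modelConfig}} used for every fold.
#' @param verbose print per-fold progress.
#' @return list with \code{group_auc} (named vector, NA where undefined),
#'   \code{mean_auc}/\code{sd_auc} over defined groups, \code{pooled_auc}
#'   over all held-out predictions, \code{curves} (per-group ROC points)
#'   and \code{predictions} (data.frame graph, group, label, score).
#' @export
groupedCrossValidation <- function(graphs, config = modelConfig(),
                                   verbose = FALSE) {
  groups <- vapply(graphs, tissueGroup, character(1))
  labels <- vapply(graphs, responseLabel, integer(1))
  gset <- sort(unique(groups))
  if (length(gset) < 2L)
    .vstop("grouped cross-validation needs at least 2 groups")

  preds <- data.frame(graph = seq_along(graphs), group = groups,
                      label = labels, score = NA_real_)
  for (f in seq_along(gset)) {
    gp <- gset[f]
    val <- which(groups == gp)
    trn <- which(groups != gp)
    foldCfg <- config
    foldCfg$seed <- .subSeed(config$seed, 1000L + f)
    model <- trainModel(graphs[trn], foldCfg)
    preds$score[val] <- vapply(val, function(i)
      predictGraph(model, graphs[[i]])$class_probs[2L], numeric(1))
    if (verbose)
      message("fold ", f, "/", length(gset), " (", gp, ") done")
  }
  stopifnot(!anyNA(preds$score))          # folds partition the dataset

  groupAuc <- stats::setNames(rep(NA_real_, length(gset)), gset)
  curves <- stats::setNames(vector("list", length(gset)), gset)
  for (gp in gset) {
    d <- preds[preds$group == gp, ]
    if (length(unique(d$label)) < 2L) {
      warning("group '", gp, "' has a single class; AUC undefined, ",
              "excluded from the mean", call. = FALSE)
      next
    }
    rc <- rocAuc(d$score, d$label)
    groupAuc[gp] <- rc$auc
    curves[[gp]] <- rc$curve
  }
  def <- groupAuc[!is.na(groupAuc)]
  list(group_auc = groupAuc,
       mean_auc = mean(def),
       sd_auc = stats::sd(def),
       pooled_auc = rocAuc(preds$score, preds$label)$auc,
       curves = curves,
       predictions = preds)
}

#' Permute response labels across a dataset
#'
#' Returns the same graphs with labels randomly permuted (features,
#' topology and groups untouched) — the permutation null for classifier
#' benchmarks: any real signal linking features to labels is destroyed
#' while class balance is preserved.
#'
#' @param graphs list of \linkS4class{CellDrugGraph}.
#' @param seed integer seed for the permutation.
#' @return list of \linkS4class{CellDrugGraph} with shuffled labels.
#' @export
shuffleGraphLabels <- function(graphs, seed = 1L) {
  set.seed(as.integer(seed))
  labs <- sample(vapply(graphs, responseLabel, integer(1)))
  lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    initialize(g, label = labs[i])
  })
}

#' Planted-driver recovery metrics
#'
#' Scores a per-group importance ranking against the planted driver sets:
#' precision@k = |top-k intersected with drivers| / k and
#' recall@k = |top-k intersected with drivers| / |drivers|.
#'
#' @param report an \linkS4class{ImportanceReport} (typically restricted to
#'   kinase nodes).
#' @param truth the \code{truth} element of \code{\link{generateCohort}}
#'   output (or any list with a \code{drivers} per-group list).
#' @param k ranking depth, > 0.
#' @return data.frame (group, precision, recall).
#' @export
driverRecovery <- function(report, truth, k = 5L) {
  if (k <= 0L) .vstop("k must be positive")
  top <- topRanked(report, k)
  gps <- sort(unique(top$group))
  out <- do.call(rbind, lapply(gps, function(gp) {
    drv <- truth$drivers[[gp]]
    if (is.null(drv)) .vstop("no planted drivers recorded for group ", gp)
    hits <- sum(top$node_id[top$group == gp] %in% drv)
    data.frame(group = gp, precision = hits / k,
               recall = hits / length(drv))
  }))
  rownames(out) <- NULL
  out
}
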