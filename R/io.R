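# On-disk interchange formats.
#
# A graph dataset directory holds three headered UTF-8 TSVs:
#   edges.tsv  — node1, node2 (undirected, one edge per line; shared topology)
#   nodes.tsv  — graph_id, node_id, <one column per channel> (long format)
#   labels.tsv — graph_id, label, group
# Reports and saliency tables are TSV; run configs are YAML or JSON; model
# parameters serialize to JSON with config, channel names and a format
# version so explain-time channel ordering is unambiguous.

#' Read a graph dataset directory
#'
#' @param dir directory containing \code{edges.tsv}, \code{nodes.tsv} and
#'   \code{labels.tsv}.
#' @return list of \linkS4class{CellDrugGraph}, ordered by graph id.
#' @export
readGraphDataset <- function(dir) {
  for (f in c("edges.tsv", "nodes.tsv", "labels.tsv"))
    if (!file.exists(file.path(dir, f)))
      .vstop("missing required file: ", file.path(dir, f))
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             colClasses = "character")
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"), check.names = FALSE)
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              colClasses = c("character", "integer",
                                             "character"))
  if (ncol(edges) != 2L) .vstop("edges.tsv must have exactly 2 columns")
  if (nrow(labels) == 0L) .vstop("no graphs: labels.tsv is empty")
  if (!all(c("graph_id", "node_id") %in% names(nodes)))
    .vstop("nodes.tsv needs columns graph_id, node_id")
  if (!all(c("graph_id", "label", "group") %in% names(labels)))
    .vstop("labels.tsv needs columns graph_id, label, group")
  channels <- setdiff(names(nodes), c("graph_id", "node_id"))
  if (length(channels) < 2L)
    .vstop("nodes.tsv must carry at least 2 channel columns")
  for (ch in channels)
    if (!is.numeric(nodes[[ch]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(nodes[[ch]]))))[1L]
      .vstop("non-numeric value in channel '", ch, "' at nodes.tsv line ",
             bad + 1L)
    }

  gids <- labels$graph_id
  if (anyDuplicated(gids)) .vstop("duplicate graph ids in labels.tsv")
  nodes$graph_id <- as.character(nodes$graph_id)
  nodes$node_id <- as.character(nodes$node_id)
  first <- nodes[nodes$graph_id == gids[1L], ]
  nodeIds <- first$node_id

  # validate edge endpoints with line numbers (header is line 1)
  known <- c(edges[, 1L] %in% nodeIds, edges[, 2L] %in% nodeIds)
  if (!all(known)) {
    bad <- which(!known)[1L]
    ln <- (bad - 1L) %% nrow(edges) + 1L
    id <- unlist(edges, use.names = FALSE)[bad]
    .vstop("edges.tsv line ", ln + 1L, " references unknown node '", id, "'")
  }

  lapply(seq_along(gids), function(i) {
    sub <- nodes[nodes$graph_id == gids[i], , drop = FALSE]
    if (!identical(sub$node_id, nodeIds))
      .vstop("graph '", gids[i],
             "' has a node set or order differing from graph '", gids[1L],
             "' (all graphs must share nodes)")
    X <- as.matrix(sub[, channels, drop = FALSE])
    CellDrugGraph(nodeIds, as.matrix(edges), X, channels,
                  labels$label[i], labels$group[i])
  })
}

#' Write a graph dataset directory
#'
#' Writes the canonical TSV layout read by \code{\link{readGraphDataset}};
#' re-reading and re-writing reproduces byte-identical files.
#'
#' @param graphs list of \linkS4class{CellDrugGraph} sharing a topology.
#' @param dir output directory (created if needed).
#' @param graphIds graph identifiers; default g001, g002, ...
#' @return \code{dir}, invisibly.
#' @export
writeGraphDataset <- function(graphs, dir,
                              graphIds = sprintf("g%03d",
                                                 seq_along(graphs))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g1 <- graphs[[1L]]
  A <- adjacency(g1)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  edges <- data.frame(node1 = nodeIds(g1)[idx[, 1L]],
                      node2 = nodeIds(g1)[idx[, 2L]])
  .writeTsv(edges, file.path(dir, "edges.tsv"))

  nodes <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    X <- features(graphs[[i]])
    cbind(data.frame(graph_id = graphIds[i], node_id = nodeIds(graphs[[i]])),
          as.data.frame(X, row.names = FALSE))
  }))
  .writeTsv(nodes, file.path(dir, "nodes.tsv"))

  labels <- data.frame(
    graph_id = graphIds,
    label = vapply(graphs, responseLabel, integer(1)),
    group = vapply(graphs, tissueGroup, character(1)))
  .writeTsv(labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @keywords internal
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write per-group importance reports
#'
#' Writes \code{importance.tsv} (group, node_id, score; groups sorted,
#' scores descending, ties lexicographic) and \code{topk.tsv} (the
#' \code{\link{topRanked}} table). Deterministic: identical inputs give
#' identical files.
#'
#' @param report an \linkS4class{ImportanceReport}.
#' @param dir output directory.
#' @param k ranking depth of the top-k table.
#' @return \code{dir}, invisibly.
#' @export
writeReports <- function(report, dir, k = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- importanceScores(report)
  df <- df[order(df$group, -df$score, df$node_id), ]
  .writeTsv(df, file.path(dir, "importance.tsv"))
  .writeTsv(topRanked(report, k), file.path(dir, "topk.tsv"))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# run configuration
# ---------------------------------------------------------------------------

#' Read a run configuration (YAML or JSON)
#'
#' Recognized top-level keys: \code{model}, \code{saliency},
#' \code{synthetic}, \code{evaluation}, \code{format_version}, \code{seed}.
#' Unknown keys (at top level or within a section) are rejected by name so
#' typos cannot silently fall back to defaults.
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return list with \code{model} (\code{\link{modelConfig}}),
#'   \code{saliency} (\code{\link{saliencyConfig}}), \code{synthetic}
#'   (\code{\link{syntheticConfig}}), \code{seed}, \code{format_version}.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
         else .vstop("config must be .yaml, .yml or .json")
  if (is.null(raw)) raw <- list()
  known <- c("model", "saliency", "synthetic", "evaluation",
             "format_version", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    .vstop("unknown config key(s): ", paste(extra, collapse = ", "))
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      .vstop("unknown key(s) in '", section, "' section: ",
             paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  if (is.null(raw$model$seed)) raw$model$seed <- seed
  if (is.null(raw$synthetic$seed)) raw$synthetic$seed <- seed
  list(model = build("model", modelConfig),
       saliency = build("saliency", saliencyConfig),
       synthetic = build("synthetic", syntheticConfig),
       evaluation = raw$evaluation,
       seed = seed,
       format_version = if (is.null(raw$format_version)) "1.0"
                        else as.character(raw$format_version))
}

# ---------------------------------------------------------------------------
# model serialization
# ---------------------------------------------------------------------------

#' Save / load a GraphModel as JSON
#'
#' Parameters, config, channel names, loss trace and format version are
#' written to \code{model.json} in \code{dir} at full double precision.
#'
#' @param model a \linkS4class{GraphModel}.
#' @param dir directory to write/read \code{model.json}.
#' @return \code{saveGraphModel}: \code{dir}, invisibly;
#'   \code{loadGraphModel}: the restored \linkS4class{GraphModel}.
#' @export
saveGraphModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    format_version = model@formatVersion,
    channel_names = model@channelNames,
    config = model@config,
    loss_trace = model@lossTrace,
    # 17 significant digits round-trip IEEE doubles exactly
    params = lapply(model@params, function(p)
      list(dim = if (is.matrix(p)) dim(p),
           data = sprintf("%.17g", as.numeric(p)))))
  jsonlite::write_json(payload, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname saveGraphModel
#' @export
loadGraphModel <- function(dir) {
  path <- file.path(dir, "model.json")
  if (!file.exists(path)) .vstop("no model.json in ", dir)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) {
    dat <- as.numeric(p$data)
    if (!is.null(p$dim) && length(p$dim))
      matrix(dat, p$dim[1L], p$dim[2L])
    else dat
  })
  cfg <- payload$config
  cfg$fc_layers <- as.integer(cfg$fc_layers)
  new("GraphModel", params = params, config = cfg,
      channelNames = as.character(payload$channel_names),
      lossTrace = as.numeric(payload$loss_trace),
      formatVersion = as.character(payload$format_version))
}
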