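# Synthetic planted-driver cohorts.
#
# The generator emulates the structure of real cell-line--drug inputs: a
# shared scale-free (PPI-like) topology whose nodes carry four channels
# (gene expression, kinase flag, drug binding affinity, disease
# association), with the binary response label caused by a small planted
# set of driver kinases. Because the ground truth is known, classifier
# learnability and attribution recovery are directly testable.

#' Synthetic cohort configuration
#'
#' @param n_nodes number of nodes of the shared topology.
#' @param attachment_m edges added per new node during preferential
#'   attachment (the topology has exactly (n_nodes - attachment_m) *
#'   attachment_m edges; m = 1 gives a tree).
#' @param n_kinases number of nodes flagged as kinases.
#' @param n_drivers planted driver kinases per group.
#' @param n_graphs_per_group graphs generated per group.
#' @param groups character vector of tissue tags.
#' @param effect_size expression shift added on active driver nodes.
#' @param noise_sd standard deviation of baseline expression noise.
#' @param n_targets kinases targeted (binding affinity > 0) by each graph's
#'   drug.
#' @param p_responsive probability that a graph's cell line is in the
#'   responsive state (drivers expressed above baseline).
#' @param label_rule labelling rule; only \code{"intersect"} is defined:
#'   label 1 iff the drug's target set intersects the graph's active driver
#'   set.
#' @param balance_range admissible cohort-level class-1 prevalence; the
#'   cohort is resampled (bounded retries) until prevalence falls inside.
#' @param seed master seed; topology, kinase roles, driver choice and
#'   per-graph noise each draw from sub-seeds derived from it.
#' @return config list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(n_nodes = 60L, attachment_m = 2L,
                            n_kinases = 12L, n_drivers = 3L,
                            n_graphs_per_group = 30L,
                            groups = c("breast", "digestive", "excretory",
                                       "haematopoietic", "respiratory"),
                            effect_size = 2.0, noise_sd = 0.5,
                            n_targets = 3L, p_responsive = 0.7,
                            label_rule = "intersect",
                            balance_range = c(0.3, 0.7), seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              attachment_m = as.integer(attachment_m),
              n_kinases = as.integer(n_kinases),
              n_drivers = as.integer(n_drivers),
              n_graphs_per_group = as.integer(n_graphs_per_group),
              groups = as.character(groups),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              n_targets = as.integer(n_targets),
              p_responsive = as.numeric(p_responsive),
              label_rule = match.arg(label_rule, "intersect"),
              balance_range = as.numeric(balance_range),
              seed = as.integer(seed))
  if (cfg$n_drivers > cfg$n_kinases || cfg$n_kinases > cfg$n_nodes)
    .vstop("need n_drivers <= n_kinases <= n_nodes")
  if (cfg$effect_size < 0) .vstop("effect_size must be >= 0")
  if (cfg$noise_sd <= 0) .vstop("noise_sd must be > 0")
  if (cfg$n_targets < 1L || cfg$n_targets > cfg$n_kinases)
    .vstop("need 1 <= n_targets <= n_kinases")
  if (cfg$p_responsive <= 0 || cfg$p_responsive > 1)
    .vstop("p_responsive must be in (0, 1]")
  if (length(cfg$balance_range) != 2L ||
      cfg$balance_range[1] > cfg$balance_range[2])
    .vstop("balance_range must be an increasing pair")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Generate the shared scale-free topology
#'
#' Barabasi--Albert preferential attachment: starting from
#' \code{attachment_m} unconnected seed nodes, each new node attaches to
#' \code{attachment_m} distinct existing nodes sampled with probability
#' proportional to degree + 1, giving a connected graph with exactly
#' (n_nodes - attachment_m) * attachment_m edges and heavy-tailed degrees
#' as in protein--protein interaction networks. Kinase roles are sampled
#' without replacement. Deterministic per seed.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return list with \code{nodeIds}, \code{edges} (2-column id matrix),
#'   \code{kinaseIds}.
#' @export
generateTopology <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  n <- cfg$n_nodes
  m <- cfg$attachment_m
  if (n <= m) .vstop("n_nodes must exceed attachment_m")
  set.seed(.subSeed(cfg$seed, 1L))
  deg <- integer(n)
  edges <- matrix(0L, nrow = (n - m) * m, ncol = 2L)
  row <- 1L
  for (v in seq.int(m + 1L, n)) {
    existing <- seq_len(v - 1L)
    nb <- existing[sample.int(length(existing), m, prob = deg[existing] + 1)]
    for (u in nb) {
      edges[row, ] <- c(u, v)
      row <- row + 1L
    }
    deg[nb] <- deg[nb] + 1L
    deg[v] <- deg[v] + m
  }
  nodeIds <- sprintf("GENE%03d", seq_len(n))
  kin <- sort(sample.int(n, cfg$n_kinases))
  list(nodeIds = nodeIds,
       edges = cbind(nodeIds[edges[, 1L]], nodeIds[edges[, 2L]]),
       kinaseIds = nodeIds[kin])
}

#' Generate a planted-driver cohort
#'
#' All graphs share the topology from \code{\link{generateTopology}} and
#' carry four channels: \code{expression} (baseline N(0, noise_sd), shifted
#' by +effect_size on the drivers of responsive graphs), \code{kinase_flag}
#' (0/1), \code{binding_affinity} (Unif(0.5, 1) on the drug's target
#' kinases, 0 elsewhere), and \code{disease_assoc} (Unif(0, 1) noise). Per
#' group a driver set of \code{n_drivers} kinases is planted; per graph the
#' cell line is responsive with probability \code{p_responsive} (all its
#' drivers are then active, i.e. expression-shifted) and the drug targets
#' \code{n_targets} random kinases. The label is 1 iff the target set
#' intersects the active driver set, so positive-label graphs always bind
#' at least one driver. Cohort-level class balance is enforced by
#' resampling (up to 100 attempts).
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return list with \code{graphs} (list of \linkS4class{CellDrugGraph}),
#'   \code{truth} (planted \code{drivers} per group, \code{kinaseIds},
#'   \code{nodeIds}, config echo), and \code{topology}.
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  topo <- generateTopology(cfg)
  n <- cfg$n_nodes
  kinIdx <- match(topo$kinaseIds, topo$nodeIds)
  channels <- c("expression", "kinase_flag", "binding_affinity",
                "disease_assoc")
  kflag <- numeric(n)
  kflag[kinIdx] <- 1

  set.seed(.subSeed(cfg$seed, 2L))
  drivers <- lapply(cfg$groups, function(gp)
    sort(sample(topo$kinaseIds, cfg$n_drivers)))
  names(drivers) <- cfg$groups

  nG <- cfg$n_graphs_per_group * length(cfg$groups)
  set.seed(.subSeed(cfg$seed, 3L))
  for (attempt in seq_len(100L)) {
    graphs <- vector("list", nG)
    labels <- integer(nG)
    i <- 0L
    for (gp in cfg$groups) {
      drvIdx <- match(drivers[[gp]], topo$nodeIds)
      for (j in seq_len(cfg$n_graphs_per_group)) {
        i <- i + 1L
        responsive <- stats::runif(1) < cfg$p_responsive
        active <- if (responsive) drvIdx else integer(0)
        targets <- kinIdx[sample.int(length(kinIdx), cfg$n_targets)]
        expr <- stats::rnorm(n, 0, cfg$noise_sd)
        expr[active] <- expr[active] + cfg$effect_size
        aff <- numeric(n)
        aff[targets] <- stats::runif(cfg$n_targets, 0.5, 1)
        dis <- stats::runif(n)
        lab <- as.integer(length(intersect(targets, active)) > 0L)
        X <- cbind(expr, kflag, aff, dis)
        colnames(X) <- channels
        labels[i] <- lab
        graphs[[i]] <- CellDrugGraph(topo$nodeIds, .edgesToAdj(topo, n),
                                     X, channels, lab, gp)
      }
    }
    prev <- mean(labels)
    if (prev >= cfg$balance_range[1] && prev <= cfg$balance_range[2])
      return(list(graphs = graphs,
                  truth = list(drivers = drivers,
                               kinaseIds = topo$kinaseIds,
                               nodeIds = topo$nodeIds,
                               config = unclass(cfg)),
                  topology = topo))
  }
  .vstop("could not reach class balance in ", cfg$balance_range[1], "-",
         cfg$balance_range[2], " after 100 attempts; adjust the config")
}

# cache-free dense adjacency from the shared edge list
#' @keywords internal
.edgesToAdj <- function(topo, n) {
  A <- matrix(0, n, n, dimnames = list(topo$nodeIds, topo$nodeIds))
  i <- match(topo$edges[, 1L], topo$nodeIds)
  j <- match(topo$edges[, 2L], topo$nodeIds)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  A
}
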