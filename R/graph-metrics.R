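#' Canonical frequency bands
#'
#' Conventional MEG band boundaries (Hz). Bands are half-open `[low, high)`
#' except the last, which is closed at the top so the analysis band is fully
#' covered.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 80))
}

.assign_band <- function(f, bands = canonical_bands()) {
  out <- rep(NA_integer_, length(f))
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1]
    hi <- bands[[b]][2]
    hit <- if (b == length(bands)) f >= lo & f <= hi else f >= lo & f < hi
    out[hit & is.na(out)] <- b
  }
  out
}

#' Mean clustering coefficient
#'
#' Per-node triangle density `C_i = 2 T_i / (deg_i (deg_i - 1))`, with
#' `C_i = 0` for nodes of degree < 2, averaged over all nodes.
#'
#' @param net a `functional_network` or igraph graph.
#' @return A single number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) < 3) stop("need at least 3 nodes")
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over ordered node pairs, with
#' disconnected pairs contributing 0.
#'
#' @param net a `functional_network` or igraph graph.
#' @return A single number in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes")
  if (igraph::ecount(g) == 0) return(0)
  igraph::global_efficiency(g, directed = FALSE)
}

#' Degree assortativity (Newman's r)
#'
#' Pearson correlation of endpoint degrees over all edges (counted in both
#' orientations). Undefined on degree-regular edge sets (zero variance);
#' returned as `NaN` with attribute `degenerate = TRUE` in that case.
#'
#' @param net a `functional_network` or igraph graph.
#' @return A number in `[-1, 1]`, or `NaN` (flagged) when undefined.
#' @export
assortativity_coefficient <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) < 2) stop("need at least 2 edges")
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (!is.finite(r)) {
    r <- NaN
    attr(r, "degenerate") <- TRUE
  }
  r
}

#' Louvain module counts over repeated randomized runs
#'
#' Runs Louvain community detection `n_runs` times, each on a uniformly
#' random relabelling of the vertices (the algorithm's greedy sweep depends on
#' vertex order, which is the stochastic element), and averages the number of
#' modules and the modularity Q. Every node is assigned; isolated nodes count
#' as their own module. An edgeless graph yields one module per node, Q = 0.
#'
#' @param net a `functional_network` or igraph graph.
#' @param n_runs number of runs (default 500).
#' @param seed optional integer seed.
#' @return list with `mean_modules`, `mean_q`, `module_counts` (per run).
#' @export
louvain_modules <- function(net, n_runs = 500, seed = NULL) {
  g <- as_igraph(net)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    return(list(mean_modules = n, mean_q = 0,
                module_counts = rep(n, n_runs)))
  }
  counts <- integer(n_runs)
  qs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    counts[r] <- length(unique(igraph::membership(cl)))
    qs[r] <- igraph::modularity(gp, igraph::membership(cl))
  }
  list(mean_modules = mean(counts), mean_q = mean(qs),
       module_counts = counts)
}

#' Degree-preserving randomization (double-edge swaps)
#'
#' Maslov-Sneppen rewiring: attempts `swaps_per_edge * E` double-edge swaps,
#' skipping swaps that would create a loop or multi-edge, so the degree
#' sequence is preserved exactly and the graph stays simple. Graphs with no
#' valid swap (e.g. a star) are returned unchanged.
#'
#' @param net a `functional_network` or igraph graph.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed optional integer seed.
#' @return An igraph graph with the same degree sequence.
#' @export
rewire_preserving_degree <- function(net, swaps_per_edge = 10, seed = NULL) {
  g <- as_igraph(net)
  if (igraph::ecount(g) < 2) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(as.integer(seed))
  igraph::rewire(g,
                 igraph::keeping_degseq(loops = FALSE,
                                        niter = swaps_per_edge *
                                          igraph::ecount(g)))
}

#' Rich-club extraction normalized by rewired random networks
#'
#' For every degree level k at which at least two nodes of degree > k exist,
#' computes the rich-club density
#' `phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))` over the subgraph of nodes
#' with degree > k, and normalizes by the mean of the same quantity across
#' `n_random` degree-preserving rewired networks. The club is extracted at
#' `k* = argmax phi_norm(k)` (ties toward the smallest k): its members are the
#' nodes of degree > k*, and the reported characteristics are the member count
#' (Rich Club Nodes), the minimum member degree (Rich Club Degree), and the
#' normalized coefficient `phi(k*) / mean phi_rand(k*)` (Rich Club
#' Coefficient).
#'
#' @param net a `functional_network` or igraph graph.
#' @param n_random number of rewired networks (default 500).
#' @param swaps_per_edge rewiring intensity, see
#'   [rewire_preserving_degree()].
#' @param seed optional integer seed.
#' @return An object of class `rich_club_result`: `k` (evaluated levels),
#'   `phi`, `phi_rand_mean`, `phi_norm`, `k_star`, `members`, `n_nodes`,
#'   `min_degree`, `coefficient`, `n_random`.
#' @export
rich_club_analysis <- function(net, n_random = 500, swaps_per_edge = 10,
                               seed = NULL) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- as.character(seq_along(deg))
  phi_of <- function(graph, k_levels, degree_ref) {
    vapply(k_levels, function(k) {
      keep <- which(degree_ref > k)
      sg <- igraph::induced_subgraph(graph, keep)
      n_k <- length(keep)
      2 * igraph::ecount(sg) / (n_k * (n_k - 1))
    }, 0)
  }
  k_levels <- 0:max(0, max(deg) - 1)
  k_levels <- k_levels[vapply(k_levels, function(k) sum(deg > k) >= 2,
                              TRUE)]
  if (length(k_levels) == 0) {
    stop("no rich club definable: fewer than 2 nodes above any degree level")
  }
  phi <- phi_of(g, k_levels, deg)
  if (!is.null(seed)) set.seed(as.integer(seed))
  phi_rand <- matrix(0, n_random, length(k_levels))
  for (r in seq_len(n_random)) {
    gr <- rewire_preserving_degree(g, swaps_per_edge = swaps_per_edge)
    # rewiring preserves degrees, so the node sets above each level are fixed
    phi_rand[r, ] <- phi_of(gr, k_levels, deg)
  }
  phi_rand_mean <- colMeans(phi_rand)
  phi_norm <- ifelse(phi_rand_mean > 0, phi / phi_rand_mean,
                     ifelse(phi > 0, Inf, NA_real_))
  score <- ifelse(is.na(phi_norm), -Inf, phi_norm)
  k_star <- k_levels[which.max(score)] # first max = smallest k at ties
  members <- labels[deg > k_star]
  structure(list(k = k_levels, phi = phi, phi_rand_mean = phi_rand_mean,
                 phi_norm = phi_norm, k_star = k_star, members = members,
                 n_nodes = length(members),
                 min_degree = min(deg[deg > k_star]),
                 coefficient = phi_norm[match(k_star, k_levels)],
                 n_random = n_random),
            class = "rich_club_result")
}

#' @export
print.rich_club_result <- function(x, ...) {
  cat("<rich_club_result> k* =", x$k_star, "|", x$n_nodes,
      "members, min degree", x$min_degree,
      sprintf(", coefficient %.3f (vs %d rewired nulls)\n",
              x$coefficient, x$n_random))
  invisible(x)
}

#' Identify network hubs
#'
#' Hubs are the `fraction` (default 10%) of nodes with the highest degree:
#' `max(1, floor(fraction * N))` nodes, ties at the cutoff broken by label
#' order.
#'
#' @param net a `functional_network` or igraph graph.
#' @param fraction fraction of nodes (default 0.10).
#' @return Character vector of hub labels.
#' @examples
#' g <- generate_toy_graph("planted_club", n = 41, club_size = 8)
#' length(identify_hubs(g)) # 4
#' @export
identify_hubs <- function(net, fraction = 0.10) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- as.character(seq_along(deg))
  n_hubs <- max(1L, floor(fraction * length(deg)))
  labels[order(-deg, labels)][seq_len(n_hubs)]
}

#' Connection-frequency statistics of an edge set
#'
#' @param edges data.frame with a `f_star_hz` column (or a numeric vector of
#'   per-edge frequencies).
#' @param bands band definition, see [canonical_bands()].
#' @return list with `mean_frequency_hz` (`NA` with `degenerate = TRUE` when
#'   there are no edges) and integer `band_counts` summing to the edge count.
#' @export
connection_frequency_stats <- function(edges, bands = canonical_bands()) {
  f <- if (is.data.frame(edges)) edges$f_star_hz else as.numeric(edges)
  counts <- setNames(integer(length(bands)), names(bands))
  if (length(f) == 0) {
    return(list(mean_frequency_hz = NA_real_, band_counts = counts,
                degenerate = TRUE))
  }
  idx <- .assign_band(f, bands)
  tab <- table(factor(idx, levels = seq_along(bands)))
  counts[] <- as.integer(tab)
  list(mean_frequency_hz = mean(f), band_counts = counts, degenerate = FALSE)
}

#' Full network metric battery for one subject/timepoint
#'
#' Computes the complete topology battery on the (binary) thresholded
#' network: mean clustering coefficient, global efficiency, degree
#' assortativity, rich-club characteristics against rewired nulls, mean
#' Louvain module count, hubs, and connection-frequency statistics. Band and
#' frequency statistics are computed on the configurable edge set
#' (`"gated"` candidates by default, or the `"thresholded"` network).
#'
#' @param net a `functional_network` from [fit_network()] (or
#'   [threshold_network()]).
#' @param config a [pipeline_config()]; defaults to the one stored in `net`.
#' @param seed optional integer seed; defaults to a [child_seed()] split of
#'   the config's master seed by subject/timepoint.
#' @return An object of class `metrics_record`.
#' @export
network_metrics <- function(net, config = NULL, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  if (is.null(config)) config <- net$config
  if (is.null(config)) config <- pipeline_config()
  if (is.null(seed)) {
    seed <- child_seed(config$master_seed, "metrics",
                       if (is.null(net$subject_id)) "" else net$subject_id,
                       if (is.null(net$timepoint)) "" else net$timepoint)
  }
  g <- net$graph
  edge_set <- switch(config$band_count_edge_set,
    gated = net$candidates[net$candidates$connected, , drop = FALSE],
    thresholded = net$edges,
    stop("band_count_edge_set must be 'gated' or 'thresholded'")
  )
  freq_stats <- connection_frequency_stats(edge_set, config$bands)
  rc <- if (!net$empty) {
    rich_club_analysis(g, n_random = config$n_random_networks,
                       seed = child_seed(seed, "richclub"))
  } else {
    NULL
  }
  lv <- louvain_modules(g, n_runs = config$n_louvain_runs,
                        seed = child_seed(seed, "louvain"))
  assort <- if (igraph::ecount(g) >= 2) assortativity_coefficient(g) else NaN
  structure(list(
    subject_id = net$subject_id, timepoint = net$timepoint,
    clustering_coefficient = clustering_coefficient(g),
    global_efficiency = global_efficiency(g),
    assortativity = as.numeric(assort),
    assortativity_degenerate = isTRUE(attr(assort, "degenerate")),
    rich_club = rc,
    rich_club_coefficient = if (is.null(rc)) NA_real_ else rc$coefficient,
    rich_club_nodes = if (is.null(rc)) NA_real_ else rc$n_nodes,
    rich_club_min_degree = if (is.null(rc)) NA_real_ else rc$min_degree,
    n_modules_mean = lv$mean_modules,
    modularity_mean = lv$mean_q,
    mean_connection_frequency = freq_stats$mean_frequency_hz,
    band_counts = freq_stats$band_counts,
    hubs = identify_hubs(g, fraction = config$hub_fraction),
    n_edges = nrow(net$edges),
    achieved_K = net$achieved_K,
    seed = seed
  ), class = "metrics_record")
}

#' @export
summary.functional_network <- function(object, config = NULL, seed = NULL,
                                       ...) {
  network_metrics(object, config = config, seed = seed)
}

#' @export
print.metrics_record <- function(x, ...) {
  cat("<metrics_record>")
  if (!is.null(x$subject_id)) cat(" subject", x$subject_id, "/", x$timepoint)
  cat("\n")
  num <- function(v) formatC(v, digits = 3, format = "fg")
  cat("  clustering coefficient  ", num(x$clustering_coefficient), "\n")
  cat("  global efficiency       ", num(x$global_efficiency), "\n")
  cat("  assortativity           ", num(x$assortativity),
      if (x$assortativity_degenerate) "(degenerate)" else "", "\n")
  cat("  rich club coefficient   ", num(x$rich_club_coefficient), "\n")
  cat("  rich club nodes         ", x$rich_club_nodes, "\n")
  cat("  rich club min degree    ", x$rich_club_min_degree, "\n")
  cat("  mean modules            ", num(x$n_modules_mean), "\n")
  cat("  mean connection freq    ", num(x$mean_connection_frequency),
      "Hz\n")
  cat("  band counts             ",
      paste(names(x$band_counts), x$band_counts, collapse = ", "), "\n")
  cat("  hubs                    ", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}
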