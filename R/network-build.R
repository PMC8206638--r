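#' Target average degree under the S-exponent density criterion
#'
#' The density criterion `S = log(N) / log(K)` fixes the average degree of an
#' N-node network at `K = N^(1/S)`; the implied edge count is
#' `E = round(N * K / 2)`.
#'
#' @param n_nodes node count N (>= 2).
#' @param s density exponent (default 2.5).
#' @return list with `K` (average degree) and `E` (target edge count).
#' @examples
#' target_degree(41)   # K ~ 4.42, E = 91
#' target_degree(100, s = 2) # K = 10
#' @export
target_degree <- function(n_nodes, s = 2.5) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (s <= 0) stop("s must be positive")
  k <- n_nodes^(1 / s)
  list(K = k, E = as.integer(round(n_nodes * k / 2)))
}

#' Threshold gated candidates into a functional network
#'
#' Keeps the `E` gated candidates of largest effect size `z_max`
#' (`E` from [target_degree()]); ties at the E-th rank are broken by lower
#' connection frequency, then label order, so the result is deterministic. If
#' fewer candidates pass the gate than the density criterion asks for, all of
#' them are kept and the achieved average degree is recorded (the gate is a
#' noise floor and is never backed off). Zero gated candidates yield an
#' empty-edge network with a warning flag rather than an error.
#'
#' @param candidates data.frame as returned by [connection_candidates()].
#' @param node_labels character vector of all node labels.
#' @param s density exponent.
#' @param gate the SD gate the candidates were called at (recorded).
#' @return An object of class `functional_network`: igraph `graph`, `edges`
#'   data.frame (`roi_i`, `roi_j`, `f_star_hz`, `z_max`), the full
#'   `candidates` table, `n_nodes`, `target_K`, `achieved_K`, `s`, `gate`,
#'   logical `empty`.
#' @export
threshold_network <- function(candidates, node_labels, s = 2.5, gate = 2.5) {
  stopifnot(is.data.frame(candidates),
            all(c("roi_i", "roi_j", "z_max", "f_star_hz",
                  "connected") %in% names(candidates)))
  node_labels <- as.character(node_labels)
  n <- length(node_labels)
  if (!all(c(candidates$roi_i, candidates$roi_j) %in% node_labels)) {
    stop("candidate labels not covered by node_labels")
  }
  td <- target_degree(n, s)
  conn <- candidates[candidates$connected, , drop = FALSE]
  empty <- nrow(conn) == 0
  if (empty) warning("no candidate passed the gate: empty network")
  ord <- order(-conn$z_max, conn$f_star_hz, conn$roi_i, conn$roi_j)
  kept <- conn[ord, , drop = FALSE][seq_len(min(td$E, nrow(conn))), ,
                                    drop = FALSE]
  rownames(kept) <- NULL
  g <- igraph::graph_from_data_frame(
    kept[, c("roi_i", "roi_j", "f_star_hz", "z_max")],
    directed = FALSE, vertices = data.frame(name = node_labels)
  )
  structure(list(graph = g,
                 edges = kept[, c("roi_i", "roi_j", "f_star_hz", "z_max")],
                 candidates = candidates, n_nodes = n,
                 node_labels = node_labels,
                 target_K = td$K, target_E = td$E,
                 achieved_K = 2 * nrow(kept) / n,
                 s = s, gate = gate, empty = empty),
            class = "functional_network")
}

#' Coerce to igraph
#'
#' @param x a `functional_network` or igraph graph.
#' @return An igraph graph.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "functional_network")) return(x$graph)
  if (inherits(x, "igraph")) return(x)
  stop("cannot coerce ", class(x)[1], " to igraph")
}

#' Fit a functional brain network to ROI source series
#'
#' The central estimator: builds the subject's phase-randomized surrogate
#' null, calls every ROI pair's connection at the frequency of maximal
#' real-minus-surrogate difference (in null SD units), gates at
#' `config$gate_sd`, and thresholds to the density implied by
#' `config$s_exponent`. All stochastic stages are seeded from
#' `config$master_seed` via [child_seed()], split by subject and timepoint, so
#' subjects can be recomputed independently with identical results.
#'
#' @param x a [source_series_set()].
#' @param config a [pipeline_config()].
#' @return A `functional_network` (see [threshold_network()]) with additional
#'   fields `subject_id`, `timepoint`, `fs`, `config`, and a `provenance` list
#'   (seeds and stage counts).
#' @seealso [summary.functional_network()] for the metric battery,
#'   [network_metrics()].
#' @export
fit_network <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "source_series_set"),
            inherits(config, "pipeline_config"))
  seed_null <- child_seed(config$master_seed, "surrogate",
                          x$subject_id, x$timepoint)
  null <- build_surrogate_null(x, params = config$spectral,
                               n_pairs = config$n_surrogate_pairs,
                               seed = seed_null)
  cand <- connection_candidates(x, null, params = config$spectral,
                                gate = config$gate_sd)
  net <- suppressWarnings(
    threshold_network(cand, x$roi_labels, s = config$s_exponent,
                      gate = config$gate_sd)
  )
  net$subject_id <- x$subject_id
  net$timepoint <- x$timepoint
  net$fs <- x$fs
  net$null <- null
  net$config <- config
  net$provenance <- list(
    seed_null = seed_null,
    n_surrogate_pairs = config$n_surrogate_pairs,
    n_candidates = nrow(cand),
    n_gated = sum(cand$connected),
    n_edges = nrow(net$edges),
    target_E = net$target_E,
    achieved_K = net$achieved_K
  )
  net
}

#' @export
print.functional_network <- function(x, ...) {
  cat("<functional_network>")
  if (!is.null(x$subject_id)) {
    cat(" subject", x$subject_id, "/", x$timepoint)
  }
  cat("\n  ", x$n_nodes, "nodes,", nrow(x$edges), "edges",
      sprintf("(target E = %d, achieved K = %.2f, S = %g, gate = %g SD)\n",
              x$target_E, x$achieved_K, x$s, x$gate))
  if (isTRUE(x$empty)) cat("   [empty: no candidate passed the gate]\n")
  invisible(x)
}

#' Plot a functional network
#'
#' Circular layout with vertex size scaled by degree; hubs (top 10% by
#' degree) are highlighted, and edges are coloured by canonical frequency
#' band.
#'
#' @param x a `functional_network`.
#' @param hub_fraction fraction of nodes highlighted as hubs.
#' @param bands band definition, see [canonical_bands()].
#' @param ... passed to `plot.igraph`.
#' @export
plot.functional_network <- function(x, hub_fraction = 0.10,
                                    bands = canonical_bands(), ...) {
  g <- x$graph
  deg <- igraph::degree(g)
  hubs <- identify_hubs(x, fraction = hub_fraction)
  cols <- grDevices::hcl.colors(length(bands), "Dark 3")
  band_of <- .assign_band(igraph::E(g)$f_star_hz, bands)
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    vertex.size = 4 + 10 * deg / max(1, max(deg)),
    vertex.color = ifelse(igraph::V(g)$name %in% hubs, "tomato", "grey80"),
    vertex.label.cex = 0.6,
    edge.color = cols[band_of], ...
  )
  invisible(x)
}

#' Export a network's adjacency matrix
#'
#' @param net a `functional_network`.
#' @return A binary N x N symmetric matrix with dimnames.
#' @export
adjacency_matrix <- function(net) {
  g <- as_igraph(net)
  as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
}
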