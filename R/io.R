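#' Write / read ROI source series as TSV plus metadata sidecar
#'
#' On-disk layout: a tab-separated matrix (row = ROI, column = sample, first
#' column `roi`) at `path`, and a YAML sidecar at `<path minus .tsv>.meta.yaml`
#' holding `subject_id`, `timepoint`, `fs`, `n_rois`, `n_samples`. Values are
#' written with 17 significant digits so that `read(write(x))` reproduces the
#' doubles bit-identically.
#'
#' @param x a [source_series_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_source_series <- function(x, path) {
  stopifnot(inherits(x, "source_series_set"))
  df <- data.frame(roi = x$roi_labels,
                   matrix(sprintf("%.17g", x$data), nrow(x$data)),
                   stringsAsFactors = FALSE)
  names(df) <- c("roi", sprintf("s%d", seq_len(ncol(x$data))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = x$subject_id, timepoint = x$timepoint,
               fs = x$fs, n_rois = nrow(x$data), n_samples = ncol(x$data))
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

.sidecar_path <- function(path) {
  paste0(sub("\\.tsv$", "", path), ".meta.yaml")
}

#' @rdname write_source_series
#' @param path TSV path written by [write_source_series()].
#' @export
read_source_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  for (field in c("fs", "subject_id", "timepoint")) {
    if (is.null(meta[[field]])) {
      stop("metadata sidecar missing required field '", field, "'")
    }
  }
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  labels <- df[[1]]
  mat <- matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
                nrow = nrow(df))
  if (!is.null(meta$n_rois) && nrow(mat) != meta$n_rois) {
    stop("shape mismatch: sidecar says ", meta$n_rois, " ROIs, file has ",
         nrow(mat))
  }
  if (!is.null(meta$n_samples) && ncol(mat) != meta$n_samples) {
    stop("shape mismatch: sidecar says ", meta$n_samples,
         " samples, file has ", ncol(mat))
  }
  source_series_set(mat, fs = meta$fs, roi_labels = labels,
                    subject_id = meta$subject_id, timepoint = meta$timepoint)
}

#' Write / read a connection-candidate or edge table as TSV
#'
#' @param candidates data.frame from [connection_candidates()] (or the
#'   `edges` slot of a `functional_network`).
#' @param path TSV path.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  for (v in names(out)) {
    if (is.double(out[[v]])) out[[v]] <- sprintf("%.17g", out[[v]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (v in intersect(c("f_star_hz", "z_max"), names(df))) {
    df[[v]] <- as.numeric(df[[v]])
  }
  if ("connected" %in% names(df)) df$connected <- as.logical(df$connected)
  df
}

#' Write a surrogate null as TSV (freq, mu, sigma)
#'
#' @param null a [build_surrogate_null()] result.
#' @param path TSV path.
#' @export
write_null <- function(null, path) {
  write.table(
    data.frame(freq_hz = sprintf("%.17g", null$freqs),
               mu = sprintf("%.17g", null$mu),
               sigma = sprintf("%.17g", null$sigma)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a metrics record as flat JSON
#'
#' Serializes the scalar battery (plus band counts, hubs and rich-club
#' members) of a [network_metrics()] record as a flat key-value JSON file.
#'
#' @param record a `metrics_record`.
#' @param path output path.
#' @export
write_metrics <- function(record, path) {
  stopifnot(inherits(record, "metrics_record"))
  out <- list(
    subject_id = record$subject_id, timepoint = record$timepoint,
    clustering_coefficient = record$clustering_coefficient,
    global_efficiency = record$global_efficiency,
    assortativity = record$assortativity,
    rich_club_coefficient = record$rich_club_coefficient,
    rich_club_nodes = record$rich_club_nodes,
    rich_club_min_degree = record$rich_club_min_degree,
    n_modules_mean = record$n_modules_mean,
    mean_connection_frequency = record$mean_connection_frequency,
    band_counts = as.list(record$band_counts),
    hubs = record$hubs,
    rich_club_members = if (is.null(record$rich_club)) character(0) else
      record$rich_club$members,
    n_edges = record$n_edges, achieved_K = record$achieved_K,
    seed = record$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write adjacency matrix as a square TSV
#'
#' @param net a `functional_network` or igraph graph.
#' @param path TSV path.
#' @export
write_adjacency <- function(net, path) {
  adj <- adjacency_matrix(net)
  write.table(data.frame(roi = rownames(adj), adj, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
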