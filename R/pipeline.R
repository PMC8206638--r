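#' Pipeline configuration
#'
#' Collects every analysis constant in one validated object. Defaults are the
#' full-scale study settings: 1-80 Hz analysis band, 2.5 SD surrogate gate,
#' density exponent S = 2.5, 5000 surrogate pairs, 500 rewired random
#' networks, 500 Louvain runs, top 10% hubs, membership inclusion at 3
#' subjects. Tests and examples scale the counts down; every value is a
#' parameter, never hard-coded downstream.
#'
#' @param f_min,f_max,segment_length_s,overlap_fraction spectral estimation,
#'   see [spectral_params()].
#' @param gate_sd surrogate gate in null-SD units.
#' @param s_exponent density exponent S.
#' @param n_surrogate_pairs surrogate draws per subject.
#' @param n_random_networks rewired nulls for the rich-club normalization.
#' @param n_louvain_runs Louvain repetitions.
#' @param hub_fraction top-degree fraction called hubs.
#' @param bands frequency-band edges, see [canonical_bands()].
#' @param band_count_edge_set `"gated"` (all candidates passing the gate;
#'   default) or `"thresholded"` (the density-thresholded network) — the edge
#'   set on which band counts and mean connection frequency are computed.
#' @param min_count,hub_min_count membership-table inclusion thresholds for
#'   rich-club and hub tables.
#' @param reference_intake g/kg reference for the one-sample effect size of
#'   the drinking summary (default 1.5, the final induction dose).
#' @param collapse_map optional ROI-to-structure map used by the cohort
#'   report, see [collapse_regions()].
#' @param master_seed integer seed from which every stochastic stage derives
#'   its own seed via [child_seed()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(f_min = 1, f_max = 80, segment_length_s = 2,
                            overlap_fraction = 0.5, gate_sd = 2.5,
                            s_exponent = 2.5, n_surrogate_pairs = 5000,
                            n_random_networks = 500, n_louvain_runs = 500,
                            hub_fraction = 0.10, bands = canonical_bands(),
                            band_count_edge_set = c("gated", "thresholded"),
                            min_count = 3, hub_min_count = 1,
                            reference_intake = 1.5, collapse_map = NULL,
                            master_seed = 1) {
  stopifnot(gate_sd > 0, s_exponent > 0, n_surrogate_pairs >= 1,
            n_random_networks >= 1, n_louvain_runs >= 1,
            hub_fraction > 0, hub_fraction <= 1, min_count >= 1,
            hub_min_count >= 1)
  lows <- vapply(bands, `[`, 0, 1)
  his <- vapply(bands, `[`, 0, 2)
  if (any(his <= lows) || any(diff(lows) <= 0) ||
      any(abs(his[-length(his)] - lows[-1]) > 1e-9)) {
    stop("bands must be increasing, non-overlapping and contiguous")
  }
  structure(list(
    spectral = spectral_params(f_min, f_max, segment_length_s,
                               overlap_fraction),
    gate_sd = gate_sd, s_exponent = s_exponent,
    n_surrogate_pairs = n_surrogate_pairs,
    n_random_networks = n_random_networks,
    n_louvain_runs = n_louvain_runs, hub_fraction = hub_fraction,
    bands = bands,
    band_count_edge_set = match.arg(band_count_edge_set),
    min_count = min_count, hub_min_count = hub_min_count,
    reference_intake = reference_intake, collapse_map = collapse_map,
    master_seed = as.integer(master_seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  band %g-%g Hz, %g s segments (%.0f%% overlap)\n",
              x$spectral$f_min, x$spectral$f_max,
              x$spectral$segment_length_s,
              100 * x$spectral$overlap_fraction))
  cat(sprintf("  gate %g SD | S = %g | %d surrogate pairs | %d rewired",
              x$gate_sd, x$s_exponent, x$n_surrogate_pairs,
              x$n_random_networks),
      sprintf("nulls | %d Louvain runs\n", x$n_louvain_runs))
  cat(sprintf("  hubs: top %.0f%% | band counts on %s edge set | seed %d\n",
              100 * x$hub_fraction, x$band_count_edge_set, x$master_seed))
  invisible(x)
}

#' Run the per-subject pipeline: series to network and metrics
#'
#' Convenience wrapper: [fit_network()] then [network_metrics()].
#'
#' @param series a [source_series_set()].
#' @param config a [pipeline_config()].
#' @return list with `network` (a `functional_network`) and `metrics`
#'   (a `metrics_record`).
#' @export
run_subject <- function(series, config = pipeline_config()) {
  net <- fit_network(series, config)
  list(network = net, metrics = network_metrics(net, config))
}

.metrics_row <- function(m) {
  data.frame(
    clustering_coefficient = m$clustering_coefficient,
    global_efficiency = m$global_efficiency,
    assortativity = m$assortativity,
    rich_club_coefficient = m$rich_club_coefficient,
    rich_club_nodes = m$rich_club_nodes,
    rich_club_min_degree = m$rich_club_min_degree,
    n_modules = m$n_modules_mean,
    mean_connection_frequency = m$mean_connection_frequency,
    t(as.matrix(setNames(as.numeric(m$band_counts),
                         paste0(names(m$band_counts), "_connections"))))
  )
}

#' Group-level report over a two-timepoint cohort
#'
#' Implements the group analyses: per-metric descriptive summary and paired t
#' across timepoints; Spearman screen of baseline metrics against the
#' drinking outcome; hub and rich-club membership tables with the
#' across-region paired t and per-region exact McNemar; and the drinking
#' summary (mean, SD, one-sample and paired Cohen's d forms). Subjects
#' missing a timepoint are dropped with a warning.
#'
#' @param fits named list, one element per subject, each a list with
#'   `baseline` and `free_access` [network_metrics()] records (a
#'   `functional_network` is summarized on the fly).
#' @param outcomes named numeric vector of free-access daily average intake
#'   (g/kg), names matching the subjects.
#' @param config a [pipeline_config()].
#' @return An object of class `cohort_report` with elements
#'   `metric_summary`, `correlations`, `hub_membership`,
#'   `rich_club_membership` (each membership entry containing the table and
#'   its change tests), and `drinking`.
#' @export
run_cohort <- function(fits, outcomes, config = pipeline_config()) {
  as_metrics <- function(x) {
    if (inherits(x, "functional_network")) network_metrics(x, config) else x
  }
  complete <- vapply(fits, function(f)
    !is.null(f$baseline) && !is.null(f$free_access), TRUE)
  if (any(!complete)) {
    warning("dropping subjects missing a timepoint: ",
            paste(names(fits)[!complete], collapse = ", "))
    fits <- fits[complete]
  }
  if (length(fits) < 3) stop("need at least 3 complete subjects")
  subjects <- names(fits)
  m1 <- lapply(fits, function(f) as_metrics(f$baseline))
  m2 <- lapply(fits, function(f) as_metrics(f$free_access))
  tab1 <- do.call(rbind, lapply(m1, .metrics_row))
  tab2 <- do.call(rbind, lapply(m2, .metrics_row))
  metric_summary <- do.call(rbind, lapply(names(tab1), function(v) {
    x <- tab1[[v]]
    y <- tab2[[v]]
    ok <- is.finite(x) & is.finite(y)
    tt <- if (sum(ok) >= 2) paired_t(x[ok], y[ok]) else NULL
    data.frame(metric = v,
               baseline_mean = mean(x, na.rm = TRUE),
               baseline_sd = stats::sd(x[is.finite(x)]),
               free_access_mean = mean(y, na.rm = TRUE),
               free_access_sd = stats::sd(y[is.finite(y)]),
               t = if (is.null(tt) || tt$degenerate) NA_real_ else
                 tt$statistic,
               df = if (is.null(tt) || tt$degenerate) NA_real_ else tt$df,
               p_value = if (is.null(tt) || tt$degenerate) NA_real_ else
                 tt$p_value,
               stringsAsFactors = FALSE)
  }))
  outcomes <- outcomes[subjects]
  screen_cols <- c("mean_connection_frequency", "rich_club_coefficient",
                   "rich_club_nodes", "rich_club_min_degree",
                   "clustering_coefficient", "assortativity")
  correlations <- if (length(subjects) >= 4) {
    metric_outcome_screen(tab1[, screen_cols, drop = FALSE],
                          as.numeric(outcomes))
  } else {
    # rank correlation on fewer than 4 subjects is not meaningful
    data.frame(metric = screen_cols, rho = NA_real_, p_value = NA_real_)
  }
  membership <- function(extract, min_count, kind) {
    mt <- build_membership_table(lapply(m1, extract), lapply(m2, extract),
                                 collapse_map = config$collapse_map,
                                 min_count = min_count, kind = kind)
    list(table = mt, tests = if (nrow(mt$table) >= 2)
      membership_change_tests(mt) else NULL)
  }
  hub_membership <- membership(function(m) m$hubs, config$hub_min_count,
                               "hub")
  rc_membership <- membership(function(m) m$rich_club$members,
                              config$min_count, "rich_club")
  drinking <- list(
    n = length(outcomes),
    mean_g_per_kg = mean(outcomes),
    sd_g_per_kg = stats::sd(outcomes),
    cohens_d_vs_reference = cohens_d_one_sample(as.numeric(outcomes),
                                                config$reference_intake),
    reference_intake = config$reference_intake
  )
  structure(list(subjects = subjects, metric_summary = metric_summary,
                 correlations = correlations,
                 hub_membership = hub_membership,
                 rich_club_membership = rc_membership,
                 drinking = drinking, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", length(x$subjects), "subjects\n\n")
  cat("Drinking: mean", round(x$drinking$mean_g_per_kg, 1), "g/kg, SD",
      round(x$drinking$sd_g_per_kg, 1), "\n\n")
  cat("Network metrics (mean (SD), baseline vs free access):\n")
  ms <- x$metric_summary
  for (i in seq_len(nrow(ms))) {
    cat(sprintf("  %-28s %.2f (%.2f) vs %.2f (%.2f)",
                ms$metric[i], ms$baseline_mean[i], ms$baseline_sd[i],
                ms$free_access_mean[i], ms$free_access_sd[i]))
    if (is.finite(ms$p_value[i])) {
      cat(sprintf("  t(%d) = %.2f, p = %.3f", ms$df[i], ms$t[i],
                  ms$p_value[i]))
    }
    cat("\n")
  }
  cat("\nBaseline metric vs outcome (Spearman):\n")
  print(x$correlations, row.names = FALSE)
  for (kind in c("hub_membership", "rich_club_membership")) {
    mb <- x[[kind]]
    cat("\n", mb$table$kind, "membership counts:\n")
    print(mb$table$table, row.names = FALSE)
    if (!is.null(mb$tests) && !mb$tests$paired_t$degenerate) {
      cat(sprintf("  distribution change: t(%d) = %.2f, p = %.3f\n",
                  mb$tests$paired_t$df, mb$tests$paired_t$statistic,
                  mb$tests$paired_t$p_value))
    }
  }
  invisible(x)
}

#' End-to-end analysis of a synthetic cohort
#'
#' Fits every subject at every generated timepoint and, when both timepoints
#' are present, assembles the full [run_cohort()] report; with baseline only,
#' returns the baseline metric table and outcome screen.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [pipeline_config()].
#' @return A `cohort_report`, or (baseline-only) a list with
#'   `baseline_metrics` (data.frame) and `correlations`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  outcomes <- setNames(vapply(cohort, `[[`, 0, "outcome"), names(cohort))
  two_tp <- all(vapply(cohort, function(s)
    !is.null(s$free_access), TRUE))
  if (two_tp) {
    fits <- lapply(cohort, function(s) {
      list(baseline = run_subject(s$baseline, config)$metrics,
           free_access = run_subject(s$free_access, config)$metrics)
    })
    return(run_cohort(fits, outcomes, config))
  }
  m1 <- lapply(cohort, function(s) run_subject(s$baseline, config)$metrics)
  tab1 <- do.call(rbind, lapply(m1, .metrics_row))
  screen_cols <- c("mean_connection_frequency", "rich_club_coefficient",
                   "rich_club_nodes", "rich_club_min_degree",
                   "clustering_coefficient", "assortativity")
  list(baseline_metrics = tab1,
       correlations = metric_outcome_screen(
         tab1[, screen_cols, drop = FALSE], as.numeric(outcomes)))
}
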