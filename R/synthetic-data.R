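#' Specify planted phase-lag coupling between ROI pairs
#'
#' Each row of `pairs` plants one coupled pair: both ROIs receive a shared
#' amplitude-modulated sinusoid at `freq_hz` with a constant carrier phase lag
#' `lag_rad` (ROI `j` lags ROI `i`), scaled by
#' `amplitude * oscillator_amplitude`, on top of independent Gaussian channel
#' noise. The shared envelope is strictly positive
#' (`1 + env_depth * band-limited noise`, `env_depth < 1`) and band-limited to
#' `env_bandwidth_hz`, so the sign of the imaginary cross-spectrum is fixed by
#' the carrier lag — the analytic wPLI limit of 1 is exact — while the
#' broadened spectrum lets phase-randomized surrogates genuinely decohere
#' (a pure single-bin sinusoid would survive phase randomization with its lag
#' intact). Set `env_depth = 0` for pure sinusoids.
#'
#' @param pairs data.frame with columns `i`, `j` (ROI indices), `freq_hz`,
#'   `lag_rad` (in (-pi, pi]), `amplitude` (>= 0). When pairs share an ROI,
#'   give them distinct frequencies: same-frequency oscillators superpose
#'   into a single effective sinusoid with uncontrolled pairwise lags.
#' Slow random phase modulation (`pm_depth`, radians, same bandwidth as the
#' envelope and likewise shared within a pair) emulates the phase diffusion of
#' real neural oscillators. It leaves every within-pair lag constant — wPLI
#' stays exactly 1 — but makes the relative phase of *different* oscillators
#' drift, which matters: two deterministic carriers whose frequency difference
#' times the segment step is an integer would otherwise be perfectly
#' phase-locked across Welch segments and show up as spurious connections.
#'
#' @param noise_sd standard deviation of the independent Gaussian noise added
#'   to every channel (dimensionless amplitude units).
#' @param oscillator_amplitude global scale applied to every planted
#'   oscillator.
#' @param env_depth amplitude-modulation depth in `[0, 1)`.
#' @param env_bandwidth_hz modulation bandwidth (Hz) of envelope and phase
#'   drift; keep it below the lowest coupling frequency.
#' @param pm_depth phase-modulation depth in radians (0 disables).
#' @param pm_bandwidth_hz bandwidth of the phase drift (Hz); slower than the
#'   envelope so the instantaneous frequency stays within about one grid bin
#'   of the carrier.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(pairs, noise_sd = 1, oscillator_amplitude = 1,
                          env_depth = 0.8, env_bandwidth_hz = 1,
                          pm_depth = 3, pm_bandwidth_hz = 0.3) {
  pairs <- as.data.frame(pairs)
  needed <- c("i", "j", "freq_hz", "lag_rad", "amplitude")
  if (!all(needed %in% names(pairs))) {
    stop("pairs must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(pairs) > 0) {
    if (any(pairs$i == pairs$j)) stop("self-coupling (i == j) is not allowed")
    if (any(pairs$freq_hz <= 0)) stop("coupling frequencies must be positive")
    if (any(pairs$lag_rad <= -pi | pairs$lag_rad > pi)) {
      stop("phase lags must lie in (-pi, pi]")
    }
    if (any(pairs$amplitude < 0)) stop("coupling amplitudes must be >= 0")
    key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
    if (anyDuplicated(key)) stop("duplicate coupled pair in spec")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (oscillator_amplitude < 0) stop("oscillator_amplitude must be >= 0")
  if (env_depth < 0 || env_depth >= 1) stop("env_depth must be in [0, 1)")
  if (env_bandwidth_hz <= 0) stop("env_bandwidth_hz must be positive")
  if (pm_depth < 0) stop("pm_depth must be >= 0")
  if (pm_bandwidth_hz <= 0) stop("pm_bandwidth_hz must be positive")
  structure(list(pairs = pairs, noise_sd = noise_sd,
                 oscillator_amplitude = oscillator_amplitude,
                 env_depth = env_depth,
                 env_bandwidth_hz = env_bandwidth_hz, pm_depth = pm_depth,
                 pm_bandwidth_hz = pm_bandwidth_hz),
            class = "coupling_spec")
}

# strictly band-limited noise in [0, f_max] Hz, scaled to max |.| = 1
.lowpass_noise <- function(t_len, fs, f_max) {
  w <- stats::fft(rnorm(t_len))
  freqs <- (seq_len(t_len) - 1) * fs / t_len
  w[pmin(freqs, fs - freqs) > f_max] <- 0
  s <- Re(stats::fft(w, inverse = TRUE)) / t_len
  s / max(abs(s), .Machine$double.xmin)
}

.envelope <- function(spec, t_len, fs) {
  if (spec$env_depth == 0) return(rep(1, t_len))
  1 + spec$env_depth * .lowpass_noise(t_len, fs, spec$env_bandwidth_hz)
}

.phase_drift <- function(spec, t_len, fs) {
  if (is.null(spec$pm_depth) || spec$pm_depth == 0) return(numeric(t_len))
  spec$pm_depth * .lowpass_noise(t_len, fs, spec$pm_bandwidth_hz)
}

#' Generate ROI source series with planted phase-lag coupling
#'
#' Simulates band-limited oscillatory ROI series: every coupled pair carries a
#' common amplitude-modulated sinusoid at its planted frequency with the
#' stated constant phase lag (see [coupling_spec()]), plus independent
#' Gaussian noise on every channel. Channels not named in any pair are pure
#' noise, so uncoupled pairs share no common signal. Identical inputs
#' (including `seed`) give bit-identical output.
#'
#' @param spec a [coupling_spec()].
#' @param n_rois number of channels to generate.
#' @param duration_s record length in seconds (>= 2).
#' @param fs sampling rate, Hz. Defaults emulate a downsampled resting-state
#'   MEG record; tests use smaller values.
#' @param seed integer seed (required: reproducibility contract).
#' @param roi_labels,subject_id,timepoint passed to [source_series_set()].
#' @return A [source_series_set()].
#' @examples
#' spec <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 10,
#'                                  lag_rad = pi / 4, amplitude = 1),
#'                       noise_sd = 0)
#' x <- generate_coupled_sources(spec, n_rois = 2, duration_s = 4,
#'                               fs = 100, seed = 1)
#' @export
generate_coupled_sources <- function(spec, n_rois, duration_s, fs = 600,
                                     seed, roi_labels = NULL,
                                     subject_id = "S1",
                                     timepoint = "baseline") {
  stopifnot(inherits(spec, "coupling_spec"))
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  if (duration_s < 2) stop("duration_s must be at least 2 s")
  p <- spec$pairs
  if (nrow(p) > 0) {
    if (any(p$freq_hz >= fs / 2)) {
      bad <- p$freq_hz[p$freq_hz >= fs / 2]
      stop("coupling frequency at or above Nyquist (", fs / 2, " Hz): ",
           paste(bad, collapse = ", "))
    }
    if (any(p$i > n_rois | p$j > n_rois | p$i < 1 | p$j < 1)) {
      stop("pair indices outside 1..n_rois")
    }
  }
  t_len <- round(duration_s * fs)
  tt <- (seq_len(t_len) - 1) / fs
  set.seed(as.integer(seed))
  x <- matrix(rnorm(n_rois * t_len, sd = spec$noise_sd), n_rois, t_len)
  if (nrow(p) > 0) {
    for (k in seq_len(nrow(p))) {
      phi0 <- runif(1, 0, 2 * pi)
      env <- .envelope(spec, t_len, fs)
      theta <- 2 * pi * p$freq_hz[k] * tt + phi0 +
        .phase_drift(spec, t_len, fs)
      a <- spec$oscillator_amplitude * p$amplitude[k] * env
      x[p$i[k], ] <- x[p$i[k], ] + a * sin(theta)
      x[p$j[k], ] <- x[p$j[k], ] + a * sin(theta - p$lag_rad[k])
    }
  }
  source_series_set(x, fs = fs, roi_labels = roi_labels,
                    subject_id = subject_id, timepoint = timepoint)
}

#' Deterministic toy graphs with known metric values
#'
#' Fixture generator for the graph-metric oracles. `planted_club` returns a
#' graph whose `club_size` highest-degree nodes form a clique (each club node
#' additionally receives periphery attachments round-robin) and whose
#' periphery (a cycle) has strictly lower degree.
#'
#' @param kind one of `"star"`, `"complete"`, `"path"`, `"ring"`,
#'   `"planted_club"`, `"two_cliques"`.
#' @param n number of nodes (for `two_cliques`, per-clique size).
#' @param club_size clique size for `planted_club`.
#' @return An igraph graph with character vertex names `"n01"`, ...
#' @examples
#' g <- generate_toy_graph("planted_club", n = 20, club_size = 5)
#' @export
generate_toy_graph <- function(kind = c("star", "complete", "path", "ring",
                                        "planted_club", "two_cliques"),
                               n, club_size = NULL) {
  kind <- match.arg(kind)
  g <- switch(kind,
    star = igraph::make_star(n, mode = "undirected"),
    complete = igraph::make_full_graph(n),
    path = igraph::make_ring(n, circular = FALSE),
    ring = igraph::make_ring(n, circular = TRUE),
    two_cliques = {
      g1 <- igraph::make_full_graph(n) + igraph::make_full_graph(n)
      igraph::add_edges(g1, c(1, n + 1))
    },
    planted_club = {
      if (is.null(club_size)) stop("planted_club needs club_size")
      if (club_size > n) stop("club_size exceeds n_nodes")
      if (club_size < 3) stop("club_size must be >= 3")
      club <- seq_len(club_size)
      edges <- t(utils::combn(club, 2))
      peri <- setdiff(seq_len(n), club)
      if (length(peri) >= 2) {
        ring <- cbind(peri, c(peri[-1], peri[1]))
        if (length(peri) == 2) ring <- ring[1, , drop = FALSE]
        edges <- rbind(edges, ring)
      }
      if (length(peri) > 0) {
        # round-robin attachment keeps club degrees balanced and maximal
        edges <- rbind(edges,
                       cbind(club[((seq_along(peri) - 1) %% club_size) + 1],
                             peri))
      }
      g0 <- igraph::make_empty_graph(n, directed = FALSE)
      g0 <- igraph::add_edges(g0, t(edges))
      deg <- igraph::degree(g0)
      if (length(peri) > 0 && min(deg[club]) <= max(deg[peri])) {
        stop("planted club is not strictly above the periphery; ",
             "increase club_size relative to n")
      }
      g0
    }
  )
  igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
  g
}

#' Specify a synthetic cohort with a planted rich-club/outcome relationship
#'
#' Each subject's baseline coupling graph is a clique on
#' `planted_min_degree + 1` ROIs — the planted rich club. All club members
#' share one amplitude-modulated oscillator with node-specific carrier phase
#' offsets `m * pi / (club_size + 1)`, so every within-club pair has a
#' constant lag strictly inside (0, pi) and a wPLI analytic limit of 1; the
#' remaining ROIs are independent noise channels (degree 0 in the planted
#' graph). The scalar outcome (daily average ethanol intake, g/kg) is
#' `intercept + outcome_slope * planted_min_degree + N(0, outcome_noise_sd)`.
#' Defaults put outcomes on the observed free-access scale (mean near 4.7
#' g/kg) with a strongly negative degree-outcome coupling.
#'
#' @param n_subjects cohort size (>= 3).
#' @param n_rois channels per subject.
#' @param planted_min_degree integer vector (recycled) of planted rich-club
#'   minimum degrees; each must be >= 3 and < n_rois.
#' @param outcome_slope g/kg per degree unit (negative emulates the observed
#'   direction).
#' @param outcome_noise_sd g/kg.
#' @param intercept g/kg at zero degree.
#' @param fs,duration_s passed to the source generator.
#' @param noise_sd,coupling_amplitude channel noise SD and club oscillator
#'   amplitude.
#' @param env_depth,env_bandwidth_hz,pm_depth,pm_bandwidth_hz oscillator
#'   amplitude/phase modulation, see [coupling_spec()].
#' @param freq_pool frequencies (Hz) from which each subject/timepoint's club
#'   oscillator is drawn; keep these on the analysis frequency grid.
#' @param seed master seed; all subject-level randomness is split from it via
#'   [child_seed()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 6, n_rois = 41,
                        planted_min_degree = 3:8,
                        outcome_slope = -0.8, outcome_noise_sd = 0.5,
                        intercept = 4.7, fs = 600, duration_s = 60,
                        noise_sd = 0.2, coupling_amplitude = 1,
                        env_depth = 0.8, env_bandwidth_hz = 1, pm_depth = 3,
                        pm_bandwidth_hz = 0.3,
                        freq_pool = seq(2, 30, by = 1), seed = 1) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  d <- rep_len(as.integer(planted_min_degree), n_subjects)
  if (any(d < 3)) {
    stop("planted_min_degree must be >= 3 (club of at least 4 nodes)")
  }
  if (any(d + 1 > n_rois)) stop("planted_min_degree must be < n_rois")
  if (env_depth < 0 || env_depth >= 1) stop("env_depth must be in [0, 1)")
  structure(list(n_subjects = n_subjects, n_rois = n_rois,
                 planted_min_degree = d, outcome_slope = outcome_slope,
                 outcome_noise_sd = outcome_noise_sd, intercept = intercept,
                 fs = fs, duration_s = duration_s, noise_sd = noise_sd,
                 coupling_amplitude = coupling_amplitude,
                 env_depth = env_depth, env_bandwidth_hz = env_bandwidth_hz,
                 pm_depth = pm_depth, pm_bandwidth_hz = pm_bandwidth_hz,
                 freq_pool = freq_pool, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one shared oscillator over club members; member m gets carrier offset
# m*pi/(c+1), so all pairwise lags are in (0, pi) and wPLI -> 1 exactly
.club_series <- function(spec, members, freq_hz, t_len) {
  fs <- spec$fs
  tt <- (seq_len(t_len) - 1) / fs
  x <- matrix(rnorm(spec$n_rois * t_len, sd = spec$noise_sd),
              spec$n_rois, t_len)
  phi0 <- runif(1, 0, 2 * pi)
  mod <- list(env_depth = spec$env_depth,
              env_bandwidth_hz = spec$env_bandwidth_hz,
              pm_depth = spec$pm_depth,
              pm_bandwidth_hz = spec$pm_bandwidth_hz)
  env <- .envelope(mod, t_len, fs)
  theta <- 2 * pi * freq_hz * tt + phi0 + .phase_drift(mod, t_len, fs)
  c_size <- length(members)
  for (m in seq_along(members)) {
    x[members[m], ] <- x[members[m], ] + spec$coupling_amplitude * env *
      sin(theta - m * pi / (c_size + 1))
  }
  x
}

#' Generate a synthetic two-timepoint cohort
#'
#' Realizes a [cohort_spec()]: per subject, a baseline and a free-access
#' [source_series_set()] (independently placed clubs and frequencies at the
#' two timepoints, same planted minimum degree) plus the outcome value.
#'
#' @param spec a [cohort_spec()].
#' @param timepoints which timepoints to realize; generating baseline only
#'   halves the cost when only the naive-state screen is needed.
#' @return A list of class `synthetic_cohort`: one element per subject with
#'   fields `subject_id`, `baseline`/`free_access` (as requested), `outcome`,
#'   `planted_min_degree`, `planted_members`, `planted_freq_hz` (both for the
#'   baseline timepoint).
#' @examples
#' sp <- cohort_spec(n_subjects = 3, n_rois = 10, planted_min_degree = 3:5,
#'                   fs = 128, duration_s = 4, freq_pool = seq(4, 30, 2))
#' coh <- generate_cohort(sp, timepoints = "baseline")
#' @export
generate_cohort <- function(spec,
                            timepoints = c("baseline", "free_access")) {
  stopifnot(inherits(spec, "cohort_spec"))
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  if (any(spec$freq_pool >= spec$fs / 2)) {
    stop("freq_pool contains frequencies at or above Nyquist")
  }
  t_len <- round(spec$duration_s * spec$fs)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%d", s)
    d <- spec$planted_min_degree[s]
    entry <- list(subject_id = sid, planted_min_degree = d)
    set.seed(child_seed(spec$seed, "outcome", sid))
    entry$outcome <- spec$intercept + spec$outcome_slope * d +
      rnorm(1, sd = spec$outcome_noise_sd)
    for (tp in timepoints) {
      set.seed(child_seed(spec$seed, "sources", sid, tp))
      members <- sort(sample.int(spec$n_rois, d + 1))
      freq <- spec$freq_pool[sample.int(length(spec$freq_pool), 1)]
      entry[[tp]] <- source_series_set(
        .club_series(spec, members, freq, t_len), fs = spec$fs,
        subject_id = sid, timepoint = tp
      )
      if (tp == "baseline" || is.null(entry$planted_members)) {
        entry$planted_members <- members
        entry$planted_freq_hz <- freq
      }
    }
    subjects[[s]] <- entry
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  structure(subjects, class = "synthetic_cohort", spec = spec)
}

#' Outcome table of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @return data.frame with `subject_id`, `outcome_g_per_kg`,
#'   `planted_min_degree`.
#' @export
cohort_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    outcome_g_per_kg = vapply(cohort, `[[`, 0, "outcome"),
    planted_min_degree = vapply(cohort, function(s)
      as.numeric(s$planted_min_degree), 0),
    row.names = NULL
  )
}
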