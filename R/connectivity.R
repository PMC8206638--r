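#' Spectral estimation parameters
#'
#' Welch-style segmented cross-spectra underlie the wPLI estimator: the series
#' is cut into Hann-tapered segments of `segment_length_s` seconds with
#' `overlap_fraction` overlap, and each segment contributes one complex
#' cross-spectral value per frequency bin. The frequency grid is the FFT grid
#' of a segment (spacing `1 / segment_length_s` Hz) restricted to
#' `[f_min, f_max]`; the defaults analyse 1-80 Hz at 0.5 Hz resolution.
#'
#' @param f_min,f_max analysis band, Hz. `f_max` must not exceed the Nyquist
#'   frequency of the data it is applied to.
#' @param segment_length_s segment length, seconds.
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @param window taper name; only `"hann"` is implemented.
#' @return An object of class `spectral_params`. The implied grid step
#'   (`1 / segment_length_s`) is stored as `grid_step`.
#' @export
spectral_params <- function(f_min = 1, f_max = 80, segment_length_s = 2,
                            overlap_fraction = 0.5, window = "hann") {
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  window <- match.arg(window, "hann")
  structure(list(f_min = f_min, f_max = f_max,
                 segment_length_s = segment_length_s,
                 overlap_fraction = overlap_fraction, window = window,
                 grid_step = 1 / segment_length_s),
            class = "spectral_params")
}

.hann <- function(L) 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))

.segment_plan <- function(t_len, fs, params, min_segments = 8) {
  L <- round(params$segment_length_s * fs)
  if (L < 4) stop("segment_length_s too short for this sampling rate")
  step <- max(1L, round(L * (1 - params$overlap_fraction)))
  n_seg <- if (t_len < L) 0L else (t_len - L) %/% step + 1L
  if (n_seg < min_segments) {
    stop("series too short: ", t_len, " samples give ", n_seg,
         " segments; need >= ", min_segments, " (minimum length ",
         L + (min_segments - 1) * step, " samples)")
  }
  freqs_all <- (seq_len(L) - 1) * fs / L
  if (params$f_max > fs / 2) {
    stop("f_max (", params$f_max, " Hz) exceeds Nyquist (", fs / 2, " Hz)")
  }
  band <- which(freqs_all >= params$f_min & freqs_all <= params$f_max &
                  freqs_all <= fs / 2)
  if (length(band) < 1) stop("no frequency bins inside [f_min, f_max]")
  list(L = L, step = step, n_seg = n_seg, band = band,
       freqs = freqs_all[band])
}

# Hann-tapered segment FFTs restricted to the analysis band:
# complex matrix n_freq x n_seg
.segment_ffts <- function(x, plan) {
  starts <- (seq_len(plan$n_seg) - 1L) * plan$step
  idx <- outer(seq_len(plan$L), starts, `+`)
  seg <- matrix(x[idx], plan$L, plan$n_seg) * .hann(plan$L)
  stats::mvfft(seg)[plan$band, , drop = FALSE]
}

#' Per-segment complex cross-spectra of two series
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate, Hz.
#' @param params a [spectral_params()].
#' @return A list of class `cross_spectrum`: `freqs` (Hz grid), `cross`
#'   (complex matrix, frequency x segment, with the convention
#'   `S = FFT(x) * Conj(FFT(y))` so a positive phase means `y` lags `x`),
#'   `n_segments`, `fs`.
#' @examples
#' t <- seq(0, 4, by = 1 / 100)[-1]
#' cs <- cross_spectrum(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t - pi / 2),
#'                      fs = 100, params = spectral_params(1, 40, 1))
#' @export
cross_spectrum <- function(x, y, fs, params = spectral_params()) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  plan <- .segment_plan(length(x), fs, params)
  fx <- .segment_ffts(x, plan)
  fy <- .segment_ffts(y, plan)
  structure(list(freqs = plan$freqs, cross = fx * Conj(fy),
                 n_segments = plan$n_seg, fs = fs, params = params),
            class = "cross_spectrum")
}

.wpli_from_cross <- function(m) {
  im <- Im(m)
  num <- abs(rowMeans(im))
  den <- rowMeans(abs(im))
  scale <- rowMeans(Mod(m))
  degenerate <- den <= 1e-10 * pmax(scale, .Machine$double.xmin)
  w <- ifelse(degenerate, 0, num / pmax(den, .Machine$double.xmin))
  list(wpli = pmin(pmax(w, 0), 1), degenerate = degenerate)
}

#' Weighted phase lag index spectrum
#'
#' The wPLI estimator over spectral segments:
#' `|mean_k Im S_xy(f, k)| / mean_k |Im S_xy(f, k)|`. It is insensitive to
#' source amplitude and to exactly zero-lag coupling; frequencies where the
#' mean absolute imaginary part vanishes (e.g. identical zero-lag signals)
#' return 0 with a degenerate-denominator flag, so volume-conduction-like
#' coupling can never be called a connection.
#'
#' @param cs a [cross_spectrum()] (or complex frequency x segment matrix).
#' @param pair optional `c(roi_i, roi_j)` labels carried through.
#' @return An object of class `wpli_spectrum`: `freqs`, `wpli` in `[0, 1]`,
#'   logical `degenerate` per frequency, `pair`.
#' @export
wpli <- function(cs, pair = NULL) {
  if (inherits(cs, "cross_spectrum")) {
    m <- cs$cross
    freqs <- cs$freqs
  } else {
    m <- as.matrix(cs)
    freqs <- seq_len(nrow(m))
  }
  if (ncol(m) < 2) stop("wPLI undefined for a single segment")
  res <- .wpli_from_cross(m)
  structure(list(freqs = freqs, wpli = res$wpli,
                 degenerate = res$degenerate, pair = pair),
            class = "wpli_spectrum")
}

#' Phase-randomized surrogate of a time series
#'
#' Returns a series with exactly the original amplitude spectrum but uniformly
#' random Fourier phases (conjugate-symmetric, DC and Nyquist bins kept
#' unmodified), destroying cross-series phase relations while preserving each
#' series' autocorrelation.
#'
#' @param x real-valued series.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (callers that loop over draws seed once outside).
#' @return Numeric series of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  if (!all(is.finite(x))) stop("non-finite values in input series")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(x)
  if (n < 3) return(x)
  xf <- stats::fft(x)
  half <- if (n %% 2 == 0) 2:(n / 2) else 2:((n + 1) / 2)
  phases <- runif(length(half), 0, 2 * pi)
  xf[half] <- Mod(xf[half]) * exp(1i * phases)
  xf[n + 2 - half] <- Conj(xf[half])
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Per-subject surrogate null distribution of wPLI
#'
#' Draws `n_pairs` unique (ROI-pair, realization) combinations — each draw
#' phase-randomizes both members of a uniformly sampled ROI pair with fresh
#' independent phases — computes the wPLI spectrum of each surrogate pair, and
#' pools them into a per-frequency mean (`mu`) and SD (`sigma`). One null is
#' built per subject, pooled across all ROI pairs.
#'
#' @param series_set a [source_series_set()].
#' @param params a [spectral_params()].
#' @param n_pairs number of surrogate pairs (default 5000; at least 100).
#' @param seed integer seed.
#' @return An object of class `surrogate_null`: `subject_id`, `freqs`, `mu`,
#'   `sigma`, `n_pairs`.
#' @export
build_surrogate_null <- function(series_set, params = spectral_params(),
                                 n_pairs = 5000, seed = NULL) {
  stopifnot(inherits(series_set, "source_series_set"))
  if (n_pairs < 100) stop("n_pairs must be >= 100")
  n <- nrow(series_set$data)
  plan <- .segment_plan(ncol(series_set$data), series_set$fs, params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pair_table <- which(upper.tri(diag(n)), arr.ind = TRUE)
  draw <- pair_table[sample.int(nrow(pair_table), n_pairs, replace = TRUE), ,
                     drop = FALSE]
  nf <- length(plan$freqs)
  s1 <- numeric(nf)
  s2 <- numeric(nf)
  for (k in seq_len(n_pairs)) {
    xs <- phase_randomize(series_set$data[draw[k, 1], ])
    ys <- phase_randomize(series_set$data[draw[k, 2], ])
    w <- .wpli_from_cross(.segment_ffts(xs, plan) *
                            Conj(.segment_ffts(ys, plan)))$wpli
    s1 <- s1 + w
    s2 <- s2 + w * w
  }
  mu <- s1 / n_pairs
  sigma <- sqrt(pmax(0, (s2 - n_pairs * mu^2) / (n_pairs - 1)))
  if (any(sigma <= 0)) {
    stop("degenerate surrogate null: sigma = 0 at ",
         sum(sigma <= 0), " frequencies (broken surrogates?)")
  }
  structure(list(subject_id = series_set$subject_id, freqs = plan$freqs,
                 mu = mu, sigma = sigma, n_pairs = n_pairs),
            class = "surrogate_null")
}

#' Call one connection from a real wPLI spectrum and a surrogate null
#'
#' Computes `z(f) = (wpli(f) - mu(f)) / sigma(f)` on the shared grid,
#' operationalizes the connection at the frequency of maximal `z` (ties broken
#' toward the lowest frequency), and gates it at `gate` null SDs.
#'
#' @param real a [wpli_spectrum()].
#' @param null a [build_surrogate_null()] result on the same frequency grid.
#' @param gate threshold in null-SD units (default 2.5).
#' @return An object of class `edge_candidate`: `pair`, `f_star` (Hz),
#'   `z_max`, `connected`.
#' @export
select_connection <- function(real, null, gate = 2.5) {
  stopifnot(inherits(real, "wpli_spectrum"), inherits(null, "surrogate_null"))
  if (length(real$freqs) != length(null$freqs) ||
      max(abs(real$freqs - null$freqs)) > 1e-9) {
    stop("frequency grids of real spectrum and null do not match")
  }
  z <- (real$wpli - null$mu) / null$sigma
  i <- which.max(z) # first index at ties = lowest frequency
  structure(list(pair = real$pair, f_star = real$freqs[i], z_max = z[i],
                 connected = z[i] >= gate),
            class = "edge_candidate")
}

#' Connection candidates for every ROI pair of a subject
#'
#' Computes the wPLI spectrum of all N(N-1)/2 ROI pairs (reusing one set of
#' per-ROI segment FFTs), calls each against the subject's surrogate null, and
#' returns the full candidate table.
#'
#' @inheritParams build_surrogate_null
#' @param null a [build_surrogate_null()] for this subject.
#' @param gate threshold in null-SD units.
#' @return data.frame with columns `roi_i`, `roi_j` (labels, i before j in
#'   label-index order), `f_star_hz`, `z_max`, `connected`.
#' @export
connection_candidates <- function(series_set, null,
                                  params = spectral_params(), gate = 2.5) {
  stopifnot(inherits(series_set, "source_series_set"),
            inherits(null, "surrogate_null"))
  plan <- .segment_plan(ncol(series_set$data), series_set$fs, params)
  if (length(plan$freqs) != length(null$freqs) ||
      max(abs(plan$freqs - null$freqs)) > 1e-9) {
    stop("frequency grid of series does not match the null's grid")
  }
  n <- nrow(series_set$data)
  ffts <- lapply(seq_len(n), function(i)
    .segment_ffts(series_set$data[i, ], plan))
  pair_table <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pair_table <- pair_table[order(pair_table[, 1], pair_table[, 2]), ,
                           drop = FALSE]
  m <- nrow(pair_table)
  f_star <- numeric(m)
  z_max <- numeric(m)
  for (k in seq_len(m)) {
    w <- .wpli_from_cross(ffts[[pair_table[k, 1]]] *
                            Conj(ffts[[pair_table[k, 2]]]))$wpli
    z <- (w - null$mu) / null$sigma
    i <- which.max(z)
    f_star[k] <- plan$freqs[i]
    z_max[k] <- z[i]
  }
  data.frame(roi_i = series_set$roi_labels[pair_table[, 1]],
             roi_j = series_set$roi_labels[pair_table[, 2]],
             f_star_hz = f_star, z_max = z_max,
             connected = z_max >= gate,
             stringsAsFactors = FALSE)
}
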