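params_test <- spectral_params(f_min = 2, f_max = 40, segment_length_s = 1)

test_that("cross-spectrum phase reflects the planted lag", {
  fs <- 100
  tt <- (0:1199) / fs
  x <- sin(2 * pi * 10 * tt)
  # identical signals: phase 0 at the 10 Hz bin
  cs <- cross_spectrum(x, x, fs, params_test)
  i10 <- which(cs$freqs == 10)
  expect_equal(Arg(mean(cs$cross[i10, ])), 0, tolerance = 1e-6)
  # quarter-cycle delay: phase +pi/2 (y lags x)
  y <- sin(2 * pi * 10 * tt - pi / 2)
  cs2 <- cross_spectrum(x, y, fs, params_test)
  expect_equal(abs(Arg(mean(cs2$cross[i10, ]))), pi / 2, tolerance = 1e-3)
})

test_that("segment bookkeeping and minimum-length error", {
  fs <- 64
  set.seed(1)
  x <- rnorm(16 * fs)
  cs <- cross_spectrum(x, rnorm(length(x)), fs,
                       spectral_params(2, 30, segment_length_s = 1))
  expect_equal(cs$n_segments, 31) # 50% overlap of 1 s segments in 16 s
  expect_equal(ncol(cs$cross), 31)
  expect_error(
    cross_spectrum(x[1:200], x[1:200], fs,
                   spectral_params(2, 30, segment_length_s = 1)),
    "minimum length"
  )
})

test_that("wPLI analytic limits and degenerate conventions hold", {
  # constant lag pi/4, noiseless: wPLI = 1 at the planted frequency
  spec <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 10,
                                   lag_rad = pi / 4, amplitude = 1),
                        noise_sd = 0)
  x <- generate_coupled_sources(spec, 2, duration_s = 12, fs = 100, seed = 1)
  w <- wpli(cross_spectrum(x$data[1, ], x$data[2, ], 100, params_test))
  expect_equal(w$wpli[w$freqs == 10], 1, tolerance = 1e-9)

  # zero-lag identical signals: Im = 0, wPLI = 0 with degenerate flag
  spec0 <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 10,
                                    lag_rad = 0, amplitude = 1),
                         noise_sd = 0)
  x0 <- generate_coupled_sources(spec0, 2, duration_s = 12, fs = 100,
                                 seed = 1)
  w0 <- wpli(cross_spectrum(x0$data[1, ], x0$data[2, ], 100, params_test))
  expect_equal(w0$wpli[w0$freqs == 10], 0)
  expect_true(w0$degenerate[w0$freqs == 10])

  # perfect cancellation: imaginary parts {+a, -a}
  m <- matrix(complex(real = 0, imaginary = c(2, -2, 3, -3)), 1)
  expect_equal(wpli(m)$wpli, 0)

  # single segment is undefined
  expect_error(wpli(matrix(1i, 2, 1)), "single segment")
})

test_that("wPLI is amplitude-invariant and symmetric", {
  set.seed(42)
  fs <- 64
  x <- rnorm(16 * fs)
  y <- rnorm(16 * fs)
  p <- spectral_params(2, 30, 1)
  w1 <- wpli(cross_spectrum(x, y, fs, p))$wpli
  w2 <- wpli(cross_spectrum(3.7 * x, 0.2 * y, fs, p))$wpli
  expect_equal(w1, w2, tolerance = 1e-12)
  wyx <- wpli(cross_spectrum(y, x, fs, p))$wpli
  expect_equal(w1, wyx, tolerance = 1e-12)
})

test_that("wPLI of independent noise is small on long records", {
  p <- spectral_params(2, 30, 1)
  means <- vapply(1:20, function(s) {
    set.seed(s)
    mean(wpli(cross_spectrum(rnorm(3200), rnorm(3200), 64, p))$wpli)
  }, 0)
  expect_lt(mean(means), 0.2)
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(9)
  for (n in c(1000, 1001)) { # even and odd lengths
    x <- rnorm(n)
    s <- phase_randomize(x, seed = 11)
    rel <- abs(Mod(fft(s)) - Mod(fft(x))) / pmax(Mod(fft(x)), 1e-12)
    expect_lt(max(rel), 1e-9)
    expect_true(all(abs(Im(fft(s)[1])) < 1e-9)) # DC untouched
  }
  # constant series: all energy at DC, surrogate is the same constant
  expect_equal(phase_randomize(rep(2.5, 100), seed = 1), rep(2.5, 100),
               tolerance = 1e-12)
  # determinism
  set.seed(1)
  x <- rnorm(500)
  expect_identical(phase_randomize(x, seed = 3), phase_randomize(x, seed = 3))
  expect_error(phase_randomize(c(1, NA)), "non-finite")
})

test_that("surrogate null records its draw count and is positive", {
  set.seed(2)
  x <- source_series_set(matrix(rnorm(3 * 1200), 3), fs = 100)
  null <- build_surrogate_null(x, params_test, n_pairs = 120, seed = 5)
  expect_equal(null$n_pairs, 120)
  expect_true(all(null$mu > 0)) # wPLI >= 0 and biased up under H0
  expect_true(all(null$sigma > 0))
  expect_error(build_surrogate_null(x, params_test, n_pairs = 50), ">= 100")
})

test_that("null means shrink with more segments and agree across seeds", {
  set.seed(4)
  x <- source_series_set(matrix(rnorm(2 * 2400), 2), fs = 100)
  p_few <- spectral_params(2, 40, segment_length_s = 2) # 23 segments
  p_many <- spectral_params(2, 40, segment_length_s = 0.5) # 95 segments
  n_few <- build_surrogate_null(x, p_few, n_pairs = 150, seed = 1)
  n_many <- build_surrogate_null(x, p_many, n_pairs = 150, seed = 1)
  expect_lt(mean(n_many$mu), mean(n_few$mu))
  # disjoint seeds: mu curves agree at resampling precision
  a <- build_surrogate_null(x, p_few, n_pairs = 150, seed = 10)
  b <- build_surrogate_null(x, p_few, n_pairs = 150, seed = 20)
  se <- pmax(a$sigma, b$sigma) / sqrt(150)
  expect_gte(mean(abs(a$mu - b$mu) <= 3 * se), 0.97)
  expect_true(all(abs(a$mu - b$mu) <= 5 * se))
})

test_that("connection selection applies the SD gate and tie rule", {
  null <- structure(list(subject_id = "S", freqs = c(6, 10, 20),
                         mu = c(0.2, 0.2, 0.2), sigma = c(0.1, 0.1, 0.1),
                         n_pairs = 100), class = "surrogate_null")
  # wpli == mu everywhere: z_max = 0, unconnected
  flat <- structure(list(freqs = c(6, 10, 20), wpli = c(0.2, 0.2, 0.2),
                         degenerate = rep(FALSE, 3), pair = c("a", "b")),
                    class = "wpli_spectrum")
  e <- select_connection(flat, null)
  expect_equal(e$z_max, 0)
  expect_false(e$connected)
  # two equal maxima at 6 and 20 Hz: the lower frequency wins
  tie <- structure(list(freqs = c(6, 10, 20), wpli = c(0.5, 0.2, 0.5),
                        degenerate = rep(FALSE, 3), pair = c("a", "b")),
                   class = "wpli_spectrum")
  e2 <- select_connection(tie, null)
  expect_equal(e2$f_star, 6)
  expect_true(e2$connected)
  # mismatched grids error
  bad <- structure(list(freqs = c(6, 10, 21), wpli = c(0.5, 0.2, 0.5),
                        degenerate = rep(FALSE, 3), pair = NULL),
                   class = "wpli_spectrum")
  expect_error(select_connection(bad, null), "grid")
})

test_that("candidate table covers all pairs once, labels ordered", {
  set.seed(6)
  x <- source_series_set(matrix(rnorm(4 * 1200), 4), fs = 100)
  null <- build_surrogate_null(x, params_test, n_pairs = 100, seed = 2)
  cand <- connection_candidates(x, null, params_test)
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$roi_i < cand$roi_j))
  expect_false(anyDuplicated(pair_key(cand$roi_i, cand$roi_j)) > 0)
})
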