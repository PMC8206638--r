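test_that("coupling_spec validates pair specifications", {
  ok <- data.frame(i = 1, j = 2, freq_hz = 10, lag_rad = pi / 4,
                   amplitude = 1)
  expect_s3_class(coupling_spec(ok), "coupling_spec")
  expect_error(coupling_spec(transform(ok, j = 1)), "self-coupling")
  expect_error(coupling_spec(rbind(ok, transform(ok, i = 2, j = 1))),
               "duplicate")
  expect_error(coupling_spec(transform(ok, lag_rad = -pi)), "lags")
  expect_error(coupling_spec(transform(ok, amplitude = -1)), "amplitudes")
  expect_error(coupling_spec(ok, env_depth = 1), "env_depth")
})

test_that("generated sources honour the determinism contract", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 8,
                                   lag_rad = pi / 3, amplitude = 1))
  a <- generate_coupled_sources(spec, 3, duration_s = 3, fs = 64, seed = 7)
  b <- generate_coupled_sources(spec, 3, duration_s = 3, fs = 64, seed = 7)
  c <- generate_coupled_sources(spec, 3, duration_s = 3, fs = 64, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("frequencies at or above Nyquist are rejected with a message", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 32,
                                   lag_rad = pi / 4, amplitude = 1))
  expect_error(
    generate_coupled_sources(spec, 2, duration_s = 3, fs = 64, seed = 1),
    "Nyquist"
  )
})

test_that("uncoupled channels are independent noise", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, freq_hz = 8,
                                   lag_rad = pi / 3, amplitude = 1))
  x <- generate_coupled_sources(spec, 4, duration_s = 10, fs = 64, seed = 3)
  # channels 3 and 4 carry no oscillator: correlation at noise level
  expect_lt(abs(stats::cor(x$data[3, ], x$data[4, ])), 0.1)
  # coupled channels share the oscillator (cos(pi/3) carrier alignment
  # diluted by envelope variance and unit noise)
  expect_gt(abs(stats::cor(x$data[1, ], x$data[2, ])), 0.1)
})

test_that("toy graphs have their defining shapes", {
  g <- generate_toy_graph("complete", 4)
  expect_equal(igraph::ecount(g), 6)
  expect_true(all(igraph::degree(g) == 3))
  s <- generate_toy_graph("star", 5)
  expect_equal(unname(sort(igraph::degree(s))), c(1, 1, 1, 1, 4))
  pc <- generate_toy_graph("planted_club", 20, club_size = 5)
  deg <- igraph::degree(pc)
  expect_setequal(order(-deg)[1:5], 1:5) # club nodes are the top degrees
  expect_gt(min(deg[1:5]), max(deg[6:20]))
  # the club is a clique
  expect_equal(igraph::ecount(igraph::induced_subgraph(pc, 1:5)), 10)
  expect_error(generate_toy_graph("planted_club", 4, club_size = 5),
               "exceeds")
})

test_that("cohort generation is reproducible element-wise", {
  sp3 <- cohort_spec(n_subjects = 3, n_rois = 8, planted_min_degree = 3:5,
                     fs = 64, duration_s = 4, freq_pool = seq(4, 20, 2),
                     seed = 5)
  sp4 <- cohort_spec(n_subjects = 4, n_rois = 8,
                     planted_min_degree = c(3:5, 4),
                     fs = 64, duration_s = 4, freq_pool = seq(4, 20, 2),
                     seed = 5)
  c3 <- generate_cohort(sp3, timepoints = "baseline")
  c4 <- generate_cohort(sp4, timepoints = "baseline")
  # adding a subject does not change earlier subjects (per-subject seeds)
  expect_identical(c3$S2$baseline$data, c4$S2$baseline$data)
  expect_identical(c3$S1$outcome, c4$S1$outcome)
})

test_that("cohort outcomes follow the planted linear model", {
  sp <- cohort_spec(n_subjects = 6, n_rois = 10, planted_min_degree = 3:8,
                    outcome_slope = -0.8, outcome_noise_sd = 0,
                    fs = 64, duration_s = 4, freq_pool = seq(4, 20, 2),
                    seed = 1)
  out <- cohort_outcomes(generate_cohort(sp, timepoints = "baseline"))
  expect_equal(out$outcome_g_per_kg, 4.7 - 0.8 * (3:8), tolerance = 1e-12)
  # noiseless monotone limit: rank correlation with planted degree is -1
  st <- spearman_test(out$planted_min_degree, out$outcome_g_per_kg)
  expect_equal(st$statistic, -1)
})

test_that("cohort baseline realizes the planted club structure", {
  sp <- cohort_spec(n_subjects = 3, n_rois = 10, planted_min_degree = c(3, 4, 5),
                    fs = 64, duration_s = 8, noise_sd = 0.2,
                    freq_pool = seq(4, 20, 2), seed = 2)
  coh <- generate_cohort(sp, timepoints = "baseline")
  for (s in coh) {
    expect_length(s$planted_members, s$planted_min_degree + 1)
    # club members carry the shared oscillator: pairwise correlation of
    # band-passed members well above noise pairs
    m <- s$planted_members
    others <- setdiff(seq_len(10), m)[1:2]
    expect_gt(abs(stats::cor(s$baseline$data[m[1], ],
                             s$baseline$data[m[2], ])),
              abs(stats::cor(s$baseline$data[others[1], ],
                             s$baseline$data[others[2], ])))
  }
})

test_that("zero-amplitude coupling stays below the gate at its frequency", {
  # null-calibration example: with no planted signal the fixed-frequency
  # z score exceeds 2.5 SD only at the null rate (<= 5% of seeded repeats)
  params <- spectral_params(f_min = 2, f_max = 40, segment_length_s = 1)
  z <- vapply(1:40, null_pair_z, 0, params = params)
  expect_gte(mean(z < 2.5), 0.95)
})
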