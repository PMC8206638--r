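# Brute-force oracles, independent of the igraph-backed implementations:
# everything here works on the raw adjacency matrix with naive algorithms.

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
}

# per-node triangle density, averaged; C_i = 0 for degree < 2
brute_clustering <- function(g) {
  a <- adj_of(g)
  n <- nrow(a)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  }, 0)
  mean(ci)
}

# mean inverse shortest path via Floyd-Warshall, 1/Inf = 0
brute_efficiency <- function(g) {
  a <- adj_of(g)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Pearson correlation over endpoint degrees, edges in both orientations
brute_assortativity <- function(g) {
  a <- adj_of(g)
  deg <- rowSums(a)
  e <- which(a > 0, arr.ind = TRUE) # both orientations
  suppressWarnings(stats::cor(deg[e[, 1]], deg[e[, 2]])) # NA if regular
}

# rich-club density among nodes of degree > k
brute_phi <- function(g, k) {
  a <- adj_of(g)
  deg <- rowSums(a)
  idx <- which(deg > k)
  nk <- length(idx)
  if (nk < 2) return(NA_real_)
  sum(a[idx, idx]) / (nk * (nk - 1))
}

toy_fixtures <- function() {
  list(complete4 = generate_toy_graph("complete", 4),
       star5 = generate_toy_graph("star", 5),
       path3 = generate_toy_graph("path", 3),
       ring6 = generate_toy_graph("ring", 6),
       planted20 = generate_toy_graph("planted_club", 20, club_size = 5),
       twocliques5 = generate_toy_graph("two_cliques", 5))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# 16-edge planted graph on 12 nodes (= the S = 2.5 target edge count),
# distinct even frequencies, segment step incommensurate with every
# frequency spacing below 10 Hz
recovery_fixture <- function(seed) {
  ring <- cbind(1:12, c(2:12, 1))
  chords <- rbind(c(1, 7), c(2, 8), c(4, 10), c(5, 11))
  pairs <- data.frame(i = c(ring[, 1], chords[, 1]),
                      j = c(ring[, 2], chords[, 2]),
                      freq_hz = seq(6, 36, by = 2),
                      lag_rad = pi / 3, amplitude = 1)
  params <- spectral_params(f_min = 2, f_max = 40, segment_length_s = 0.5,
                            overlap_fraction = 0.4)
  series <- generate_coupled_sources(coupling_spec(pairs, noise_sd = 0.3),
                                     n_rois = 12, duration_s = 24, fs = 200,
                                     seed = seed)
  list(pairs = pairs, params = params, series = series)
}

# pure-noise two-channel set and its fixed-frequency z score
null_pair_z <- function(seed, params, fs = 100, duration_s = 12,
                        at_hz = 20) {
  spec0 <- coupling_spec(data.frame(i = integer(), j = integer(),
                                    freq_hz = numeric(), lag_rad = numeric(),
                                    amplitude = numeric()))
  x <- generate_coupled_sources(spec0, n_rois = 2, duration_s = duration_s,
                                fs = fs, seed = seed)
  null <- build_surrogate_null(x, params = params, n_pairs = 100,
                               seed = seed + 5000)
  w <- wpli(cross_spectrum(x$data[1, ], x$data[2, ], fs = fs,
                           params = params))
  z <- (w$wpli - null$mu) / null$sigma
  z[which.min(abs(w$freqs - at_hz))]
}
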