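# ICA correlation patterns, regression weights, signed-quartile meta-states.

# wFC-shaped series from a known mixing of orthogonal patterns with
# independent non-Gaussian (Laplace) weights
planted_mixing <- function(n_windows = 400, n_pairs = 60, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n_pairs * 4), n_pairs, 4)))
  patterns <- t(q) # 4 x n_pairs, orthonormal rows
  w <- matrix(sign(runif(n_windows * 4) - 0.5) * rexp(n_windows * 4),
              n_windows, 4)
  series <- structure(list(
    vectors = w %*% patterns, window_width_frames = 70L, step_frames = 1L,
    window_start_frames = seq_len(n_windows), n_neurons = 12L,
    sampling_period_s = 0.1506, n_zero_variance = 0L), class = "wfc_series")
  list(series = series, patterns = patterns, weights = w)
}

test_that("ICA recovers planted orthogonal patterns up to order and sign", {
  pm <- planted_mixing(seed = 3)
  basis <- extract_correlation_patterns(pm$series, seed = 5)
  expect_true(basis$converged)
  cosim <- abs(tcrossprod(
    basis$patterns / sqrt(rowSums(basis$patterns^2)),
    pm$patterns / sqrt(rowSums(pm$patterns^2))))
  # each planted pattern matched by exactly one recovered component
  expect_true(all(apply(cosim, 2, max) > 0.95))
  expect_identical(sort(apply(cosim, 2, which.max)), 1:4)

  # determinism under the same seed
  basis2 <- extract_correlation_patterns(pm$series, seed = 5)
  expect_identical(basis$patterns, basis2$patterns)

  # sign convention: every weight series has nonnegative skewness
  sk <- apply(basis$sources, 2, function(v) mean((v - mean(v))^3))
  expect_true(all(sk >= 0))
})

test_that("ICA contracts on degenerate input", {
  pm <- planted_mixing(n_windows = 3, seed = 1)
  pm$series$vectors <- pm$series$vectors[1:3, ]
  pm$series$window_start_frames <- 1:3
  expect_error(extract_correlation_patterns(pm$series),
               class = "fcdyn_invalid_input")

  # rank-deficient series (rank 2 < 4 components)
  set.seed(2)
  low <- matrix(rnorm(100 * 2), 100, 2) %*% matrix(rnorm(2 * 30), 2, 30)
  s <- structure(list(vectors = low, window_width_frames = 70L,
                      step_frames = 1L, window_start_frames = 1:100,
                      n_neurons = 6L, sampling_period_s = 0.1506,
                      n_zero_variance = 0L), class = "wfc_series")
  expect_error(extract_correlation_patterns(s),
               class = "fcdyn_degenerate_basis")
})

test_that("weights reproduce the basis and match the normal equations", {
  pm <- planted_mixing(seed = 7)
  basis <- extract_correlation_patterns(pm$series, seed = 2)
  p <- basis$patterns

  # row equal to pattern 2 -> weights (0, 1, 0, 0)
  s1 <- pm$series
  s1$vectors <- rbind(p[2, ], 2 * p[1, ] - 3 * p[4, ])
  w <- compute_weights(s1, basis)
  gram <- tcrossprod(p)
  expect_equal(as.numeric(w[1, ]),
               as.numeric(solve(gram, p %*% p[2, ])), tolerance = 1e-9)
  expect_equal(as.numeric(w[2, ]),
               as.numeric(solve(gram, p %*% (2 * p[1, ] - 3 * p[4, ]))),
               tolerance = 1e-9)

  # independent least-squares oracle on random rows (qr.solve on t(p))
  set.seed(4)
  s2 <- pm$series
  s2$vectors <- matrix(rnorm(5 * ncol(p)), 5, ncol(p))
  w2 <- compute_weights(s2, basis)
  for (i in 1:5) {
    expect_equal(as.numeric(w2[i, ]),
                 as.numeric(qr.solve(t(p), s2$vectors[i, ])),
                 tolerance = 1e-8)
  }

  # degenerate basis signals
  bad <- basis
  bad$patterns[2, ] <- bad$patterns[1, ]
  expect_error(compute_weights(s2, bad), class = "fcdyn_degenerate_basis")
})

test_that("signed quartile discretization matches its definition", {
  # equal occupancy on 1..8
  w <- cbind(1:8, 1:8, 1:8, 1:8)
  expect_identical(discretize_weights(w)[, 1], rep(1:4, each = 2))

  # sign mirror symmetry
  set.seed(6)
  w2 <- matrix(rnorm(200), 50, 4)
  expect_identical(discretize_weights(-w2), -discretize_weights(w2))

  # rank-then-bin oracle on random weights
  codes <- discretize_weights(w2)
  for (j in 1:4) {
    expect_identical(codes[, j], oracle_signed_quartiles(w2[, j]))
  }

  # zeros map to +1 (messaged), all-zero component errors
  w3 <- w2
  w3[5, 2] <- 0
  expect_message(c3 <- discretize_weights(w3), "exact-zero")
  expect_identical(c3[5, 2], 1L)
  w4 <- w2
  w4[, 3] <- 0
  expect_error(discretize_weights(w4), class = "fcdyn_degenerate_component")

  # strictly positive rescaling of a component leaves its codes unchanged
  w5 <- w2
  w5[, 1] <- w5[, 1] * 123.4
  expect_identical(discretize_weights(w5), codes)
})

test_that("run-length encoding is exact and conserving", {
  a <- c(1L, 1L, 1L, 1L)
  b <- c(2L, 1L, 1L, 1L)
  codes <- rbind(a, a, b, b, a)
  runs <- metastate_sequence(codes)
  expect_identical(runs$runs$start, c(1L, 3L, 5L)) # spec's 0-based (0,2,4)
  expect_identical(runs$runs$length, c(2L, 2L, 1L))
  expect_identical(runs$representatives[2, ], b)

  # constant codes: a single run
  const <- matrix(1L, 40, 4)
  expect_identical(nrow(metastate_sequence(const)$runs), 1L)

  # property: run lengths always concatenate to n_windows
  for (s in 1:5) {
    codes_r <- random_codes(120, seed = s)
    r <- metastate_sequence(codes_r)
    expect_identical(sum(r$runs$length), 120L)
    expect_lte(length(unique(r$runs$state)), min(120L, 4096L))
  }
  expect_error(metastate_sequence(matrix(0L, 3, 4)),
               class = "fcdyn_invalid_input")
})

test_that("planted two-state dynamics yield recoverable hub meta-states", {
  sim <- simulate_fluorescence(two_state_sim(seed = 12, n_frames = 900,
                                             mean_dwell = 150))
  fm <- subtract_baseline(sim$fluorescence)
  s <- sliding_window_fc(fm, 70)
  basis <- extract_correlation_patterns(s, seed = 1)
  expect_true(basis$converged)
  runs <- metastate_sequence(discretize_weights(compute_weights(s, basis)))
  vars <- compute_fc_variables(runs, 0.1506)
  expect_gte(vars$n_hub_ms, 2)

  # majority window-label agreement: map each of the two most-occupied
  # meta-states to its best planted state; their windows must agree with the
  # planted labels more often than not
  centers <- s$window_start_frames + 35
  lab <- sim$ground_truth$state_labels[centers]
  keys <- apply(runs$codes, 1, paste, collapse = ",")
  occupancy <- sort(table(keys), decreasing = TRUE)
  top2 <- names(occupancy)[1:2]
  agree <- sum(sapply(top2, function(k) {
    max(table(factor(lab[keys == k], levels = 1:2)))
  }))
  expect_gt(agree / sum(keys %in% top2), 0.5)
})
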