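# Simulator: state sequences, scale-free graphs, fluorescence generation.

test_that("state sequences have the planted dwell structure", {
  # single state: constant, no transitions
  s1 <- generate_state_sequence(1, 500, 50, seed = 3)
  expect_identical(s1, rep(1L, 500))

  # determinism
  expect_identical(generate_state_sequence(3, 1877, 200, seed = 7),
                   generate_state_sequence(3, 1877, 200, seed = 7))
  expect_false(identical(generate_state_sequence(3, 1877, 200, seed = 7),
                         generate_state_sequence(3, 1877, 200, seed = 8)))

  # geometric dwell: empirical mean run length within 20% of the target
  # over 50 seeds (completed runs only; the final truncated run is excluded)
  runs <- unlist(lapply(1:50, function(s) {
    r <- rle(generate_state_sequence(3, 1877, 200, seed = s))
    if (length(r$lengths) > 1) r$lengths[-length(r$lengths)] else r$lengths
  }))
  expect_gt(mean(runs), 200 * 0.8)
  expect_lt(mean(runs), 200 * 1.2)

  # all states reachable
  expect_setequal(unique(generate_state_sequence(4, 5000, 20, seed = 1)), 1:4)

  expect_error(generate_state_sequence(0, 100, 10), class = "fcdyn_invalid_argument")
  expect_error(generate_state_sequence(2, 0, 10), class = "fcdyn_invalid_argument")
})

test_that("scale-free graphs are simple, symmetric and seeded", {
  a <- generate_scale_free_graph(3, -1.4, seed = 5)
  expect_identical(a, t(a))
  expect_identical(diag(a), rep(0L, 3))

  b1 <- generate_scale_free_graph(60, -1.4, seed = 11)
  b2 <- generate_scale_free_graph(60, -1.4, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1 %in% c(0L, 1L)))
  expect_identical(b1, t(b1))
  expect_identical(diag(b1), rep(0L, 60))
})

test_that("fitted slope ordering tracks the planted exponent", {
  slope_at <- function(expo, seeds) {
    mean(sapply(seeds, function(s) {
      deg <- rowSums(generate_scale_free_graph(400, expo, seed = s))
      fit_power_law(deg)$parameters[["slope"]]
    }))
  }
  s_shallow <- slope_at(-1.4, 1:5)
  s_steep <- slope_at(-2.0, 1:5)
  expect_lt(s_steep, s_shallow) # steeper planted law -> steeper fitted slope
  expect_lt(s_shallow, -1.0)
})

test_that("silent configuration yields a constant matrix", {
  cfg <- sim_config(n_neurons = 5, n_frames = 100, baseline_rate_hz = 0,
                    coactivation_prob = 0, noise_sd = 0, seed = 1)
  sim <- simulate_fluorescence(cfg)
  expect_true(all(sim$fluorescence$values == cfg$baseline_offset))
  expect_length(unlist(sim$ground_truth$spike_trains), 0)
})

test_that("a single planted event is recovered with the kernel's half-width", {
  cfg <- sim_config(n_neurons = 2, n_frames = 400, baseline_rate_hz = 0,
                    coactivation_prob = 0, noise_sd = 0, baseline_offset = 0,
                    n_states = 1, seed = 1)
  sim <- simulate_fluorescence(cfg)
  v <- sim$fluorescence$values
  T_s <- cfg$sampling_period_s
  # inject one event by hand at frame 100 on neuron 1
  kern <- calcium_kernel((0:299) * T_s, cfg$kernel_rise_s, cfg$kernel_decay_s)
  v[1, 100:399] <- kern
  ev <- detect_events(v[1, ], T_s)
  expect_identical(nrow(ev), 1L)
  hw_true <- kernel_half_width(cfg$kernel_rise_s, cfg$kernel_decay_s)
  expect_lt(abs(ev$half_width_s - hw_true), T_s)
})

test_that("planted assemblies correlate within more than between", {
  sim <- simulate_fluorescence(two_state_sim(seed = 4))
  fm <- subtract_baseline(sim$fluorescence)
  cfg <- sim$ground_truth$config
  r <- static_fc(fm)
  asm <- cfg$assembly_map[[1]]
  within <- c()
  between <- c()
  for (i in 1:(cfg$n_neurons - 1)) for (j in (i + 1):cfg$n_neurons) {
    same <- (i %in% asm[[1]]) == (j %in% asm[[1]])
    # assemblies differ across the two states; "within" means together in
    # at least one state's partition
    asm2 <- cfg$assembly_map[[2]]
    same2 <- (i %in% asm2[[1]]) == (j %in% asm2[[1]])
    if (same || same2) within <- c(within, r[i, j]) else between <- c(between, r[i, j])
  }
  expect_gt(mean(within), mean(between))
})

test_that("event rate is conserved across seeds", {
  rate <- 0.2 # Hz, elevated so 30 small networks give a stable estimate
  n <- 8
  nf <- 500
  T_s <- 0.1506
  counts <- sapply(1:30, function(s) {
    cfg <- sim_config(n_neurons = n, n_frames = nf, baseline_rate_hz = rate,
                      coactivation_prob = 0, noise_sd = 0, seed = s)
    length(unlist(simulate_fluorescence(cfg)$ground_truth$spike_trains))
  })
  # per-frame Bernoulli thinning of the Poisson rate
  p <- 1 - exp(-rate * T_s)
  expected <- n * nf * p
  se <- sqrt(30 * expected * (1 - p)) / 30
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("simulation is bit-identical under one seed and rejects bad kinetics", {
  cfg <- two_state_sim(seed = 9)
  s1 <- simulate_fluorescence(cfg)
  s2 <- simulate_fluorescence(cfg)
  expect_identical(s1$fluorescence$values, s2$fluorescence$values)
  expect_identical(s1$ground_truth$state_labels, s2$ground_truth$state_labels)

  # a kernel with half-width >= 10 s violates the transient-kinetics bound
  expect_error(sim_config(kernel_rise_s = 5, kernel_decay_s = 60),
               class = "fcdyn_config_rejected")
  expect_silent(sim_config(kernel_rise_s = 5, kernel_decay_s = 60,
                           emulate_paper_kinetics = FALSE))
})

test_that("bleach trend multiplies traces down over time", {
  base <- two_state_sim(seed = 2, noise_sd = 0)
  cfg <- sim_config(n_neurons = 12, n_frames = 600, n_states = 2,
                    mean_dwell_frames = 150, baseline_rate_hz = 0.01,
                    coactivation_prob = 0.08, noise_sd = 0,
                    bleach_tau_s = 30, seed = 2)
  plain <- simulate_fluorescence(base)$fluorescence$values
  bleached <- simulate_fluorescence(cfg)$fluorescence$values
  trend <- exp(-(0:599) * 0.1506 / 30)
  expect_equal(bleached, sweep(plain, 2, trend, `*`), tolerance = 1e-12)
})
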