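# Independent oracles and fixture builders shared by the test files. Each
# oracle is deliberately naive (brute force, direct definition) and never
# calls the implementation path it checks.

# Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# full pairwise lower-triangle vector in the package's documented pair order:
# (i, j), i > j, column-major
oracle_pair_vector <- function(mat_rows) {
  n <- nrow(mat_rows)
  out <- c()
  for (j in seq_len(n - 1)) {
    for (i in (j + 1):n) {
      out <- c(out, oracle_pearson(mat_rows[i, ], mat_rows[j, ]))
    }
  }
  out
}

# sort-and-interpolate percentile (R type-7 rule, written out by hand)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# rank-then-bin signed quartile discretization, one component
oracle_signed_quartiles <- function(v) {
  out <- integer(length(v))
  out[v == 0] <- 1L
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(v > 0) else which(v < 0)
    if (!length(idx)) next
    m <- abs(v[idx])
    qs <- sapply(c(0.25, 0.5, 0.75), function(p) oracle_quantile(m, p))
    code <- sapply(m, function(val) 1L + sum(val > qs))
    out[idx] <- as.integer(sgn * code)
  }
  out
}

# the nine FC variables recomputed by a naive pass over raw window codes
oracle_fc_variables <- function(codes, T) {
  n <- nrow(codes)
  keys <- apply(codes, 1, paste, collapse = ",")
  # walk windows, building runs
  run_keys <- keys[1]
  run_lens <- 1L
  reps <- list(codes[1, ])
  for (t in 2:n) {
    if (keys[t] == keys[t - 1]) {
      run_lens[length(run_lens)] <- run_lens[length(run_lens)] + 1L
    } else {
      run_keys <- c(run_keys, keys[t])
      run_lens <- c(run_lens, 1L)
      reps <- c(reps, list(codes[t, ]))
    }
  }
  l1 <- function(a, b) sum(abs(a - b))
  succ <- if (length(reps) > 1) {
    sapply(2:length(reps), function(i) l1(reps[[i - 1]], reps[[i]]))
  } else numeric(0)
  uniq <- unique(reps)
  dr <- 0
  if (length(uniq) > 1) {
    for (a in 1:(length(uniq) - 1)) for (b in (a + 1):length(uniq)) {
      dr <- max(dr, l1(uniq[[a]], uniq[[b]]))
    }
  }
  counts <- table(run_keys)
  hubs <- names(counts)[counts >= 2]
  hub_run <- run_keys %in% hubs
  list(n_visited_ms = length(uniq),
       n_change_points = length(run_keys) - 1L,
       mean_time_in_ms_s = mean(run_lens) * T,
       max_successive_distance = if (length(succ)) max(succ) else 0,
       traveled_distance = sum(succ),
       dynamic_range = dr,
       n_hub_ms = length(hubs),
       mean_time_in_hub_s = if (any(hub_run)) mean(run_lens[hub_run]) * T else NA_real_,
       n_visits_to_hubs = sum(hub_run))
}

# random meta-state code matrix (valid codes, sticky transitions)
random_codes <- function(n_windows, seed, sticky = 0.7) {
  set.seed(seed)
  vals <- c(-4:-1, 1:4)
  codes <- matrix(0L, n_windows, 4)
  codes[1, ] <- sample(vals, 4, replace = TRUE)
  for (t in 2:n_windows) {
    codes[t, ] <- ifelse(runif(4) < sticky, codes[t - 1, ],
                         sample(vals, 4, replace = TRUE))
  }
  codes
}

# small two-state switching network used across modules
two_state_sim <- function(seed = 1, n_neurons = 12, n_frames = 600,
                          mean_dwell = 150, noise_sd = 0.02) {
  sim_config(n_neurons = n_neurons, n_frames = n_frames,
             n_states = 2, mean_dwell_frames = mean_dwell,
             baseline_rate_hz = 0.01, coactivation_prob = 0.08,
             noise_sd = noise_sd, seed = seed)
}

# cohort of simple variable tables for the mixed model
simulate_variable_table <- function(n_lines = 20, nets_per_line = 5,
                                    beta_dx = 0, sd_line = 0.5, sd_noise = 1,
                                    seed = 1) {
  set.seed(seed)
  lines <- paste0("line", seq_len(n_lines))
  dx <- as.integer(seq_len(n_lines) > n_lines / 2)
  line_eff <- rnorm(n_lines, sd = sd_line)
  rows <- lapply(seq_len(n_lines), function(i) {
    nn <- sample(15:250, nets_per_line, replace = TRUE)
    data.frame(network_id = paste0(lines[i], "_n", seq_len(nets_per_line)),
               cell_line_id = lines[i], diagnosis = dx[i], n_neurons = nn,
               y = beta_dx * dx[i] + line_eff[i] + rnorm(nets_per_line, sd = sd_noise))
  })
  do.call(rbind, rows)
}
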