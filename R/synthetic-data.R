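# Synthetic calcium-network simulator with planted switching connectivity
# structure and a scale-free structural graph. Every downstream stage of the
# pipeline has a recovery test against the ground truth returned here.

#' Simulation configuration
#'
#' Describes one synthetic network: its size, recording geometry, the planted
#' connectivity-state process, the transient kernel, and noise. Defaults
#' emulate the recordings the pipeline targets: 1877 frames at 6.64 Hz
#' (T = 0.1506 s, ~4.7 min), 15-250 neurons, calcium transients with
#' half-widths well under 10 s, and recurring co-activation configurations.
#'
#' @param n_neurons number of active neurons (>= 2).
#' @param n_frames number of frames (default 1877).
#' @param sampling_period_s T in seconds (default 0.1506).
#' @param n_states number K of planted connectivity states (default 2).
#' @param mean_dwell_frames mean dwell time per state in frames (default 200,
#'   ~30 s: long enough that each visited configuration spans many 70-frame
#'   windows).
#' @param assembly_map per-state partition of neurons into co-active
#'   assemblies: a list of length `n_states`, each element a list of integer
#'   vectors covering `1:n_neurons`. Default: each state splits the neurons
#'   into two contiguous blocks at a state-dependent cut, so different states
#'   impose different block-correlation structure.
#' @param baseline_rate_hz spontaneous per-neuron event rate (default 0.02 Hz).
#' @param coactivation_prob per-frame probability that an assembly of the
#'   active state fires together (default 0.05).
#' @param kernel_rise_s,kernel_decay_s transient kernel time constants
#'   (defaults 0.3 s and 1.5 s; half-width ~1.5 s).
#' @param noise_sd additive Gaussian noise sd (default 0.05, relative to unit
#'   transient amplitude).
#' @param baseline_offset constant fluorescence baseline added to every frame
#'   (default 1); removed again by [subtract_baseline()].
#' @param bleach_tau_s optional photobleaching time constant in seconds; when
#'   present every trace is multiplied by `exp(-t / bleach_tau_s)`. Off by
#'   default (bleach correction is out of pipeline scope; the trend exists
#'   only to test robustness).
#' @param degree_exponent negative exponent of the structural scale-free graph
#'   (default -1.4).
#' @param emulate_paper_kinetics when TRUE (default), reject kernels whose
#'   half-width reaches 10 s, the empirical upper bound for transient
#'   kinetics at this sampling rate.
#' @param seed master seed; all stage randomness derives from it through
#'   named streams (`graph`, `states`, `spikes`, `noise`).
#' @param network_id,plate_id,cell_line_id,diagnosis metadata labels passed
#'   through to the generated [fluorescence_matrix()].
#' @return a `sim_config` list.
#' @seealso [simulate_fluorescence()]
#' @export
sim_config <- function(n_neurons = 50L, n_frames = 1877L,
                       sampling_period_s = 0.1506,
                       n_states = 2L, mean_dwell_frames = 200,
                       assembly_map = NULL,
                       baseline_rate_hz = 0.02, coactivation_prob = 0.05,
                       kernel_rise_s = 0.3, kernel_decay_s = 1.5,
                       noise_sd = 0.05, baseline_offset = 1,
                       bleach_tau_s = NULL, degree_exponent = -1.4,
                       emulate_paper_kinetics = TRUE, seed = 1L,
                       network_id = "sim1", plate_id = "plate1",
                       cell_line_id = "line1", diagnosis = "HC") {
  assert_count(n_neurons, "n_neurons", min = 2L)
  assert_count(n_frames, "n_frames", min = 2L)
  assert_count(n_states, "n_states", min = 1L)
  assert_scalar(mean_dwell_frames, "mean_dwell_frames", lower = 1)
  assert_scalar(baseline_rate_hz, "baseline_rate_hz", lower = 0)
  assert_scalar(coactivation_prob, "coactivation_prob", lower = 0, upper = 1)
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  assert_scalar(degree_exponent, "degree_exponent", upper = -1e-9)
  if (!is.null(bleach_tau_s)) assert_scalar(bleach_tau_s, "bleach_tau_s", lower = 1e-9)
  hw <- kernel_half_width(kernel_rise_s, kernel_decay_s)
  if (isTRUE(emulate_paper_kinetics) && hw >= 10) {
    stop_fcdyn(sprintf(
      "kernel half-width %.2f s >= 10 s violates the transient-kinetics bound; %s",
      hw, "shorten kernel_rise_s/kernel_decay_s or set emulate_paper_kinetics = FALSE"),
      "fcdyn_config_rejected")
  }
  if (is.null(assembly_map)) {
    assembly_map <- default_assembly_map(n_neurons, n_states)
  }
  validate_assembly_map(assembly_map, n_neurons, n_states)
  structure(
    list(n_neurons = as.integer(n_neurons), n_frames = as.integer(n_frames),
         sampling_period_s = sampling_period_s, n_states = as.integer(n_states),
         mean_dwell_frames = mean_dwell_frames, assembly_map = assembly_map,
         baseline_rate_hz = baseline_rate_hz,
         coactivation_prob = coactivation_prob,
         kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
         kernel_half_width_s = hw,
         noise_sd = noise_sd, baseline_offset = baseline_offset,
         bleach_tau_s = bleach_tau_s, degree_exponent = degree_exponent,
         emulate_paper_kinetics = isTRUE(emulate_paper_kinetics),
         seed = as.integer(seed),
         network_id = network_id, plate_id = plate_id,
         cell_line_id = cell_line_id, diagnosis = diagnosis),
    class = "sim_config"
  )
}

# Each state splits neurons into two contiguous assemblies at a cut that
# rotates with the state index, so consecutive states differ in which neurons
# co-activate.
default_assembly_map <- function(n_neurons, n_states) {
  lapply(seq_len(n_states), function(k) {
    cut <- max(1L, min(n_neurons - 1L,
                       round(n_neurons * k / (n_states + 1))))
    list(seq_len(cut), seq.int(cut + 1L, n_neurons))
  })
}

validate_assembly_map <- function(map, n_neurons, n_states) {
  if (!is.list(map) || length(map) != n_states) {
    stop_fcdyn("assembly_map must be a list with one entry per state",
               "fcdyn_invalid_argument")
  }
  for (k in seq_along(map)) {
    covered <- sort(unlist(map[[k]]))
    if (!identical(as.integer(covered), seq_len(n_neurons))) {
      stop_fcdyn(sprintf(
        "assembly_map state %d must partition neurons 1..%d", k, n_neurons),
        "fcdyn_invalid_argument")
    }
  }
  invisible(map)
}

#' Generate a planted connectivity-state sequence
#'
#' First-order Markov chain over `K` states with geometric dwell times of the
#' stated mean (switch probability `1 / mean_dwell_frames`, uniform choice
#' among the other states). Emulates the recurring connectivity
#' configurations seen in resting-state recordings.
#'
#' @param K number of states (>= 1).
#' @param n_frames sequence length.
#' @param mean_dwell_frames mean dwell time in frames (>= 1).
#' @param seed integer seed.
#' @return integer vector of length `n_frames` with values in `1:K`.
#' @export
generate_state_sequence <- function(K, n_frames, mean_dwell_frames, seed = 1L) {
  assert_count(K, "K", min = 1L)
  assert_count(n_frames, "n_frames", min = 1L)
  assert_scalar(mean_dwell_frames, "mean_dwell_frames", lower = 1)
  if (K == 1L) return(rep(1L, n_frames))
  p_switch <- 1 / mean_dwell_frames
  labels <- integer(n_frames)
  withr_seed(seed, {
    labels[1L] <- sample.int(K, 1L)
    switches <- stats::runif(n_frames - 1L) < p_switch
    # pre-drawing uniforms keeps the path deterministic and vectorizable
    pick <- ceiling(stats::runif(n_frames - 1L) * (K - 1L))
    for (t in seq_len(n_frames - 1L)) {
      if (switches[t]) {
        others <- seq_len(K)[-labels[t]]
        labels[t + 1L] <- others[pick[t]]
      } else {
        labels[t + 1L] <- labels[t]
      }
    }
  })
  labels
}

# set.seed scoped to an expression; restores the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a scale-free structural graph
#'
#' Draws a degree sequence from a discrete power law `P(k) ~ k^exponent` and
#' realizes it as a simple graph by stub matching with degree-preserving edge
#' switches that remove self-loops and multi-edges
#' (`igraph::sample_degseq(method = "edge.switching.simple")`), so the
#' realized degree sequence equals the drawn one exactly.
#'
#' The law's support is truncated at the structural cutoff
#' `k_max = sqrt(n <k>)` (computed as a fixed point over the truncated law)
#' rather than at `n - 1`: beyond that cutoff a heavy-tailed degree sequence
#' is essentially never graphical as a simple graph, so hubs above it cannot
#' exist in the functional graphs this emulates.
#'
#' @param n_neurons number of nodes (>= 3).
#' @param exponent negative power-law exponent (e.g. -1.4).
#' @param seed integer seed.
#' @param max_retries bounded number of degree-sequence redraws allowed when a
#'   draw is not graphical (default 100).
#' @return symmetric binary adjacency matrix with zero diagonal and attribute
#'   `"degree_cutoff"` holding the support cutoff used.
#' @export
generate_scale_free_graph <- function(n_neurons, exponent, seed = 1L,
                                      max_retries = 100L) {
  assert_count(n_neurons, "n_neurons", min = 3L)
  assert_scalar(exponent, "exponent", upper = -1e-9)
  assert_count(max_retries, "max_retries", min = 1L)
  k_max <- structural_cutoff(n_neurons, exponent)
  k_vals <- seq_len(k_max)
  pmf <- k_vals^exponent
  pmf <- pmf / sum(pmf)
  degrees <- NULL
  adj <- NULL
  withr_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      cand <- sample(k_vals, n_neurons, replace = TRUE, prob = pmf)
      if (sum(cand) %% 2L == 1L) {
        i <- which.max(cand < k_max)
        cand[i] <- cand[i] + 1L
      }
      if (igraph::is_graphical(cand)) {
        degrees <- cand
        break
      }
    }
    if (!is.null(degrees)) {
      g <- igraph::sample_degseq(degrees, method = "edge.switching.simple")
      adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    }
  })
  if (is.null(degrees)) {
    stop_fcdyn(sprintf(
      "no graphical degree sequence drawn after %d retries", max_retries),
      "fcdyn_constructive_failure", retry_limit = max_retries)
  }
  storage.mode(adj) <- "integer"
  dimnames(adj) <- NULL
  attr(adj, "degree_cutoff") <- k_max
  adj
}

# Structural cutoff for simple scale-free graphs: k_max = sqrt(n <k>), solved
# as a fixed point because <k> itself depends on the truncation.
structural_cutoff <- function(n, exponent) {
  k_max <- n - 1L
  for (i in 1:100) {
    k <- seq_len(k_max)
    p <- k^exponent
    p <- p / sum(p)
    mu <- sum(k * p)
    new_max <- max(2L, min(n - 1L, as.integer(floor(sqrt(n * mu)))))
    if (new_max == k_max) break
    k_max <- new_max
  }
  k_max
}

#' Simulate a fluorescence recording with planted dynamics
#'
#' Event trains are Poisson at `baseline_rate_hz` per neuron plus, per frame,
#' assembly-wide co-activations with probability `coactivation_prob` for each
#' assembly of the currently active planted state. Each event injects a
#' difference-of-exponentials transient ([calcium_kernel()]); additive
#' Gaussian noise and an optional multiplicative bleach trend complete the
#' trace. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `fluorescence` (a [fluorescence_matrix()])
#'   and `ground_truth` (state labels per frame, per-neuron event frames,
#'   structural adjacency, planted exponent).
#' @examples
#' sim <- simulate_fluorescence(sim_config(n_neurons = 10, n_frames = 300))
#' dim(sim$fluorescence)
#' table(sim$ground_truth$state_labels)
#' @export
simulate_fluorescence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_neurons
  nf <- config$n_frames
  T_s <- config$sampling_period_s

  states <- generate_state_sequence(config$n_states, nf,
                                    config$mean_dwell_frames,
                                    seed = derive_seed(config$seed, "states"))
  adj <- generate_scale_free_graph(max(n, 3L), config$degree_exponent,
                                   seed = derive_seed(config$seed, "graph"))[
    seq_len(n), seq_len(n), drop = FALSE]

  # Binary spike raster: baseline Poisson thinned per frame + planted
  # assembly-wide co-activation drives.
  spikes <- matrix(FALSE, n, nf)
  p_base <- 1 - exp(-config$baseline_rate_hz * T_s)
  withr_seed(derive_seed(config$seed, "spikes"), {
    if (p_base > 0) {
      spikes[] <- stats::runif(n * nf) < p_base
    }
    if (config$coactivation_prob > 0) {
      for (k in seq_len(config$n_states)) {
        frames_k <- which(states == k)
        if (!length(frames_k)) next
        for (assembly in config$assembly_map[[k]]) {
          fire <- frames_k[stats::runif(length(frames_k)) < config$coactivation_prob]
          if (length(fire)) spikes[assembly, fire] <- TRUE
        }
      }
    }
  })

  # Convolve each spike train with the transient kernel (truncated where the
  # kernel has decayed below 1e-3 of peak).
  kernel_len <- min(nf, ceiling(-log(1e-3) * config$kernel_decay_s / T_s) + 1L)
  kern <- calcium_kernel(seq.int(0L, kernel_len - 1L) * T_s,
                         config$kernel_rise_s, config$kernel_decay_s)
  values <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    ev <- which(spikes[i, ])
    for (f in ev) {
      idx <- f:min(nf, f + kernel_len - 1L)
      values[i, idx] <- values[i, idx] + kern[seq_along(idx)]
    }
  }

  if (config$noise_sd > 0) {
    withr_seed(derive_seed(config$seed, "noise"), {
      values <- values + matrix(stats::rnorm(n * nf, sd = config$noise_sd), n, nf)
    })
  }
  values <- values + config$baseline_offset
  if (!is.null(config$bleach_tau_s)) {
    trend <- exp(-(seq_len(nf) - 1L) * T_s / config$bleach_tau_s)
    values <- sweep(values, 2L, trend, `*`)
  }

  fluor <- fluorescence_matrix(values, sampling_period_s = T_s,
                               network_id = config$network_id,
                               plate_id = config$plate_id,
                               cell_line_id = config$cell_line_id,
                               diagnosis = config$diagnosis)
  truth <- list(
    state_labels = states,
    spike_trains = apply(spikes, 1L, which, simplify = FALSE),
    structural_adjacency = adj,
    planted_degree_exponent = config$degree_exponent,
    config = config
  )
  list(fluorescence = fluor, ground_truth = truth)
}
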