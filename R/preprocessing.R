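# Baseline subtraction and calcium transient event detection.

#' Subtract the per-neuron baseline fluorescence
#'
#' For every neuron the trace quantile at `baseline_quantile` (default 0.08,
#' the 8th percentile — a low-activity baseline estimate robust to sparse
#' transients) is subtracted from every frame. Quantiles use linear
#' interpolation between order statistics (R type 7).
#'
#' @param raw a [fluorescence_matrix()].
#' @param baseline_quantile quantile in (0, 1), default 0.08.
#' @return a [fluorescence_matrix()] of identical shape and metadata.
#' @examples
#' fm <- fluorescence_matrix(matrix(1:20, nrow = 2) + 5)
#' range(subtract_baseline(fm)$values)
#' @export
subtract_baseline <- function(raw, baseline_quantile = 0.08) {
  stopifnot(inherits(raw, "fluorescence_matrix"))
  assert_scalar(baseline_quantile, "baseline_quantile",
                lower = 1e-12, upper = 1 - 1e-12)
  v <- raw$values
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant trace(s) become all-zero after baseline subtraction",
                    sum(sds == 0)), call. = FALSE)
  }
  baselines <- apply(v, 1L, stats::quantile,
                     probs = baseline_quantile, names = FALSE, type = 7)
  out <- raw
  out$values <- v - baselines
  out
}

#' Detect individual calcium transient events in one trace
#'
#' Amplitude-threshold detection: candidate events are local maxima whose
#' value reaches `threshold_fraction` of the trace's global maximum (ties at
#' the threshold count as detected). Peaks closer than
#' `min_separation_frames` are merged, keeping the higher peak — a
#' deterministic replacement for manual visual confirmation. The half-width
#' is the duration between the rising and falling crossings of half the
#' event's peak amplitude, linearly interpolated between frames.
#'
#' Event amplitude is the peak value minus the greater of zero and the local
#' pre-onset minimum, so a residual baseline offset does not inflate it.
#'
#' @param trace numeric vector, a baseline-subtracted single-neuron trace.
#' @param T sampling period in seconds.
#' @param threshold_fraction fraction of the global maximum (default 0.4).
#' @param min_separation_frames peaks closer than this are merged (default 3).
#' @param neuron_index 0-based neuron index stored on the events.
#' @return a data frame with one row per event: `neuron_index`,
#'   `onset_frame`, `peak_frame` (0-based), `amplitude`, `half_width_s`.
#'   Zero rows for traces with no positive excursion.
#' @export
detect_events <- function(trace, T, threshold_fraction = 0.4,
                          min_separation_frames = 3L, neuron_index = 0L) {
  assert_scalar(T, "T", lower = 1e-12)
  assert_scalar(threshold_fraction, "threshold_fraction",
                lower = 1e-12, upper = 1 - 1e-12)
  assert_count(min_separation_frames, "min_separation_frames", min = 1L)
  trace <- as.numeric(trace)
  empty <- data.frame(neuron_index = integer(), onset_frame = integer(),
                      peak_frame = integer(), amplitude = numeric(),
                      half_width_s = numeric())
  if (!length(trace) || all(!is.finite(trace)) || max(trace) <= 0) return(empty)

  thr <- threshold_fraction * max(trace)
  peaks <- local_maxima(trace)
  peaks <- peaks[trace[peaks] >= thr] # tie at threshold counts as detected
  if (!length(peaks)) return(empty)

  # merge peaks closer than min_separation_frames, keeping the higher one
  peaks <- peaks[order(trace[peaks], decreasing = TRUE)]
  kept <- integer()
  for (p in peaks) {
    if (!length(kept) || all(abs(kept - p) >= min_separation_frames)) {
      kept <- c(kept, p)
    }
  }
  kept <- sort(kept)

  rows <- lapply(kept, function(p) {
    lo <- preceding_valley(trace, p)
    hi <- following_valley(trace, p)
    amp <- trace[p] - max(0, trace[lo])
    if (amp <= 0) return(NULL)
    level <- trace[p] - amp / 2
    hw <- crossing_width(trace, p, lo, hi, level) * T
    data.frame(neuron_index = as.integer(neuron_index),
               onset_frame = lo - 1L, peak_frame = p - 1L,
               amplitude = amp, half_width_s = hw)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  left <- c(TRUE, x[-1L] > x[-n])          # strictly above the previous frame
  right <- c(x[-n] >= x[-1L], TRUE)        # at least the next frame (plateaus
  which(left & right)                      # keep their first frame)
}

preceding_valley <- function(x, p) {
  i <- p
  while (i > 1L && x[i - 1L] <= x[i]) i <- i - 1L
  i
}

following_valley <- function(x, p) {
  n <- length(x)
  i <- p
  while (i < n && x[i + 1L] <= x[i]) i <- i + 1L
  i
}

# width, in frames, between the rising and falling crossings of `level`
# within [lo, hi]; linear interpolation between frames, clamped at the
# segment boundaries when a crossing is not reached.
crossing_width <- function(x, p, lo, hi, level) {
  t_rise <- lo
  for (i in p:lo) {
    if (x[i] < level) {
      t_rise <- i + (level - x[i]) / (x[i + 1L] - x[i])
      break
    }
  }
  t_fall <- hi
  for (i in p:hi) {
    if (x[i] < level) {
      t_fall <- (i - 1L) + (level - x[i - 1L]) / (x[i] - x[i - 1L])
      break
    }
  }
  t_fall - t_rise
}

#' Detect events for every neuron of a network
#'
#' @param mat a baseline-subtracted [fluorescence_matrix()].
#' @inheritParams detect_events
#' @return a data frame of events across all neurons, with a `network_id`
#'   column prepended.
#' @export
detect_events_network <- function(mat, threshold_fraction = 0.4,
                                  min_separation_frames = 3L) {
  stopifnot(inherits(mat, "fluorescence_matrix"))
  evs <- lapply(seq_len(nrow(mat$values)), function(i) {
    detect_events(mat$values[i, ], mat$sampling_period_s,
                  threshold_fraction, min_separation_frames,
                  neuron_index = i - 1L)
  })
  out <- do.call(rbind, evs)
  cbind(network_id = rep(mat$network_id, nrow(out)), out)
}

#' Histogram of event half-widths
#'
#' @param events event data frame from [detect_events()] (needs a
#'   `half_width_s` column, nonempty).
#' @param bin_width_s histogram bin width in seconds.
#' @return a list with `breaks_s`, `counts`, `cumulative_fraction`
#'   (reaching exactly 1), and `n_events`.
#' @export
half_width_histogram <- function(events, bin_width_s = 0.5) {
  assert_scalar(bin_width_s, "bin_width_s", lower = 1e-12)
  hw <- events$half_width_s
  if (is.null(hw) || !length(hw)) {
    stop_fcdyn("empty event list: no half-widths to histogram",
               "fcdyn_empty_input")
  }
  breaks <- seq(0, (ceiling(max(hw) / bin_width_s) + 1) * bin_width_s,
                by = bin_width_s)
  counts <- as.integer(table(cut(hw, breaks, right = FALSE)))
  list(breaks_s = breaks, counts = counts,
       cumulative_fraction = cumsum(counts) / length(hw),
       n_events = length(hw))
}
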