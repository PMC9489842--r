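# Sliding-window functional connectivity wFC(t) and the time x time
# functional-connectivity-dynamics (FCD) matrix.

#' Sliding-window functional connectivity series
#'
#' For every fully contained window of `window_width_frames` frames
#' (rectangular, no taper), computes the Pearson correlations of all neuron
#' pairs and stores them as the vectorized strictly-lower triangle of the
#' window's correlation matrix. With step 1 and 1877 frames at width 70 this
#' yields the canonical 1808 windows.
#'
#' Pair order is fixed: pairs `(i, j)` with `i > j`, ordered lexicographically
#' by `(j, i)` — i.e. column-major order of the lower triangle, the order
#' returned by `m[lower.tri(m)]`.
#'
#' A pair involving a neuron that is constant within some window gets
#' correlation 0 in that window (keeping the series rectangular for the ICA
#' stage); the number of such imputations is recorded in attribute
#' `"n_zero_variance"`.
#'
#' @param matrix a [fluorescence_matrix()].
#' @param window_width_frames window width in frames (default 70, ~10.5 s at
#'   T = 0.1506 s).
#' @param step_frames step between window starts (default 1).
#' @return a `wfc_series` list: `vectors` (n_windows x n_pairs),
#'   `window_width_frames`, `step_frames`, `window_start_frames` (1-based),
#'   `n_neurons`, `sampling_period_s`.
#' @export
sliding_window_fc <- function(matrix, window_width_frames = 70L,
                              step_frames = 1L) {
  stopifnot(inherits(matrix, "fluorescence_matrix"))
  assert_count(window_width_frames, "window_width_frames", min = 3L)
  assert_count(step_frames, "step_frames", min = 1L)
  v <- matrix$values
  n <- nrow(v)
  nf <- ncol(v)
  if (n < 2L) stop_fcdyn("need at least 2 neurons", "fcdyn_invalid_input")
  if (window_width_frames > nf) {
    stop_fcdyn("window width exceeds the number of frames",
               "fcdyn_invalid_argument")
  }
  starts <- seq.int(1L, nf - window_width_frames + 1L, by = step_frames)
  n_pairs <- n * (n - 1L) / 2L
  out <- base::matrix(0, nrow = length(starts), ncol = n_pairs)
  lower <- lower.tri(diag(n))
  n_zero <- 0L
  tv <- t(v)
  for (w in seq_along(starts)) {
    slice <- tv[starts[w]:(starts[w] + window_width_frames - 1L), ,
                drop = FALSE]
    r <- suppressWarnings(stats::cor(slice))
    vec <- r[lower]
    bad <- !is.finite(vec)
    if (any(bad)) {
      n_zero <- n_zero + sum(bad)
      vec[bad] <- 0
    }
    out[w, ] <- vec
  }
  structure(list(vectors = out,
                 window_width_frames = as.integer(window_width_frames),
                 step_frames = as.integer(step_frames),
                 window_start_frames = as.integer(starts),
                 n_neurons = n,
                 sampling_period_s = matrix$sampling_period_s,
                 n_zero_variance = n_zero),
            class = "wfc_series")
}

#' @export
print.wfc_series <- function(x, ...) {
  cat(sprintf("<wfc_series> %d windows x %d pairs (width %d, step %d)\n",
              nrow(x$vectors), ncol(x$vectors),
              x$window_width_frames, x$step_frames))
  invisible(x)
}

#' Functional-connectivity-dynamics (FCD) matrix
#'
#' Pearson correlation between every pair of wFC(t) vectors: a time x time
#' matrix whose off-diagonal blocks of high correlation reveal reoccurring
#' connectivity configurations.
#'
#' @param series a `wfc_series` from [sliding_window_fc()] with at least 2
#'   windows and 2 pairs.
#' @return symmetric matrix (n_windows x n_windows), unit diagonal. Rows of
#'   the series with zero variance correlate as 0 with everything (count in
#'   attribute `"n_zero_variance_rows"`).
#' @export
fcd <- function(series) {
  stopifnot(inherits(series, "wfc_series"))
  x <- series$vectors
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_fcdyn("FCD needs at least 2 windows and 2 neuron pairs",
               "fcdyn_invalid_input")
  }
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  c_mat <- suppressWarnings(stats::cor(t(x)))
  if (any(flat)) c_mat[flat, ] <- c_mat[, flat] <- 0
  c_mat <- (c_mat + t(c_mat)) / 2
  diag(c_mat) <- 1
  attr(c_mat, "n_zero_variance_rows") <- sum(flat)
  c_mat
}
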