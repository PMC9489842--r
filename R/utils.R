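# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one user-visible seed; each
#' stochastic stage (graph, states, spikes, noise, ICA restarts, ...) draws
#' from its own named stream so stages can be re-run independently without
#' perturbing each other.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @param index optional nonnegative integer for indexed streams (e.g. retry k).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  h <- (h * 131 + as.numeric(index)) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fcdyn <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "fcdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop_fcdyn(sprintf("`%s` must be a single integer >= %d", name, min),
               "fcdyn_invalid_argument")
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_fcdyn(sprintf("`%s` must be a finite scalar in [%s, %s]",
                       name, format(lower), format(upper)),
               "fcdyn_invalid_argument")
  }
  invisible(as.numeric(x))
}

#' Difference-of-exponentials calcium transient kernel
#'
#' `g(t) = exp(-t / decay) - exp(-t / rise)`, normalized to unit peak. This is
#' the canonical phenomenological shape for an indicator transient: fast rise,
#' slow decay.
#'
#' @param t_s nonnegative times in seconds.
#' @param rise_s,decay_s rise and decay time constants in seconds
#'   (`rise_s < decay_s`).
#' @return kernel values, peak exactly 1.
#' @examples
#' k <- calcium_kernel(seq(0, 10, by = 0.1506), 0.3, 1.5)
#' max(k) # 1 at the analytic peak time
#' @export
calcium_kernel <- function(t_s, rise_s, decay_s) {
  assert_scalar(rise_s, "rise_s", lower = 1e-9)
  assert_scalar(decay_s, "decay_s", lower = 1e-9)
  if (rise_s >= decay_s) {
    stop_fcdyn("`rise_s` must be smaller than `decay_s`", "fcdyn_invalid_argument")
  }
  t_peak <- kernel_peak_time(rise_s, decay_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  out <- (exp(-t_s / decay_s) - exp(-t_s / rise_s)) / peak
  out[t_s < 0] <- 0
  out
}

kernel_peak_time <- function(rise_s, decay_s) {
  (decay_s * rise_s / (decay_s - rise_s)) * log(decay_s / rise_s)
}

#' Analytic half-width of the transient kernel
#'
#' Full width at half the peak amplitude, found by root bracketing on the
#' normalized kernel (the crossing equations have no elementary closed form).
#'
#' @inheritParams calcium_kernel
#' @return half-width in seconds.
#' @export
kernel_half_width <- function(rise_s, decay_s) {
  t_peak <- kernel_peak_time(rise_s, decay_s)
  f <- function(t) calcium_kernel(t, rise_s, decay_s) - 0.5
  t_rise <- stats::uniroot(f, c(0, t_peak), tol = 1e-12)$root
  upper <- t_peak
  while (f(upper) > 0) upper <- upper * 2 + decay_s
  t_fall <- stats::uniroot(f, c(t_peak, upper), tol = 1e-12)$root
  t_fall - t_rise
}
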