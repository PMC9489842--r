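# Reduction of the wFC series to four independent correlation patterns (CP)
# per network, per-window regression weights, and signed-quartile meta-state
# discretization.
#
# FastICA is implemented here (symmetric fixed-point iteration, logcosh
# contrast) rather than imported: the decomposition is the core of the
# meta-state method and no ICA package is a guaranteed dependency.

#' Extract independent correlation patterns from a wFC series
#'
#' Runs whitened fixed-point ICA (FastICA, symmetric orthogonalization,
#' logcosh nonlinearity) over the temporal collection of wFC vectors:
#' windows are observations, neuron pairs are variables. The mixing rows are
#' the correlation patterns (CP); each window is later re-expressed as four
#' regression weights on this basis.
#'
#' Sign indeterminacy is fixed by flipping each component so that its weight
#' time series has nonnegative skewness (recorded in `sign_convention`); all
#' downstream count/distance variables are invariant under any global sign
#' flip. On non-convergence the iteration restarts from a fresh sub-seed up
#' to `max_retries` times; a basis that still failed carries
#' `converged = FALSE` and should be excluded from meta-state statistics.
#'
#' @param series a `wfc_series` from [sliding_window_fc()].
#' @param n_components number of independent components (default 4).
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_retries restarts allowed on non-convergence (default 5).
#' @param max_iter fixed-point iterations per attempt (default 200).
#' @param tol convergence tolerance on the rotation update (default 1e-4).
#' @return a `cp_basis` list: `patterns` (n_components x n_pairs),
#'   `sources` (n_windows x n_components ICA weight time series),
#'   `converged`, `n_iterations`, `seed`, `sign_convention`,
#'   `column_means` of the series.
#' @export
extract_correlation_patterns <- function(series, n_components = 4L, seed = 1L,
                                         max_retries = 5L, max_iter = 200L,
                                         tol = 1e-4) {
  stopifnot(inherits(series, "wfc_series"))
  assert_count(n_components, "n_components", min = 1L)
  assert_count(max_retries, "max_retries", min = 1L)
  x <- series$vectors
  if (nrow(x) <= n_components) {
    stop_fcdyn("need more windows than components", "fcdyn_invalid_input")
  }
  if (ncol(x) < n_components) {
    stop_fcdyn("need at least as many neuron pairs as components",
               "fcdyn_invalid_input")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  n <- nrow(xc)

  # whiten via economy SVD: Z has unit-variance uncorrelated columns
  sv <- svd(xc, nu = n_components, nv = 0L)
  if (sv$d[n_components] < 1e-12 * sv$d[1L]) {
    stop_fcdyn("wFC series is rank-deficient below the component count",
               "fcdyn_degenerate_basis")
  }
  z <- sv$u * sqrt(n)

  result <- NULL
  for (attempt in seq_len(max_retries)) {
    w0 <- random_orthogonal(n_components,
                            derive_seed(seed, "ica", attempt - 1L))
    fp <- fastica_fixed_point(z, w0, max_iter = max_iter, tol = tol)
    if (fp$converged) {
      result <- fp
      break
    }
    if (is.null(result)) result <- fp # keep the first attempt for reporting
  }

  s <- z %*% result$w # n x nc source (weight) time series
  # mixing: xc ~ s %*% patterns; columns of s are uncorrelated, unit variance
  patterns <- crossprod(s, xc) / n
  # sign convention: nonnegative skewness of each weight time series
  skews <- apply(s, 2L, function(v) mean((v - mean(v))^3))
  flip <- ifelse(skews < 0, -1, 1)
  s <- sweep(s, 2L, flip, `*`)
  patterns <- patterns * flip

  structure(list(patterns = patterns, sources = s,
                 converged = result$converged,
                 n_iterations = result$iterations,
                 seed = as.integer(seed),
                 sign_convention = "nonnegative-weight-skewness",
                 column_means = mu,
                 n_components = as.integer(n_components)),
            class = "cp_basis")
}

#' @export
print.cp_basis <- function(x, ...) {
  cat(sprintf("<cp_basis> %d patterns x %d pairs; converged: %s (%d iterations)\n",
              nrow(x$patterns), ncol(x$patterns), x$converged, x$n_iterations))
  invisible(x)
}

# Symmetric fixed-point FastICA on whitened data z (n x nc), logcosh
# contrast g = tanh. Returns the orthogonal unmixing rotation.
fastica_fixed_point <- function(z, w, max_iter, tol) {
  n <- nrow(z)
  w <- sym_decorrelate(w)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    s <- z %*% w
    g <- tanh(s)
    gp <- colMeans(1 - g^2)
    w_new <- crossprod(z, g) / n - sweep(w, 2L, gp, `*`)
    w_new <- sym_decorrelate(w_new)
    # rotation change: diagonal of w_new' w near +-1 at a fixed point
    delta <- max(abs(abs(diag(crossprod(w_new, w))) - 1))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, converged = converged, iterations = iterations)
}

# W (W'W)^{-1/2}: nearest orthonormal matrix with the same column span
sym_decorrelate <- function(w) {
  e <- eigen(crossprod(w), symmetric = TRUE)
  w %*% (e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                            nrow = length(e$values)) %*% t(e$vectors))
}

random_orthogonal <- function(k, seed) {
  withr_seed(seed, {
    m <- matrix(stats::rnorm(k * k), k, k)
  })
  qr.Q(qr(m))
}

#' Express every wFC vector as regression weights on the CP basis
#'
#' Ordinary least squares of each wFC row on the patterns, with no intercept:
#' each window is modeled as a linear combination of the four correlation
#' patterns only.
#'
#' @param series a `wfc_series`.
#' @param basis a `cp_basis` from [extract_correlation_patterns()].
#' @return numeric matrix n_windows x n_components of weights.
#' @export
compute_weights <- function(series, basis) {
  stopifnot(inherits(series, "wfc_series"), inherits(basis, "cp_basis"))
  p <- basis$patterns
  gram <- tcrossprod(p)
  if (qr(gram)$rank < nrow(p) || !is.finite(rcond(gram)) || rcond(gram) < 1e-12) {
    stop_fcdyn("correlation-pattern basis is rank deficient",
               "fcdyn_degenerate_basis")
  }
  # normal equations: w = X P' (P P')^{-1}
  series$vectors %*% t(p) %*% solve(gram)
}

#' Discretize CP weights into signed quartile codes
#'
#' Per component, positive weights are ranked among that component's positive
#' weights and mapped to quartiles 1..4 (ascending value); negative weights
#' are ranked among negatives by ascending magnitude and mapped to -1..-4.
#' Positive and negative weights are discretized separately. Quartile
#' boundaries are the empirical 25/50/75 percentiles (linear interpolation);
#' a value exactly on a boundary falls in the lower quartile. Exact zeros
#' are assigned code +1 (a measure-zero event in floating point; each
#' occurrence is messaged).
#'
#' @param weights matrix n_windows x n_components from [compute_weights()].
#' @return integer matrix of codes in `{-4,...,-1, 1,...,4}` (no zeros).
#' @export
discretize_weights <- function(weights) {
  weights <- as.matrix(weights)
  if (!nrow(weights)) stop_fcdyn("empty weight series", "fcdyn_invalid_input")
  codes <- matrix(0L, nrow(weights), ncol(weights))
  for (j in seq_len(ncol(weights))) {
    v <- weights[, j]
    if (all(v == 0)) {
      stop_fcdyn(sprintf("component %d has all-zero weights", j),
                 "fcdyn_degenerate_component")
    }
    if (any(v == 0)) {
      message(sprintf("component %d: %d exact-zero weight(s) assigned code +1",
                      j, sum(v == 0)))
    }
    cj <- integer(length(v))
    cj[v == 0] <- 1L
    pos <- v > 0
    if (any(pos)) cj[pos] <- quartile_codes(v[pos])
    neg <- v < 0
    if (any(neg)) cj[neg] <- -quartile_codes(-v[neg])
    codes[, j] <- cj
  }
  codes
}

# ascending quartile code 1..4 within one sign class; boundary ties go to
# the lower quartile (strict > comparisons)
quartile_codes <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  1L + (v > q[1L]) + (v > q[2L]) + (v > q[3L])
}

#' Run-length encode a meta-state code sequence
#'
#' A meta-state is a particular combination of the four discretized weights;
#' its visits are the maximal runs of identical 4-tuples in temporal order.
#'
#' @param codes integer matrix n_windows x n_components from
#'   [discretize_weights()].
#' @return a `metastate_runs` list: `codes` (the input), `runs` (data frame
#'   with `state` key, `start` 1-based window index, `length`), and
#'   `representatives` (one code row per run).
#' @export
metastate_sequence <- function(codes) {
  codes <- as.matrix(codes)
  if (!nrow(codes)) stop_fcdyn("empty code sequence", "fcdyn_invalid_input")
  if (any(codes == 0L)) stop_fcdyn("codes must be nonzero", "fcdyn_invalid_input")
  keys <- apply(codes, 1L, paste, collapse = ",")
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  structure(list(
    codes = codes,
    runs = data.frame(state = r$values, start = as.integer(starts),
                      length = as.integer(r$lengths),
                      stringsAsFactors = FALSE),
    representatives = codes[starts, , drop = FALSE]
  ), class = "metastate_runs")
}

#' @export
print.metastate_runs <- function(x, ...) {
  cat(sprintf("<metastate_runs> %d windows, %d runs, %d distinct meta-states\n",
              nrow(x$codes), nrow(x$runs), length(unique(x$runs$state))))
  invisible(x)
}
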