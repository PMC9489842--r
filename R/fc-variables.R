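# The nine FC-dynamics variables computed per network from its meta-state
# run sequence.

#' Manhattan (L1) distance between two meta-states
#'
#' Sum over the four components of the absolute difference of the signed
#' quartile codes. The largest possible value is 32, between (4,4,4,4) and
#' (-4,-4,-4,-4).
#'
#' @param ms_a,ms_b integer 4-tuples of meta-state codes.
#' @return nonnegative integer.
#' @export
manhattan <- function(ms_a, ms_b) {
  stopifnot(length(ms_a) == length(ms_b))
  as.integer(sum(abs(ms_a - ms_b)))
}

#' Compute the nine FC-dynamics variables
#'
#' From a network's meta-state run sequence:
#' \enumerate{
#'   \item `n_visited_ms`: number of distinct meta-states realized.
#'   \item `n_change_points`: transitions between successive differing
#'     meta-states (number of runs minus one).
#'   \item `mean_time_in_ms_s`: mean run length converted to seconds
#'     (frames x T).
#'   \item `max_successive_distance`: largest L1 distance between two
#'     consecutive meta-states.
#'   \item `traveled_distance`: summed L1 distance over all successive
#'     transitions.
#'   \item `dynamic_range`: largest L1 distance between any two visited
#'     meta-states.
#'   \item `n_hub_ms`: number of distinct meta-states visited at least twice
#'     (a visit is a maximal run, so a hub is returned to after absence).
#'   \item `mean_time_in_hub_s`: mean length of runs that belong to hub
#'     meta-states, in seconds (`NA` when there are no hubs).
#'   \item `n_visits_to_hubs`: number of runs belonging to hub meta-states.
#' }
#' Distances are evaluated between run representatives at transitions, not
#' between all consecutive windows (which would add zero-length terms).
#'
#' @param runs a `metastate_runs` from [metastate_sequence()].
#' @param T sampling period in seconds (default 0.1506; run lengths are in
#'   windows, stepped one frame apart).
#' @return an `fc_variables` one-row data frame with the nine variables plus
#'   `n_windows` and `n_runs`.
#' @export
compute_fc_variables <- function(runs, T = 0.1506) {
  stopifnot(inherits(runs, "metastate_runs"))
  assert_scalar(T, "T", lower = 1e-12)
  if (!nrow(runs$runs)) stop_fcdyn("empty run sequence", "fcdyn_invalid_input")
  reps <- runs$representatives
  lens <- runs$runs$length
  keys <- runs$runs$state
  n_runs <- nrow(reps)

  succ <- if (n_runs >= 2L) {
    vapply(seq_len(n_runs - 1L),
           function(i) manhattan(reps[i, ], reps[i + 1L, ]), integer(1))
  } else integer(0)

  distinct <- unique(reps)
  dr <- 0L
  if (nrow(distinct) >= 2L) {
    for (a in seq_len(nrow(distinct) - 1L)) {
      for (b in (a + 1L):nrow(distinct)) {
        dr <- max(dr, manhattan(distinct[a, ], distinct[b, ]))
      }
    }
  }

  visit_counts <- table(keys)
  hub_keys <- names(visit_counts)[visit_counts >= 2L]
  hub_run <- keys %in% hub_keys

  structure(data.frame(
    n_visited_ms = nrow(distinct),
    n_change_points = n_runs - 1L,
    mean_time_in_ms_s = mean(lens) * T,
    max_successive_distance = if (length(succ)) max(succ) else 0L,
    traveled_distance = sum(succ),
    dynamic_range = dr,
    n_hub_ms = length(hub_keys),
    mean_time_in_hub_s = if (any(hub_run)) mean(lens[hub_run]) * T else NA_real_,
    n_visits_to_hubs = sum(hub_run),
    n_windows = sum(lens),
    n_runs = n_runs
  ), class = c("fc_variables", "data.frame"))
}

#' The nine variable names in canonical order
#' @return character vector of length 9.
#' @export
fc_variable_names <- function() {
  c("n_visited_ms", "n_change_points", "mean_time_in_ms_s",
    "max_successive_distance", "traveled_distance", "dynamic_range",
    "n_hub_ms", "mean_time_in_hub_s", "n_visits_to_hubs")
}
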