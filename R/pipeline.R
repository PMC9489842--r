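# End-to-end orchestration: simulate or ingest fluorescence matrices, run
# preprocessing -> static topology -> sliding-window FC -> meta-states ->
# FC variables -> group comparison, and persist reproducible artifacts
# (TSV tables + a JSON manifest with checksums).

#' Analyze one network end to end
#'
#' Baseline subtraction, static FC and degree-fit, then per window width:
#' sliding-window FC, ICA correlation patterns, weights, meta-state codes,
#' runs, and the nine FC-dynamics variables.
#'
#' @param fm a [fluorescence_matrix()] (raw; baseline is subtracted here).
#' @param window_widths integer vector of window widths in frames
#'   (default 70).
#' @param fc_cutoff absolute-correlation threshold for the static graph.
#' @param n_components ICA components (default 4).
#' @param baseline_quantile baseline quantile (default 0.08).
#' @param seed seed for the ICA initialization.
#' @param compute_fcd also compute and return the FCD matrix per width
#'   (off by default: quadratic in window count).
#' @return a `network_analysis` list: `fluorescence` (baseline-subtracted),
#'   `static` (fc, adjacency, degrees, power-law fit), `events` table, and
#'   `per_width` (named by width: wfc, basis, weights, codes, runs,
#'   variables, optionally fcd). Networks whose ICA failed to converge have
#'   `converged = FALSE` and no meta-state results for that width.
#' @export
analyze_network <- function(fm, window_widths = 70L, fc_cutoff = 0.4,
                            n_components = 4L, baseline_quantile = 0.08,
                            seed = 1L, compute_fcd = FALSE) {
  stopifnot(inherits(fm, "fluorescence_matrix"))
  sub <- subtract_baseline(fm, baseline_quantile)
  r <- static_fc(sub)
  graph <- threshold_graph(r, fc_cutoff)
  pl <- tryCatch(fit_power_law(graph$degrees),
                 fcdyn_insufficient_support = function(e) NULL)
  events <- detect_events_network(sub)

  per_width <- lapply(window_widths, function(w) {
    wfc <- sliding_window_fc(sub, window_width_frames = w)
    basis <- tryCatch(
      extract_correlation_patterns(wfc, n_components = n_components,
                                   seed = derive_seed(seed, "ica-width", w)),
      fcdyn_degenerate_basis = function(e) NULL)
    res <- list(wfc = wfc, basis = basis, converged = FALSE)
    if (compute_fcd) res$fcd <- fcd(wfc)
    if (!is.null(basis) && basis$converged) {
      weights <- compute_weights(wfc, basis)
      codes <- discretize_weights(weights)
      runs <- metastate_sequence(codes)
      res$weights <- weights
      res$codes <- codes
      res$runs <- runs
      res$variables <- compute_fc_variables(runs, fm$sampling_period_s)
      res$converged <- TRUE
    }
    res
  })
  names(per_width) <- as.character(window_widths)

  structure(list(fluorescence = sub, static_fc = r, graph = graph,
                 power_law = pl, events = events, per_width = per_width,
                 network_id = fm$network_id, plate_id = fm$plate_id,
                 cell_line_id = fm$cell_line_id, diagnosis = fm$diagnosis,
                 n_neurons = nrow(fm$values)),
            class = "network_analysis")
}

#' Run the full pipeline over a cohort
#'
#' @param configs list of [sim_config()] objects (synthetic cohort) and/or
#'   paths to fluorescence TSV files written by [write_fluorescence()].
#' @param out_dir output directory; created if absent. `NULL` keeps
#'   everything in memory only.
#' @param window_widths window widths in frames (default 70; use
#'   `c(70, 100, 200)` for the sensitivity set).
#' @param fc_cutoff,n_components,baseline_quantile stage parameters.
#' @param seed master seed for analysis-stage randomness (ICA restarts).
#' @param compare fit the mixed-model group comparison when both diagnoses
#'   are present (default TRUE; needs >= 10 networks and 2 cell lines).
#' @return a `pipeline_result` list: `analyses`, `variable_tables` (one
#'   tidy data frame per width), `comparisons` (per width, or NULL),
#'   `non_convergent` (network ids per width), `manifest`.
#' @export
run_pipeline <- function(configs, out_dir = NULL, window_widths = 70L,
                         fc_cutoff = 0.4, n_components = 4L,
                         baseline_quantile = 0.08, seed = 1L,
                         compare = TRUE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  analyses <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    fm <- if (inherits(cfg, "sim_config")) {
      simulate_fluorescence(cfg)$fluorescence
    } else if (is.character(cfg)) {
      read_fluorescence(cfg)
    } else if (inherits(cfg, "fluorescence_matrix")) {
      cfg
    } else {
      stop_fcdyn(sprintf("input %d: expected sim_config, path, or fluorescence_matrix", i),
                 "fcdyn_invalid_argument")
    }
    tryCatch(
      analyze_network(fm, window_widths = window_widths,
                      fc_cutoff = fc_cutoff, n_components = n_components,
                      baseline_quantile = baseline_quantile, seed = seed),
      error = function(e) {
        stop_fcdyn(sprintf("stage failure in network '%s': %s",
                           fm$network_id, conditionMessage(e)),
                   "fcdyn_stage_failure")
      })
  })

  widths <- as.character(window_widths)
  variable_tables <- lapply(widths, function(w) {
    rows <- lapply(analyses, function(a) {
      pw <- a$per_width[[w]]
      if (!isTRUE(pw$converged)) return(NULL)
      cbind(data.frame(network_id = a$network_id, plate_id = a$plate_id,
                       cell_line_id = a$cell_line_id, diagnosis = a$diagnosis,
                       n_neurons = a$n_neurons,
                       n_possible_connections = a$n_neurons * (a$n_neurons - 1) / 2,
                       power_law_slope = if (is.null(a$power_law)) NA_real_ else
                         a$power_law$parameters[["slope"]],
                       window_width = as.integer(w),
                       stringsAsFactors = FALSE),
            pw$variables[, c(fc_variable_names(), "n_windows", "n_runs")])
    })
    do.call(rbind, rows)
  })
  names(variable_tables) <- widths

  non_convergent <- lapply(widths, function(w) {
    ids <- vapply(analyses, function(a) a$network_id, character(1))
    ids[!vapply(analyses, function(a) isTRUE(a$per_width[[w]]$converged),
                logical(1))]
  })
  names(non_convergent) <- widths

  comparisons <- NULL
  if (compare) {
    comparisons <- lapply(variable_tables, function(tab) {
      if (is.null(tab) || length(unique(tab$diagnosis)) < 2L ||
          nrow(tab) < 10L || length(unique(tab$cell_line_id)) < 2L) {
        return(NULL)
      }
      compare_groups(tab)
    })
  }

  result <- structure(list(analyses = analyses,
                           variable_tables = variable_tables,
                           comparisons = comparisons,
                           non_convergent = non_convergent,
                           window_widths = window_widths,
                           seed = seed),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    result$manifest <- persist_pipeline(result, out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d networks, widths: %s\n",
              length(x$analyses),
              paste(x$window_widths, collapse = ", ")))
  for (w in names(x$non_convergent)) {
    nc <- x$non_convergent[[w]]
    if (length(nc)) {
      cat(sprintf("  width %s: ICA non-convergent and excluded: %s\n",
                  w, paste(nc, collapse = ", ")))
    }
  }
  invisible(x)
}

# Write the per-width variable tables, comparison tables, and a manifest
# with md5 checksums. Returns the manifest.
persist_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (w in names(result$variable_tables)) {
    tab <- result$variable_tables[[w]]
    if (is.null(tab)) next
    f <- file.path(out_dir, sprintf("variables_width%s.tsv", w))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    cmp <- result$comparisons[[w]]
    if (!is.null(cmp)) {
      fc <- file.path(out_dir, sprintf("comparison_width%s.tsv", w))
      utils::write.table(cmp, fc, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, fc)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcdyn")),
    seed = result$seed,
    window_widths = result$window_widths,
    non_convergent = result$non_convergent,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
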