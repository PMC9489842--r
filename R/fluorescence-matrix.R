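#' Construct a fluorescence intensity matrix
#'
#' The pipeline's entry container: one row per active neuron, one column per
#' frame, values in raw (or baseline-subtracted) fluorescence units, together
#' with the sampling period and the network's metadata labels.
#'
#' @param values numeric matrix, neurons x frames, no missing values.
#' @param sampling_period_s sampling period T in seconds (default 0.1506,
#'   i.e. 6.64 Hz).
#' @param network_id,plate_id,cell_line_id character labels.
#' @param diagnosis group label, conventionally `"HC"` or `"SZ"`.
#' @return an object of class `fluorescence_matrix`.
#' @examples
#' fm <- fluorescence_matrix(matrix(rnorm(40), nrow = 4))
#' dim(fm)
#' @export
fluorescence_matrix <- function(values, sampling_period_s = 0.1506,
                                network_id = "net1", plate_id = "plate1",
                                cell_line_id = "line1", diagnosis = "HC") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (anyNA(values)) {
    stop_fcdyn("fluorescence values must not contain missing values",
               "fcdyn_invalid_argument")
  }
  if (ncol(values) < 2L) {
    stop_fcdyn("a fluorescence matrix needs at least 2 frames",
               "fcdyn_invalid_argument")
  }
  assert_scalar(sampling_period_s, "sampling_period_s", lower = 1e-12)
  structure(
    list(values = values,
         sampling_period_s = as.numeric(sampling_period_s),
         network_id = as.character(network_id),
         plate_id = as.character(plate_id),
         cell_line_id = as.character(cell_line_id),
         diagnosis = as.character(diagnosis)),
    class = "fluorescence_matrix"
  )
}

#' @export
dim.fluorescence_matrix <- function(x) dim(x$values)

#' @export
print.fluorescence_matrix <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_matrix> %d neurons x %d frames, T = %.4g s (%s, %s, %s, %s)\n",
    nrow(x$values), ncol(x$values), x$sampling_period_s,
    x$network_id, x$plate_id, x$cell_line_id, x$diagnosis))
  invisible(x)
}

n_neurons <- function(x) nrow(x$values)
n_frames <- function(x) ncol(x$values)
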