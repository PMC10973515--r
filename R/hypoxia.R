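#' Marker-positive cells by raw UMI count
#'
#' Flags cells with at least `min_umi` raw UMIs of a marker gene (default
#' 2), the rule used to call VEGFA-positive cells as a guide for hypoxia
#' threshold calibration.  Positivity uses raw counts, not normalized
#' values.
#'
#' @param cells a [cell_matrix()].
#' @param gene marker gene symbol (default `"VEGFA"`).
#' @param min_umi minimum UMI count for positivity (default 2; a cell with
#'   exactly 2 UMIs is positive, with 1 it is negative).
#' @return logical vector, one flag per cell.
#' @export
marker_positive <- function(cells, gene = "VEGFA", min_umi = 2) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (!gene %in% rownames(cells$counts))
    stop(sprintf("marker gene '%s' not present in the count matrix", gene))
  flag <- as.numeric(cells$counts[gene, ]) >= min_umi
  names(flag) <- colnames(cells$counts)
  flag
}

#' Calibrate a hypoxia score threshold against a marker-positive fraction
#'
#' Sweeps a grid of candidate thresholds over the per-cell signature
#' scores.  For each candidate it records the fraction of cells scoring
#' above it (`frac_hypoxic`) and the marker-positive fraction among those
#' cells (`frac_marker_pos`).  The chosen threshold is the grid point whose
#' `frac_hypoxic` is closest to the overall marker-positive fraction (the
#' guide); ties break toward the lower threshold.  A fixed threshold can be
#' imposed via `override` to reproduce a previously published cutoff.
#'
#' @param scores per-cell signature score vector.
#' @param marker per-cell logical marker-positivity flags (same length).
#' @param grid strictly increasing candidate thresholds
#'   (default `seq(0.05, 0.95, by = 0.05)`).
#' @param override optional fixed threshold recorded as `chosen` in place
#'   of the calibrated value.
#' @return a `threshold_calibration`: list with `table` (data.frame of
#'   `threshold`, `frac_hypoxic`, `frac_marker_pos`), `marker_fraction`
#'   (the guide value), and `chosen`.
#' @export
calibrate_threshold <- function(scores, marker, grid = seq(0.05, 0.95, by = 0.05),
                                override = NULL) {
  if (!length(grid)) stop("empty threshold grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (length(scores) != length(marker))
    stop("scores and marker flags must have the same length")
  frac_hypoxic <- vapply(grid, function(t) mean(scores > t), numeric(1))
  frac_marker_pos <- vapply(grid, function(t) {
    above <- scores > t
    if (!any(above)) NA_real_ else mean(marker[above])
  }, numeric(1))
  target <- mean(marker)
  chosen <- grid[which.min(abs(frac_hypoxic - target))]  # first minimum = lowest threshold
  if (!is.null(override)) chosen <- override
  structure(list(
    table = data.frame(threshold = grid, frac_hypoxic = frac_hypoxic,
                       frac_marker_pos = frac_marker_pos),
    marker_fraction = target, chosen = chosen),
    class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("threshold_calibration: chosen %.3g (marker-positive fraction %.4f)\n",
              x$chosen, x$marker_fraction))
  invisible(x)
}

#' Classify cells as hypoxic by score threshold
#'
#' A cell is hypoxic iff its score is strictly greater than the threshold
#' (a cell scoring exactly at the threshold is non-hypoxic).
#'
#' @param scores per-cell signature score vector.
#' @param threshold finite score cutoff.
#' @return logical vector, one flag per cell.
#' @export
classify_hypoxic <- function(scores, threshold) {
  stopifnot(is.finite(threshold))
  scores > threshold
}
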