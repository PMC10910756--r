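#' Quality-filter segmented cells
#'
#' Removes artifactual nuclei by a minimum median DAPI intensity followed by
#' nuclear-area size exclusion: cells with area < 10 um^2 (fragmented nuclei)
#' or > 220 um^2 (aggregated/dividing nuclei) are removed. Both bounds are
#' strict, so areas exactly 10 or 220 are retained. When `cfg$dapi_min` is
#' `NULL` the DAPI threshold is data-adaptive: the 5th percentile of DAPI
#' within each core, logged per core.
#'
#' @param cells a cell table with `DAPI` and `nuclear_area_um2` columns.
#' @param cfg a [pipeline_config()].
#' @return list with `cells` (the retained rows), `removed` (named counts per
#'   rule, applied sequentially) and `dapi_thresholds` (per core).
#' @export
qc_filter_cells <- function(cells, cfg = pipeline_config()) {
  if (!"DAPI" %in% names(cells)) stop("DAPI column required for QC")
  if (is.null(cfg$dapi_min)) {
    thr <- tapply(cells$DAPI, cells$sample_id, quantile, probs = 0.05,
                  names = FALSE)
  } else {
    thr <- tapply(cells$DAPI, cells$sample_id, function(x) cfg$dapi_min)
  }
  keep_dapi <- cells$DAPI >= thr[cells$sample_id]
  n_dapi <- sum(!keep_dapi)
  cells2 <- cells[keep_dapi, , drop = FALSE]
  too_small <- cells2$nuclear_area_um2 < cfg$area_min
  too_large <- cells2$nuclear_area_um2 > cfg$area_max
  out <- cells2[!too_small & !too_large, , drop = FALSE]
  if (nrow(out) == 0) warning("QC removed every cell; downstream stages will refuse")
  list(cells = out,
       removed = c(dapi = n_dapi, too_small = sum(too_small),
                   too_large = sum(too_large)),
       dapi_thresholds = thr)
}

#' Arcsinh variance-stabilization of raw intensities
#'
#' `asinh(x / cofactor)`: linear near zero, logarithmic for bright signal.
#' With the panel's cofactor of 150, an intensity of 150 maps to
#' `asinh(1) = 0.881374`.
#'
#' @param x nonnegative raw intensities.
#' @param cofactor arcsinh cofactor.
#' @return transformed values.
#' @export
arcsinh_intensity <- function(x, cofactor = 150) {
  if (any(x < 0, na.rm = TRUE)) stop("raw intensities must be nonnegative")
  asinh(x / cofactor)
}

#' Arcsinh-transform and doubly z-score marker intensities
#'
#' `y = asinh(x / cofactor)` (cofactor 150), then each marker column is
#' z-scored over all cells, then each cell row is z-scored across markers.
#' Constant columns or rows map to 0 instead of NaN. Row scaling requires at
#' least two markers.
#'
#' @param cells cell table with raw marker intensity columns.
#' @param markers character vector of marker column names.
#' @param cfg a [pipeline_config()].
#' @return numeric matrix (cells x markers) of scaled expression.
#' @export
transform_and_scale <- function(cells, markers = tma_markers(),
                                cfg = pipeline_config()) {
  if (length(markers) < 2) stop("at least 2 markers required (row scaling undefined)")
  missing <- setdiff(markers, names(cells))
  if (length(missing)) stop("markers absent from table: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(cells)[, markers, drop = FALSE])
  if (any(x < 0, na.rm = TRUE)) stop("raw intensities must be nonnegative")
  y <- arcsinh_intensity(x, cfg$arcsinh_cofactor)
  y <- apply(y, 2, zscore)
  y <- t(apply(y, 1, zscore))
  dimnames(y) <- list(cells$cell_id, markers)
  y
}

#' Principal components with per-core batch adjustment
#'
#' PCA of the scaled expression matrix (plus z-scored nuclear area when
#' supplied, to help separate tumour from stromal cells), followed by a
#' location-only batch adjustment: the per-core mean of each component is
#' subtracted and the global mean added back. This removes the scalar
#' per-core staining shifts the synthetic generator plants; a full iterative
#' integration method can be swapped in at this hook point.
#'
#' Component signs follow a fixed convention (the largest-magnitude loading
#' of each component is positive) so results are reproducible.
#'
#' @param expr scaled expression matrix from [transform_and_scale()].
#' @param sample_id per-cell core identifier.
#' @param cfg a [pipeline_config()]; `cfg$n_pcs` components are returned and
#'   must be smaller than the number of feature columns.
#' @param nuclear_area optional per-cell nuclear area appended (z-scored) as
#'   an extra feature before PCA.
#' @return matrix (cells x n_pcs) of batch-adjusted component scores.
#' @export
reduce_and_adjust <- function(expr, sample_id, cfg = pipeline_config(),
                              nuclear_area = NULL) {
  x <- expr
  if (!is.null(nuclear_area)) {
    x <- cbind(x, nuclear_area = zscore(nuclear_area))
  }
  if (cfg$n_pcs >= ncol(x)) {
    stop("n_pcs must be smaller than the number of features (", ncol(x), ")")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(cfg$n_pcs), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  global <- colMeans(scores)
  tab <- table(sample_id)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("cores with < 2 cells excluded from batch centering: ",
            paste(small, collapse = ", "))
  }
  for (s in setdiff(names(tab), small)) {
    idx <- which(sample_id == s)
    scores[idx, ] <- sweep(scores[idx, , drop = FALSE], 2,
                           colMeans(scores[idx, , drop = FALSE]) - global)
  }
  scores
}
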