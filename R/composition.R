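#' Per-sample cell-type proportions
#'
#' Fraction of each cell type among typed cells per sample, optionally
#' stratified by compartment (tumour/margin/stroma). "unclassified" cells are
#' excluded from the denominator; absent types get 0. Feature columns are
#' named `prop|<type>` or `prop|<type>|<compartment>`.
#'
#' @param cells labelled cell table with `cell_type` (and `compartment` when
#'   stratified).
#' @param stratify_by `"none"` or `"compartment"`.
#' @param types type universe; defaults to the types present.
#' @return data.frame feature matrix with a `sample_id` column; a sample with
#'   no typed cells in a compartment gets `NA` for that block.
#' @export
cell_proportions <- function(cells, stratify_by = c("none", "compartment"),
                             types = NULL) {
  stratify_by <- match.arg(stratify_by)
  cells <- cells[cells$cell_type != "unclassified", , drop = FALSE]
  types <- types %||% sort(unique(cells$cell_type))
  samples <- sort(unique(cells$sample_id))
  block <- function(sub, suffix = NULL) {
    tab <- table(factor(sub$sample_id, levels = samples),
                 factor(sub$cell_type, levels = types))
    tot <- rowSums(tab)
    prop <- tab / ifelse(tot == 0, NA, tot)
    cn <- paste("prop", colnames(tab), sep = "|")
    colnames(prop) <- if (is.null(suffix)) cn else paste(cn, suffix, sep = "|")
    as.data.frame.matrix(prop)
  }
  if (stratify_by == "none") {
    out <- block(cells)
  } else {
    if (!"compartment" %in% names(cells)) stop("compartment column required")
    out <- do.call(cbind, lapply(c("tumour", "margin", "stroma"), function(cp) {
      block(cells[cells$compartment == cp, , drop = FALSE], cp)
    }))
  }
  data.frame(sample_id = samples, out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential abundance between response groups
#'
#' Welch two-sample t-test per feature, with
#' `log2FC = log2((mean_NR + eps) / (mean_R + eps))` so that positive values
#' mean higher in non-responders (orientation configurable). Zero variance in
#' both groups is reported as p = 1 (equal means) with a flag rather than an
#' error. Benjamini-Hochberg q-values are attached; primary p-values are
#' unadjusted.
#'
#' @param features feature matrix data.frame with `sample_id` column.
#' @param groups named character vector `sample_id -> "R"/"NR"`, or a
#'   clinical table with `sample_id` and `response` columns.
#' @param eps pseudofrequency keeping the fold change finite.
#' @param orientation `"NR_over_R"` (default) or `"R_over_NR"`.
#' @return data.frame: feature, mean_R, mean_NR, log2fc, t, p, q, flag.
#' @export
differential_abundance <- function(features, groups, eps = 1e-3,
                                   orientation = c("NR_over_R", "R_over_NR")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(groups)) {
    groups <- setNames(groups$response, groups$sample_id)
  }
  g <- unname(groups[features$sample_id])
  if (sum(g == "R", na.rm = TRUE) < 2 || sum(g == "NR", na.rm = TRUE) < 2) {
    stop("at least 2 samples per response group required")
  }
  feats <- setdiff(names(features), "sample_id")
  rows <- lapply(feats, function(f) {
    v <- features[[f]]
    ok <- !is.na(v) & !is.na(g)
    vr <- v[ok & g == "R"]; vn <- v[ok & g == "NR"]
    if (length(vr) < 2 || length(vn) < 2) {
      return(data.frame(feature = f, mean_R = mean(vr), mean_NR = mean(vn),
                        log2fc = NA_real_, t = NA_real_, p = NA_real_,
                        flag = "insufficient_samples"))
    }
    wt <- welch_test(vn, vr)
    # negative means (possible for generic score features) give NaN, silently
    lfc <- suppressWarnings(log2((mean(vn) + eps) / (mean(vr) + eps)))
    if (orientation == "R_over_NR") lfc <- -lfc
    data.frame(feature = f, mean_R = mean(vr), mean_NR = mean(vn),
               log2fc = lfc, t = wt$t, p = wt$p, flag = wt$flag)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("feature", "mean_R", "mean_NR", "log2fc", "t", "p", "q", "flag")]
}

#' PCA of composition features
#'
#' Centered principal component analysis of per-sample proportion features
#' (via SVD, so more features than samples is fine), with the fixed sign
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param features feature matrix data.frame with `sample_id` column.
#' @return list with `scores` (samples x PCs), `loadings`, and
#'   `explained_variance` (per-component variances summing to total variance).
#' @export
composition_pca <- function(features) {
  x <- as.matrix(features[, setdiff(names(features), "sample_id"),
                          drop = FALSE])
  if (nrow(x) < 3) stop("at least 3 samples required for composition PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) {
      pc$rotation[, j] <- -ld
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- features$sample_id
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2)
}
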