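#' Cell-type composition windows from nearest neighbours
#'
#' For each cell, the window is the cell itself plus its `window_k - 1`
#' nearest neighbours within the same sample (total `window_k`, default 10);
#' the feature vector is the fraction of each cell type in the window, so
#' rows sum to 1. Windows never cross sample boundaries; samples with fewer
#' than `window_k` cells use all their cells (flagged by a warning). Setting
#' `include_self = FALSE` uses the `window_k` nearest neighbours excluding
#' the index cell.
#'
#' @param cells labelled cell table with `x_um`, `y_um`, `cell_type`.
#' @param window_k window size.
#' @param types type universe for the composition columns.
#' @param include_self include the index cell in its own window.
#' @return numeric matrix (cells x types) of window compositions, rows
#'   aligned with `cells`.
#' @export
compute_windows <- function(cells, window_k = 10, types = NULL,
                            include_self = TRUE) {
  types <- types %||% sort(unique(cells$cell_type))
  out <- matrix(0, nrow(cells), length(types),
                dimnames = list(cells$cell_id, types))
  for (s in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == s)
    n <- length(idx)
    k_nb <- if (include_self) window_k - 1 else window_k
    if (n <= k_nb) {
      warning("sample ", s, " has fewer cells than the window size; ",
              "using all ", n, " cells")
      members <- matrix(rep(seq_len(n), each = n), n)
      if (!include_self) {
        # all cells still used; self inclusion is moot at this size
      }
      comp <- matrix(0, n, length(types))
      tt <- table(factor(cells$cell_type[idx], levels = types))
      comp[] <- rep(tt / sum(tt), each = n)
      out[idx, ] <- comp
      next
    }
    nb <- cpp_knn(cbind(cells$x_um[idx], cells$y_um[idx]), k_nb)
    if (include_self) nb <- cbind(seq_len(n), nb)
    ty <- matrix(factor(cells$cell_type[idx], levels = types)[as.vector(nb)],
                 nrow = n)
    for (t_i in seq_along(types)) {
      out[idx, t_i] <- rowSums(ty == types[t_i]) / ncol(nb)
    }
  }
  out
}

#' Cluster composition windows into cellular neighbourhoods
#'
#' k-means (10 restarts, fixed seed) on window composition vectors pooled
#' across samples; each cell is assigned the neighbourhood of its window.
#' Centroid compositions sum to 1 by convexity. All-identical windows
#' collapse to a single occupied cluster with a warning.
#'
#' @param windows matrix from [compute_windows()].
#' @param n_clusters number of neighbourhoods (default 10).
#' @param seed RNG seed for the restarts.
#' @return list with `labels` (integer 1..n_clusters per cell) and
#'   `centroids` (n_clusters x types).
#' @export
cluster_neighbourhoods <- function(windows, n_clusters = 10, seed = 1L) {
  if (nrow(windows) < n_clusters) stop("fewer windows than clusters")
  uniq <- unique(windows)
  if (nrow(uniq) == 1) {
    warning("all windows identical; a single neighbourhood is occupied")
    return(list(labels = rep(1L, nrow(windows)),
                centroids = uniq[rep(1, n_clusters), , drop = FALSE]))
  }
  set.seed(seed)
  centers <- min(n_clusters, nrow(uniq))
  km <- suppressWarnings(
    kmeans(windows, centers = centers, nstart = 10, iter.max = 100))
  list(labels = as.integer(km$cluster), centroids = km$centers)
}

#' Per-sample neighbourhood frequencies
#'
#' Fraction of each sample's cells assigned to each neighbourhood; feature
#' columns `cn|<id>` feed the response-group t-tests.
#'
#' @param labels per-cell neighbourhood labels.
#' @param sample_id per-cell sample identifiers.
#' @param n_clusters total number of neighbourhoods.
#' @return data.frame feature matrix with `sample_id` column; rows sum to 1.
#' @export
neighbourhood_frequencies <- function(labels, sample_id,
                                      n_clusters = max(labels)) {
  tab <- table(factor(sample_id), factor(labels, levels = seq_len(n_clusters)))
  freq <- tab / rowSums(tab)
  colnames(freq) <- paste0("cn|", colnames(tab))
  data.frame(sample_id = rownames(tab), as.data.frame.matrix(freq),
             check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential cell-type enrichment within neighbourhoods
#'
#' For each (neighbourhood n, cell type c) the per-sample enrichment is
#' `e = log2((f_snc + eps) / (f_sc + eps))`, where `f_snc` is the fraction of
#' type c among the sample's cells in neighbourhood n and `f_sc` the sample's
#' overall fraction of type c. An ordinary least squares model
#' `e ~ intercept + group` then scores the fold-change difference between
#' response groups; the group coefficient and its t-test p-value are
#' reported. Samples lacking a neighbourhood are omitted from that
#' neighbourhood's fits (count logged in the result).
#'
#' @param cells labelled cell table (`cell_type`, `sample_id`).
#' @param labels per-cell neighbourhood labels aligned with `cells`.
#' @param groups named vector `sample_id -> "R"/"NR"` or clinical table.
#' @param eps pseudofrequency.
#' @return data.frame: neighbourhood, cell_type, coefficient (R minus NR),
#'   p, n_samples.
#' @export
differential_enrichment <- function(cells, labels, groups, eps = 1e-3) {
  if (is.data.frame(groups)) groups <- setNames(groups$response, groups$sample_id)
  types <- sort(unique(cells$cell_type))
  samples <- sort(unique(cells$sample_id))
  g <- groups[samples]
  if (sum(g == "R") < 2 || sum(g == "NR") < 2) {
    stop("at least 2 samples per response group required")
  }
  overall <- prop.table(table(factor(cells$sample_id, levels = samples),
                              factor(cells$cell_type, levels = types)), 1)
  nbh <- sort(unique(labels))
  res <- list()
  for (n_id in nbh) {
    in_n <- labels == n_id
    tab <- table(factor(cells$sample_id[in_n], levels = samples),
                 factor(cells$cell_type[in_n], levels = types))
    present <- rowSums(tab) > 0
    f_nc <- tab / ifelse(rowSums(tab) == 0, NA, rowSums(tab))
    for (ty in types) {
      e <- log2((f_nc[present, ty] + eps) / (overall[present, ty] + eps))
      gg <- factor(g[present], levels = c("NR", "R"))
      if (length(unique(gg)) < 2 || length(e) < 3) next
      fit <- summary(stats::lm(e ~ gg))$coefficients
      if (!"ggR" %in% rownames(fit)) next
      res[[length(res) + 1]] <- data.frame(
        neighbourhood = n_id, cell_type = ty,
        coefficient = fit["ggR", "Estimate"],
        p = fit["ggR", "Pr(>|t|)"],
        n_samples = sum(present))
    }
  }
  do.call(rbind, res)
}
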