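#' Graph-based clustering of cells (Phenograph-style)
#'
#' Builds a k = 30 nearest-neighbour graph in adjusted-PC space (Euclidean),
#' weights edges by the Jaccard overlap of neighbour sets, and runs Leiden
#' community detection (modularity objective) at resolution 2 with a fixed
#' seed. The number of communities is data dependent.
#'
#' @param pcs matrix of cells x components from [reduce_and_adjust()].
#' @param cfg a [pipeline_config()]; uses `knn_graph_k`, `leiden_resolution`
#'   and `seed`.
#' @return integer vector of cluster labels `0..C-1`.
#' @export
cluster_cells <- function(pcs, cfg = pipeline_config()) {
  n <- nrow(pcs)
  if (cfg$knn_graph_k >= n) {
    stop("knn_graph_k (", cfg$knn_graph_k, ") must be smaller than the ",
         "number of cells (", n, "); choose a smaller k")
  }
  knn <- cpp_knn(as.matrix(pcs), cfg$knn_graph_k)
  ed <- cpp_jaccard_edges(knn)
  g <- igraph::make_graph(rbind(ed$from, ed$to), n = n, directed = FALSE)
  set.seed(cfg$seed)
  comm <- igraph::cluster_leiden(
    g, objective_function = "modularity", weights = ed$weight,
    resolution = cfg$leiden_resolution, n_iterations = 5)
  as.integer(igraph::membership(comm)) - 1L
}

#' Annotate clusters with cell types from canonical marker signatures
#'
#' Scores each cluster against each cell type as the mean of the cluster's
#' mean scaled expression over the type's signature markers and assigns the
#' argmax type. Clusters whose single most-expressed marker is PanCK are
#' restricted to the tumour subsets (HLADR+/CD44+/Ki67+). Ties are broken in
#' favour of the larger signature, then lexicographically. Clusters whose
#' best score falls below `score_floor` are "unclassified". Annotation is a
#' pure function of cluster means and signatures.
#'
#' @param cluster_means matrix clusters x markers of mean scaled expression;
#'   rownames are cluster labels.
#' @param signatures named list of marker vectors, see [default_signatures()].
#' @param score_floor minimum admissible best score.
#' @param panck name of the tumour-defining epithelial marker.
#' @return named character vector: cluster label -> cell type.
#' @export
annotate_clusters <- function(cluster_means, signatures = default_signatures(),
                              score_floor = 0.5, panck = "PanCK") {
  missing <- setdiff(unique(unlist(signatures)), colnames(cluster_means))
  if (length(missing)) {
    stop("configuration error: signature markers absent from panel: ",
         paste(missing, collapse = ", "))
  }
  tumour_types <- names(signatures)[vapply(signatures, function(s)
    panck %in% s, logical(1))]
  score <- vapply(signatures, function(sig) {
    rowMeans(cluster_means[, sig, drop = FALSE])
  }, numeric(nrow(cluster_means)))
  if (is.null(dim(score))) score <- matrix(score, nrow = 1,
                                           dimnames = list(rownames(cluster_means),
                                                           names(signatures)))
  sig_size <- lengths(signatures)
  assign_one <- function(i) {
    sc <- score[i, ]
    if (panck %in% colnames(cluster_means) && length(tumour_types)) {
      top_marker <- colnames(cluster_means)[which.max(cluster_means[i, ])]
      if (top_marker == panck) sc <- sc[tumour_types]
    }
    best <- max(sc)
    if (best < score_floor) return("unclassified")
    cand <- names(sc)[sc >= best - 1e-12]
    if (length(cand) > 1) {
      cand <- cand[order(-sig_size[cand], cand)]
    }
    cand[1]
  }
  out <- vapply(seq_len(nrow(score)), assign_one, character(1))
  names(out) <- rownames(cluster_means)
  out
}

#' Cluster, annotate and label cells in one step
#'
#' Runs [transform_and_scale()], [reduce_and_adjust()], [cluster_cells()] and
#' [annotate_clusters()], merging clusters that map to the same type, and
#' attaches `cluster_id` and `cell_type` columns to the cell table.
#'
#' @param cells QC-filtered cell table with marker columns.
#' @param cfg a [pipeline_config()].
#' @param markers clustering marker panel.
#' @param signatures cell-type signatures.
#' @return list with `cells` (labelled table), `cluster_means` (clusters x
#'   markers), `map` (cluster -> type) and `scaled` (the expression matrix).
#' @export
phenotype_cells <- function(cells, cfg = pipeline_config(),
                            markers = tma_markers(),
                            signatures = default_signatures()) {
  scaled <- transform_and_scale(cells, markers, cfg)
  pcs <- reduce_and_adjust(scaled, cells$sample_id, cfg,
                           nuclear_area = cells$nuclear_area_um2)
  cl <- cluster_cells(pcs, cfg)
  cm <- rowsum(scaled, cl) / as.vector(table(cl))
  rownames(cm) <- sort(unique(cl))
  map <- annotate_clusters(cm, signatures, score_floor = cfg$score_floor)
  cells$cluster_id <- cl
  cells$cell_type <- unname(map[as.character(cl)])
  list(cells = cells, cluster_means = cm, map = map, scaled = scaled)
}

#' Concordance between assigned and true cell types
#'
#' Validation report for synthetic cohorts: confusion matrix, adjusted Rand
#' index and per-type F1 between assigned and ground-truth labels.
#'
#' @param assigned character vector of assigned types.
#' @param truth character vector of true types (same cells, same order).
#' @return list with `confusion`, `ari`, `f1` and `fraction_classified`.
#' @export
phenotyping_recovery_report <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  confusion <- table(truth = truth, assigned = assigned)
  types <- unique(truth)
  f1 <- vapply(types, function(ty) {
    tp <- sum(assigned == ty & truth == ty)
    fp <- sum(assigned == ty & truth != ty)
    fn <- sum(assigned != ty & truth == ty)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(confusion = confusion,
       ari = adjusted_rand_index(assigned, truth),
       f1 = f1,
       fraction_classified = mean(assigned != "unclassified"))
}
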