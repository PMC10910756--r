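#' Pipeline configuration
#'
#' Collects every numeric constant the pipeline fixes: the arcsinh cofactor
#' (150) used to variance-stabilize antibody intensities, the nuclear-area QC
#' window (10--220 um^2), the k = 30 / resolution = 2 Phenograph-style
#' clustering parameters, the 20 um interaction radius, 10-nearest-neighbour
#' windows grouped into 10 cellular neighbourhoods, the 30 um tumour margin,
#' the 100 um^2 minimum tumour-nest area, and the 2 um raster pixel used for
#' compartment masks.
#'
#' @param arcsinh_cofactor cofactor c in `asinh(x / c)`; 150 for this panel.
#' @param dapi_min minimum median DAPI intensity; `NULL` (default) uses the
#'   5th percentile of DAPI within each core, logged per core.
#' @param area_min,area_max nuclear-area QC window in um^2. Cells are removed
#'   when area < `area_min` or > `area_max` (strict inequalities).
#' @param n_pcs number of principal components kept for clustering.
#' @param knn_graph_k neighbours in the phenotyping kNN graph.
#' @param leiden_resolution Leiden resolution (modularity objective).
#' @param interaction_radius pairwise interaction radius in um (inclusive).
#' @param interaction_knn retained for knn-mode parity; inert in radius mode.
#' @param window_k size of a neighbourhood window including the index cell.
#' @param n_neighbourhoods number of k-means neighbourhood clusters.
#' @param margin_distance tumour-margin dilation distance in um.
#' @param min_nest_area minimum tumour component area in um^2.
#' @param raster_pixel compartment raster pixel size in um.
#' @param stamp_radius radius in um of the disc stamped per tumour cell.
#' @param closing_radius morphological closing radius in um (about one cell
#'   diameter) applied to the tumour mask.
#' @param pseudofrequency epsilon added to frequencies before log ratios.
#' @param score_floor minimum annotation score below which a cluster is
#'   labelled "unclassified".
#' @param seed integer seed controlling all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(arcsinh_cofactor = 150,
                            dapi_min = NULL,
                            area_min = 10,
                            area_max = 220,
                            n_pcs = 20,
                            knn_graph_k = 30,
                            leiden_resolution = 2,
                            interaction_radius = 20,
                            interaction_knn = 3,
                            window_k = 10,
                            n_neighbourhoods = 10,
                            margin_distance = 30,
                            min_nest_area = 100,
                            raster_pixel = 2,
                            stamp_radius = 5,
                            closing_radius = 10,
                            pseudofrequency = 1e-3,
                            score_floor = 0.5,
                            seed = 1L) {
  cfg <- list(
    arcsinh_cofactor = arcsinh_cofactor, dapi_min = dapi_min,
    area_min = area_min, area_max = area_max, n_pcs = n_pcs,
    knn_graph_k = knn_graph_k, leiden_resolution = leiden_resolution,
    interaction_radius = interaction_radius, interaction_knn = interaction_knn,
    window_k = window_k, n_neighbourhoods = n_neighbourhoods,
    margin_distance = margin_distance, min_nest_area = min_nest_area,
    raster_pixel = raster_pixel, stamp_radius = stamp_radius,
    closing_radius = closing_radius, pseudofrequency = pseudofrequency,
    score_floor = score_floor, seed = as.integer(seed)
  )
  num <- cfg[!vapply(cfg, is.null, logical(1))]
  num$seed <- NULL
  bad <- vapply(num, function(v) !is.numeric(v) || v <= 0, logical(1)) &
    !names(num) %in% c("dapi_min", "margin_distance")
  if (any(bad)) stop("all pipeline_config thresholds must be positive numbers")
  if (margin_distance < 0) stop("margin_distance must be nonnegative")
  if (area_min >= area_max) stop("area_min must be smaller than area_max")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Marker panel used for clustering
#'
#' The 25-marker panel retained after signal-to-noise QC: epithelial (PanCK),
#' immune-lineage (CD45, CD3e, CD4, CD8, CD20, ...), myeloid, vascular and
#' stromal markers. DAPI is carried in cell tables for QC but is not a
#' clustering marker.
#'
#' @return Character vector of 25 marker names.
#' @export
tma_markers <- function() {
  c("PanCK", "CD117", "Ki67", "CD45", "CD20", "CD3e", "CD4", "CD45RO",
    "CD45RA", "CD8", "CD107a", "CD44", "FoxP3", "CD25", "CD197", "CD11b",
    "CD14", "CD15", "CD68", "HLADR", "CD141", "CD31", "CD34", "Podoplanin",
    "Vim")
}

#' Canonical cell-type marker signatures
#'
#' The 19 cell types resolved in ICI-treated NSCLC TMAs, each defined by its
#' required-positive canonical markers: e.g. B cells are CD45+ CD45RA+ CD20+,
#' regulatory T cells are CD45+ CD4+ FoxP3+ CD25+, and PanCK+ tumour cells
#' split into HLADR+, CD44+ and Ki67+ subsets.
#'
#' @return Named list mapping cell-type name to character vector of markers.
#' @export
default_signatures <- function() {
  list(
    "B cell"                   = c("CD45", "CD45RA", "CD20"),
    "Blood vessel"             = c("CD31", "CD34"),
    "Lymphatic"                = c("Podoplanin"),
    "CD4 T cell"               = c("CD45", "CD3e", "CD4", "CD45RO"),
    "CD8 T cell"               = c("CD45", "CD3e", "CD8", "CD45RO"),
    "Granulocyte"              = c("CD15", "CD141", "CD11b"),
    "Vessel lymphocyte"        = c("CD45", "CD31"),
    "Lymphocyte"               = c("CD45"),
    "Macrophage"               = c("CD68", "CD107a", "CD14"),
    "Mast cell"                = c("CD117"),
    "Monocyte"                 = c("CD14"),
    "Proliferating lymphocyte" = c("CD45", "Ki67"),
    "Stroma"                   = c("Vim"),
    "Treg"                     = c("CD45", "CD4", "FoxP3", "CD25"),
    "Effector CD4 T cell"      = c("CD45", "CD4", "HLADR", "CD197"),
    "CCR7 CD8 T cell"          = c("CD45", "CD45RO", "CD8", "CD197"),
    "Tumour HLADR"             = c("PanCK", "HLADR"),
    "Tumour CD44"              = c("PanCK", "CD44"),
    "Tumour Ki67"              = c("PanCK", "Ki67")
  )
}

#' Tumour cell types
#'
#' The PanCK+ subsets treated as "tumour" by the compartment mask and as the
#' reference type of triplet spatial scores.
#'
#' @param signatures signature list; types whose signature contains PanCK.
#' @return Character vector of type names.
#' @export
tumour_cell_types <- function(signatures = default_signatures()) {
  names(signatures)[vapply(signatures, function(s) "PanCK" %in% s, logical(1))]
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
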