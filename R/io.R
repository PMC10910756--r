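#' Read a segmented cell table
#'
#' Reads a CSV cell table (one row per segmented cell), validates the schema
#' and coerces types. Required columns: `cell_id`, `sample_id`, `x_um`,
#' `y_um`, `nuclear_area_um2`; marker columns must be numeric and
#' nonnegative. Unknown columns are preserved as passthrough.
#'
#' @param path CSV file.
#' @param markers marker columns expected; `NULL` skips the marker check.
#' @return data.frame cell table.
#' @export
read_cell_table <- function(path, markers = NULL) {
  dt <- data.table::fread(path, data.table = FALSE)
  required <- c("cell_id", "sample_id", "x_um", "y_um", "nuclear_area_um2")
  missing <- setdiff(c(required, markers), names(dt))
  if (length(missing)) {
    stop("schema error: missing required columns: ",
         paste(missing, collapse = ", "))
  }
  for (col in c("x_um", "y_um", "nuclear_area_um2", markers)) {
    if (!is.numeric(dt[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))
      stop("schema error: non-numeric values in ", col,
           if (length(bad)) paste0(" (rows ", paste(head(bad, 5), collapse = ", "), ")"))
    }
  }
  if (!all(is.finite(dt$x_um)) || !all(is.finite(dt$y_um))) {
    stop("schema error: non-finite coordinates")
  }
  if (anyDuplicated(dt$cell_id)) stop("schema error: duplicate cell_id")
  dt$cell_id <- as.character(dt$cell_id)
  dt$sample_id <- as.character(dt$sample_id)
  dt
}

#' @rdname read_cell_table
#' @param cells cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  data.table::fwrite(cells, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires `sample_id`, `response` (R/NR), `os_days` (> 0) and `event`
#' (0/1); covariate columns pass through.
#'
#' @param path CSV file.
#' @return data.frame clinical table.
#' @export
read_clinical_table <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  missing <- setdiff(c("sample_id", "response", "os_days", "event"), names(dt))
  if (length(missing)) {
    stop("schema error: missing required columns: ",
         paste(missing, collapse = ", "))
  }
  if (any(!dt$response %in% c("R", "NR"))) {
    stop("schema error: response must be R or NR")
  }
  if (any(dt$os_days <= 0)) stop("schema error: os_days must be positive")
  dt$sample_id <- as.character(dt$sample_id)
  dt
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> QC -> normalize -> phenotype ->
#' compartments -> composition -> interactions -> neighbourhoods ->
#' spatial scores -> outcome statistics, writing every stage output and a
#' deterministic run manifest to `out_dir`. Any stage failure halts with the
#' stage name; outputs of completed stages persist. Wall-clock timings go to
#' a separate `timings.json` so reruns with the same seed produce
#' byte-identical manifests.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [pipeline_config()].
#' @param simulate generate a synthetic cohort instead of reading inputs.
#' @param synth a [synth_config()] when simulating.
#' @param cells_path,clinical_path input CSVs when not simulating.
#' @param write_geojson also export per-core compartment masks.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, cfg = pipeline_config(), simulate = FALSE,
                         synth = synth_config(seed = cfg$seed),
                         cells_path = NULL, clinical_path = NULL,
                         write_geojson = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "spatialtma",
                   version = as.character(packageVersion("spatialtma")),
                   seed = cfg$seed, config = unclass(cfg),
                   stages = list(), outputs = list())
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    data.table::fwrite(as.data.frame(obj), path)
    manifest$outputs[[file]] <<- unname(tools::md5sum(path))
    path
  }

  inputs <- stage("input", {
    if (simulate) {
      generate_cohort(synth)
    } else {
      if (is.null(cells_path) || !file.exists(cells_path)) {
        stop("cells file not found: ", cells_path %||% "<missing>")
      }
      if (is.null(clinical_path) || !file.exists(clinical_path)) {
        stop("clinical file not found: ", clinical_path %||% "<missing>")
      }
      list(cells = read_cell_table(cells_path, markers = tma_markers()),
           clinical = read_clinical_table(clinical_path), truth = NULL)
    }
  })
  cells <- inputs$cells
  clinical <- inputs$clinical
  manifest$stages$input <- list(n_cells = nrow(cells),
                                n_samples = nrow(clinical))
  if (simulate) emit(clinical, "clinical.csv")

  qc <- stage("qc", qc_filter_cells(cells, cfg))
  cells <- qc$cells
  if (nrow(cells) == 0) stop("pipeline halted at stage 'qc': no cells passed QC")
  manifest$stages$qc <- list(n_cells = nrow(cells),
                             removed = as.list(qc$removed))

  ph <- stage("phenotype", phenotype_cells(cells, cfg))
  cells <- ph$cells
  manifest$stages$phenotype <- list(
    n_clusters = length(unique(cells$cluster_id)),
    fraction_classified = mean(cells$cell_type != "unclassified"))
  emit(data.frame(cluster = rownames(ph$cluster_means), ph$cluster_means,
                  cell_type = unname(ph$map), check.names = FALSE),
       "cluster_means.csv")

  comp <- stage("compartments", compartmentalize(cells, cfg))
  cells <- comp$cells
  manifest$stages$compartments <-
    list(fractions = as.list(prop.table(table(cells$compartment))))
  if (write_geojson) {
    for (s in names(comp$geometries)) {
      compartment_to_geojson(comp$geometries[[s]],
                             file.path(out_dir, paste0("mask_", s, ".geojson")))
    }
  }
  emit(cells, "cells_typed.csv")

  props <- stage("composition", cell_proportions(cells))
  props_comp <- stage("composition",
                      cell_proportions(cells, stratify_by = "compartment"))
  emit(props, "proportions.csv")
  emit(props_comp, "proportions_by_compartment.csv")

  ints <- stage("interactions", all_pair_scores(cells, cfg = cfg))
  emit(ints, "interactions.csv")

  nbh <- stage("neighbourhoods", {
    typed <- cells[cells$cell_type != "unclassified", , drop = FALSE]
    win <- compute_windows(typed, window_k = cfg$window_k)
    cl <- cluster_neighbourhoods(win, cfg$n_neighbourhoods, seed = cfg$seed)
    list(typed = typed, labels = cl$labels, centroids = cl$centroids,
         freq = neighbourhood_frequencies(cl$labels, typed$sample_id,
                                          cfg$n_neighbourhoods))
  })
  emit(nbh$freq, "neighbourhood_frequencies.csv")
  emit(data.frame(neighbourhood = seq_len(nrow(nbh$centroids)),
                  nbh$centroids, check.names = FALSE), "neighbourhood_centroids.csv")

  ss <- stage("spatialscore", score_panel(cells, cfg = cfg))
  emit(ss, "spatialscore.csv")

  outc <- stage("outcomes", {
    features <- Reduce(function(a, b) merge(a, b, by = "sample_id"),
                       list(props, ints, nbh$freq, ss))
    rt <- feature_response_tests(features, clinical)
    sv <- survival_screen(features, clinical)
    enr <- differential_enrichment(nbh$typed, nbh$labels, clinical,
                                   eps = cfg$pseudofrequency)
    list(features = features, response = rt, survival = sv, enrichment = enr)
  })
  emit(outc$features, "features.csv")
  emit(outc$response, "response_tests.csv")
  if (!is.null(outc$survival)) emit(outc$survival, "survival_tests.csv")
  if (!is.null(outc$enrichment)) emit(outc$enrichment, "enrichment_tests.csv")

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
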