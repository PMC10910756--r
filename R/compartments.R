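# Raster-based tumour/margin/stroma geometry for one core.
#
# The original pixel-classifier mask is re-derived from annotated cell
# points: tumour-typed cells are stamped as discs on a 2 um raster, the mask
# is morphologically closed, components below the 100 um^2 nest threshold
# are dropped, and the margin is the 30 um Euclidean dilation minus the
# tumour itself. Morphology is implemented with an exact Euclidean distance
# transform so dilation/erosion radii are true distances in um.

new_geometry <- function(tumour, origin, px, params) {
  structure(list(tumour = tumour, margin = NULL, origin = origin, px = px,
                 params = params),
            class = "compartment_geometry")
}

# squared-distance raster (um) to the TRUE pixels of `mask`
mask_distance <- function(mask, px) {
  sqrt(cpp_edt_sq(mask)) * px
}

#' Build the tumour mask of one core
#'
#' Rasterizes tumour-typed cells (any PanCK+ subset) as discs of
#' `cfg$stamp_radius` um at `cfg$raster_pixel` resolution, applies a
#' morphological closing of `cfg$closing_radius` um to bridge adjacent cells,
#' labels connected components (8-connectivity) and drops components with
#' area below `cfg$min_nest_area` (100 um^2).
#'
#' @param cells cell table of one core with `x_um`, `y_um`, `cell_type`.
#' @param cfg a [pipeline_config()].
#' @param tumour_types cell types treated as tumour.
#' @return a `compartment_geometry` (tumour mask only; see [expand_margin()]).
#' @export
build_tumour_mask <- function(cells, cfg = pipeline_config(),
                              tumour_types = tumour_cell_types()) {
  if (!"cell_type" %in% names(cells)) stop("cell_type column required")
  px <- cfg$raster_pixel
  pad <- cfg$margin_distance + cfg$closing_radius + cfg$stamp_radius + 2 * px
  x0 <- min(cells$x_um) - pad
  y0 <- min(cells$y_um) - pad
  nc <- ceiling((max(cells$x_um) + pad - x0) / px) + 1
  nr <- ceiling((max(cells$y_um) + pad - y0) / px) + 1
  origin <- c(x = x0, y = y0)
  params <- cfg[c("raster_pixel", "stamp_radius", "closing_radius",
                  "min_nest_area", "margin_distance")]
  tum <- cells[cells$cell_type %in% tumour_types, , drop = FALSE]
  mask <- matrix(FALSE, nr, nc)
  if (nrow(tum) == 0) {
    warning("no tumour cells; core treated as all-stroma")
    return(new_geometry(mask, origin, px, params))
  }
  # stamp discs: mark pixels whose centre lies within stamp_radius of the
  # cell centre, using exact (sub-pixel) distances so masks converge as the
  # raster is refined
  kr <- ceiling(cfg$stamp_radius / px) + 1
  off <- expand.grid(di = -kr:kr, dj = -kr:kr)
  ci <- round((tum$y_um - y0) / px) + 1
  cj <- round((tum$x_um - x0) / px) + 1
  ii <- rep(ci, each = nrow(off)) + off$di
  jj <- rep(cj, each = nrow(off)) + off$dj
  py <- y0 + (ii - 1) * px
  pxx <- x0 + (jj - 1) * px
  dy <- py - rep(tum$y_um, each = nrow(off))
  dx <- pxx - rep(tum$x_um, each = nrow(off))
  ok <- dx^2 + dy^2 <= cfg$stamp_radius^2 &
    ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  mask[cbind(ii[ok], jj[ok])] <- TRUE
  # closing = erosion of the dilation, both by closing_radius
  if (cfg$closing_radius > 0) {
    dil <- mask_distance(mask, px) <= cfg$closing_radius
    mask <- mask_distance(!dil, px) > cfg$closing_radius
  }
  lab <- cpp_label_components(mask, conn8 = TRUE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * px^2 >= cfg$min_nest_area)
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  params$n_components <- length(keep)
  params$component_areas <- sizes[keep] * px^2
  new_geometry(mask, origin, px, params)
}

#' Expand the tumour mask into a peripheral margin band
#'
#' The margin is the Euclidean dilation of the tumour mask by
#' `cfg$margin_distance` (30 um) minus the tumour mask itself.
#'
#' @param geom a `compartment_geometry` from [build_tumour_mask()].
#' @param cfg a [pipeline_config()].
#' @return the geometry with its `margin` raster filled in.
#' @export
expand_margin <- function(geom, cfg = pipeline_config()) {
  stopifnot(inherits(geom, "compartment_geometry"))
  if (!any(geom$tumour)) {
    geom$margin <- geom$tumour
    return(geom)
  }
  d <- mask_distance(geom$tumour, geom$px)
  geom$margin <- d > 0 & d <= cfg$margin_distance
  geom
}

#' Assign each cell to tumour, margin or stroma
#'
#' Point-in-raster lookup with precedence tumour > margin > stroma. Cells
#' outside the raster extent are labelled stroma with a warning.
#'
#' @param cells cell table of the core the geometry was built from.
#' @param geom a `compartment_geometry` with margin computed.
#' @return character vector of labels, one per cell.
#' @export
assign_compartments <- function(cells, geom) {
  stopifnot(inherits(geom, "compartment_geometry"))
  if (is.null(geom$margin)) stop("margin not computed; call expand_margin() first")
  i <- round((cells$y_um - geom$origin["y"]) / geom$px) + 1
  j <- round((cells$x_um - geom$origin["x"]) / geom$px) + 1
  nr <- nrow(geom$tumour); nc <- ncol(geom$tumour)
  outside <- i < 1 | i > nr | j < 1 | j > nc
  if (any(outside)) {
    warning(sum(outside), " cells outside raster extent labelled stroma")
  }
  lab <- rep("stroma", nrow(cells))
  idx <- cbind(pmin(pmax(i, 1), nr), pmin(pmax(j, 1), nc))
  lab[!outside & geom$margin[idx]] <- "margin"
  lab[!outside & geom$tumour[idx]] <- "tumour"
  lab
}

#' Compute per-cell compartments for a whole cohort
#'
#' Builds the tumour/margin geometry per core and appends a `compartment`
#' column to the cell table.
#'
#' @param cells labelled cell table (`cell_type` present) for all cores.
#' @param cfg a [pipeline_config()].
#' @param tumour_types cell types treated as tumour.
#' @return list with `cells` (compartment column added) and `geometries`
#'   (named per-core list).
#' @export
compartmentalize <- function(cells, cfg = pipeline_config(),
                             tumour_types = tumour_cell_types()) {
  cells$compartment <- NA_character_
  geoms <- list()
  for (s in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == s)
    geom <- withCallingHandlers(
      expand_margin(build_tumour_mask(cells[idx, , drop = FALSE], cfg,
                                      tumour_types), cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    cells$compartment[idx] <- assign_compartments(cells[idx, , drop = FALSE],
                                                  geom)
    geoms[[s]] <- geom
  }
  list(cells = cells, geometries = geoms)
}

#' Export compartment geometry as GeoJSON polygons
#'
#' Traces the tumour and margin rasters with contour lines at 0.5 and writes
#' a GeoJSON FeatureCollection (QuPath-compatible interchange); coordinates
#' are um in the core frame.
#'
#' @param geom a `compartment_geometry`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
compartment_to_geojson <- function(geom, path) {
  stopifnot(inherits(geom, "compartment_geometry"))
  ring_features <- function(mask, label) {
    if (is.null(mask) || !any(mask)) return(list())
    nr <- nrow(mask); nc <- ncol(mask)
    # pad so contours close at the border; grid lines at pixel centres
    m <- matrix(0, nr + 2, nc + 2)
    m[2:(nr + 1), 2:(nc + 1)] <- mask * 1
    ys <- geom$origin["y"] + ((0:(nr + 1)) - 1) * geom$px
    xs <- geom$origin["x"] + ((0:(nc + 1)) - 1) * geom$px
    cl <- grDevices::contourLines(x = ys, y = xs, z = m, levels = 0.5)
    lapply(cl, function(ring) {
      coords <- cbind(ring$y, ring$x)  # matrix rows = y, cols = x
      coords <- rbind(coords, coords[1, ])
      list(type = "Feature",
           properties = list(classification = label),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(coords)),
                             function(k) as.numeric(coords[k, ])))))
    })
  }
  fc <- list(type = "FeatureCollection",
             features = c(ring_features(geom$tumour, "tumour"),
                          ring_features(geom$margin, "margin")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
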