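#' Triplet distance-ratio spatial score for one sample
#'
#' For each center cell of type `C`: `D1` is the distance to the nearest
#' partner cell of type `P` (excluding itself when `C == P`), `D2` the
#' distance to the nearest reference (tumour) cell of type set `T`, and the
#' per-cell ratio is `D2 / D1`. The sample score is the arithmetic mean of
#' the ratios: a higher score means partner proximity dominates tumour
#' proximity (a suppressive topology when the partner is a macrophage).
#' Coincident points get a distance floor (`raster_pixel / 10`) and a flag.
#' The score is invariant to rigid motions and uniform scaling.
#'
#' @param cells cell table of one sample.
#' @param center,partner single type names (C and P).
#' @param reference character vector of reference types (tumour subsets).
#' @param cfg a [pipeline_config()] (distance floor).
#' @param invert report `D1 / D2` instead.
#' @return list with `score`, `ratios`, `n_center` and `flag` (`NA` score
#'   when any of the three roles is absent).
#' @export
spatial_score <- function(cells, center, partner,
                          reference = tumour_cell_types(),
                          cfg = pipeline_config(), invert = FALSE) {
  ic <- which(cells$cell_type == center)
  ip <- which(cells$cell_type == partner)
  it <- which(cells$cell_type %in% reference)
  if (!length(ic) || !length(ip) || !length(it)) {
    return(list(score = NA_real_, ratios = numeric(0), n_center = 0L,
                flag = "missing_type"))
  }
  self_p <- if (center == partner) match(ic, ip, nomatch = 0L) else
    integer(length(ic)) # zeros = no self exclusion
  if (center == partner && length(ip) < 2) {
    return(list(score = NA_real_, ratios = numeric(0), n_center = 0L,
                flag = "missing_type"))
  }
  d1 <- cpp_nn_dist(cells$x_um[ic], cells$y_um[ic],
                    cells$x_um[ip], cells$y_um[ip], self_p)
  self_t <- match(ic, it, nomatch = 0L)
  d2 <- cpp_nn_dist(cells$x_um[ic], cells$y_um[ic],
                    cells$x_um[it], cells$y_um[it], self_t)
  floor_d <- cfg$raster_pixel / 10
  flag <- NA_character_
  if (any(d1 < floor_d) || any(d2 < floor_d)) flag <- "distance_floor"
  d1 <- pmax(d1, floor_d)
  d2 <- pmax(d2, floor_d)
  ratios <- if (invert) d1 / d2 else d2 / d1
  list(score = mean(ratios), ratios = ratios, n_center = length(ic),
       flag = flag)
}

#' Spatial-score panel across samples
#'
#' One feature per (center, partner) triplet per sample, named
#' `ss|<C>|<P>`; the reference set defaults to the PanCK+ tumour subsets.
#' Default triplets probe macrophage proximity to CD4 and CD8 T cells
#' relative to tumour distance. Samples lacking any role yield `NA`.
#'
#' @param cells labelled cell table for all samples.
#' @param triplets list of `list(center =, partner =)` pairs.
#' @param reference reference (tumour) types.
#' @param cfg a [pipeline_config()].
#' @return data.frame feature matrix with `sample_id` column.
#' @export
score_panel <- function(cells,
                        triplets = list(
                          list(center = "CD4 T cell", partner = "Macrophage"),
                          list(center = "CD8 T cell", partner = "Macrophage")),
                        reference = tumour_cell_types(),
                        cfg = pipeline_config()) {
  samples <- sort(unique(cells$sample_id))
  out <- matrix(NA_real_, length(samples), length(triplets),
                dimnames = list(samples, vapply(triplets, function(tp)
                  paste("ss", tp$center, tp$partner, sep = "|"), character(1))))
  for (s in samples) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    for (k in seq_along(triplets)) {
      tp <- triplets[[k]]
      sc <- spatial_score(sub, tp$center, tp$partner, reference, cfg)
      out[s, k] <- sc$score
    }
  }
  data.frame(sample_id = samples, as.data.frame(out), check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
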