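#' Default synthetic cell-type table
#'
#' Baseline per-type proportions for responder (R) and non-responder (NR)
#' cores. Defaults are identical between groups (a null cohort); planted
#' abundance effects are introduced by editing this table, e.g. doubling the
#' Treg proportion in NR at the expense of stroma.
#'
#' @return data.frame with columns `type`, `prop_R`, `prop_NR`.
#' @export
synth_cell_types <- function() {
  p <- c(
    "Tumour HLADR" = 0.09, "Tumour CD44" = 0.09, "Tumour Ki67" = 0.07,
    "Stroma" = 0.15, "Macrophage" = 0.07, "Monocyte" = 0.05,
    "CD4 T cell" = 0.08, "CD8 T cell" = 0.06, "Treg" = 0.02,
    "B cell" = 0.05, "Lymphocyte" = 0.05, "Granulocyte" = 0.04,
    "Mast cell" = 0.02, "Blood vessel" = 0.05, "Lymphatic" = 0.02,
    "Vessel lymphocyte" = 0.02, "Proliferating lymphocyte" = 0.02,
    "Effector CD4 T cell" = 0.03, "CCR7 CD8 T cell" = 0.02
  )
  data.frame(type = names(p), prop_R = unname(p), prop_NR = unname(p),
             stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Describes a synthetic multiplexed-imaging TMA cohort: core count and
#' response split, cells per 1 mm core, cell-type proportions per response
#' group, tumour-nest geometry, optional planted pairwise spatial attractions
#' and niche regions, marker-noise and per-core batch-shift magnitudes, and a
#' proportional-hazards survival model tied to true per-core features.
#'
#' @param n_cores number of TMA cores (one core = one patient sample).
#' @param responders number of cores labelled "R"; the rest are "NR".
#' @param cells_per_core cells placed in each core.
#' @param core_radius core radius in um (1 mm diameter cores by default).
#' @param cell_types data.frame as [synth_cell_types()]; proportions must sum
#'   to 1 within each group.
#' @param nest_spec list with `n_nests`, `radius` (um) and `tumour_fraction`:
#'   the fraction of tumour-typed cells placed uniformly inside a random nest
#'   rather than anywhere in the core.
#' @param attraction_spec list of planted pairwise attractions, each a list
#'   `(a, b, radius, strength_R, strength_NR)`: for each type-`a` cell, with
#'   probability `strength`, one unused type-`b` cell is relocated to within
#'   `radius` um of it (relocation thinning).
#' @param niche_spec `NULL`, or a list with `fraction_R`, `fraction_NR` (area
#'   fraction of the core covered by a circular niche) and `composition_R`,
#'   `composition_NR` (named type-proportion vectors); cells falling inside
#'   the niche have their types redrawn from the niche composition.
#' @param batch_sdlog sdlog of the per-core, per-marker multiplicative
#'   lognormal batch shift (FFPE staining variation).
#' @param noise_sdlog sdlog of the per-cell lognormal intensity noise.
#' @param survival_spec list with `baseline_hazard` (events/day),
#'   `coefficients` (named log-hazard coefficients on standardized true
#'   per-core type proportions, e.g. `c("Treg" = log(2))`) and `censoring`
#'   (list `type` in `"uniform"`, `"exponential"`, `"none"`, `"always"` with
#'   `min`/`max` or `rate`).
#' @param seed integer seed; a fixed seed makes the cohort fully reproducible.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cores = 16,
                         responders = 8,
                         cells_per_core = 2000,
                         core_radius = 500,
                         cell_types = synth_cell_types(),
                         nest_spec = list(n_nests = 3, radius = 120,
                                          tumour_fraction = 0.9),
                         attraction_spec = list(),
                         niche_spec = NULL,
                         batch_sdlog = 0.15,
                         noise_sdlog = 0.35,
                         survival_spec = list(
                           baseline_hazard = 1 / 1000,
                           coefficients = c(),
                           censoring = list(type = "uniform",
                                            min = 258, max = 3243)),
                         seed = 1L) {
  if (n_cores < 1 || cells_per_core < 1 || responders < 0 ||
      responders > n_cores) {
    stop("configuration error: counts must be positive and responders <= n_cores")
  }
  for (gc in c("prop_R", "prop_NR")) {
    if (abs(sum(cell_types[[gc]]) - 1) > 1e-8) {
      stop("configuration error: ", gc, " proportions do not sum to 1")
    }
    if (any(cell_types[[gc]] < 0)) stop("configuration error: negative proportion")
  }
  if (nest_spec$n_nests > 0 && nest_spec$radius <= 0) {
    stop("configuration error: nest radius must be positive")
  }
  for (at in attraction_spec) {
    st <- c(at$strength_R %||% 0, at$strength_NR %||% 0)
    if (any(st < 0 | st > 1)) {
      stop("configuration error: attraction strength must be in [0, 1]")
    }
    if (!all(c(at$a, at$b) %in% cell_types$type)) {
      stop("configuration error: attraction types not in cell_type table")
    }
  }
  if (survival_spec$baseline_hazard <= 0) {
    stop("configuration error: baseline hazard must be positive")
  }
  cfg <- list(n_cores = as.integer(n_cores),
              responders = as.integer(responders),
              cells_per_core = as.integer(cells_per_core),
              core_radius = core_radius, cell_types = cell_types,
              nest_spec = nest_spec, attraction_spec = attraction_spec,
              niche_spec = niche_spec, batch_sdlog = batch_sdlog,
              noise_sdlog = noise_sdlog, survival_spec = survival_spec,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# marker mean-intensity profile for one cell type.
# Positive signature markers are bright (300 a.u.); markers shared across many
# lineages (CD45 as pan-immune, CD14 on macrophages) are dimmer (120) so that
# signature-mean scoring separates nested signatures; everything else sits at
# autofluorescence background (10). DAPI is uniformly bright.
type_marker_means <- function(markers = tma_markers(),
                              signatures = default_signatures()) {
  hi <- 300; mid <- 120; lo <- 10
  prof <- matrix(lo, nrow = length(signatures), ncol = length(markers),
                 dimnames = list(names(signatures), markers))
  for (ty in names(signatures)) {
    prof[ty, signatures[[ty]]] <- hi
    if ("CD45" %in% signatures[[ty]] && length(signatures[[ty]]) > 1) {
      prof[ty, "CD45"] <- mid
    }
  }
  prof["Macrophage", "CD14"] <- mid
  prof
}

runif_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Place the cells of one synthetic core
#'
#' Draws cell types, concentrates tumour-typed cells inside circular nests,
#' optionally retypes cells inside a planted niche region, and applies
#' pairwise attraction by relocation thinning: for each type-`a` cell, with
#' probability `strength`, one unused type-`b` cell is moved to a uniform
#' point within the attraction radius. All coordinates are um, origin at the
#' core centre.
#'
#' @param n_cells number of cells.
#' @param type_probs named probability vector over cell types (sums to 1).
#' @param core_radius core radius, um.
#' @param nest_spec,niche_spec,margin_distance see [synth_config()];
#'   `margin_distance` sets the true margin band width for ground truth.
#' @param attractions list of lists `(a, b, radius, strength)` already
#'   resolved to this core's response group.
#' @param tumour_types types placed preferentially inside nests.
#' @return list with `cells` (data.frame `x`, `y`, `type`, `compartment`)
#'   and `nests` (matrix of nest centres).
#' @export
place_core <- function(n_cells, type_probs, core_radius,
                       nest_spec = list(n_nests = 3, radius = 120,
                                        tumour_fraction = 0.9),
                       attractions = list(),
                       niche_spec = NULL,
                       margin_distance = 30,
                       tumour_types = tumour_cell_types()) {
  if (n_cells / (pi * core_radius^2) > 0.5) {
    stop("generation error: ", n_cells, " cells exceed packing feasibility ",
         "for a core of radius ", core_radius, " um")
  }
  n_nests <- nest_spec$n_nests %||% 0
  nest_r <- nest_spec$radius %||% 0
  if (n_nests > 0 && nest_r > core_radius) {
    stop("generation error: nest radius exceeds core radius (nests must fit)")
  }
  types <- sample(names(type_probs), n_cells, replace = TRUE,
                  prob = type_probs)
  xy <- runif_disc(n_cells, core_radius)
  nests <- if (n_nests > 0) runif_disc(n_nests, core_radius - nest_r)
           else matrix(numeric(0), ncol = 2)
  if (n_nests > 0) {
    tum <- which(types %in% tumour_types)
    in_nest <- tum[runif(length(tum)) < (nest_spec$tumour_fraction %||% 1)]
    if (length(in_nest)) {
      which_nest <- sample.int(n_nests, length(in_nest), replace = TRUE)
      off <- runif_disc(length(in_nest), nest_r)
      xy[in_nest, ] <- nests[which_nest, , drop = FALSE] + off
    }
  }
  in_niche <- rep(FALSE, n_cells)
  if (!is.null(niche_spec) && (niche_spec$fraction %||% 0) > 0) {
    frac <- min(niche_spec$fraction, 1)
    niche_r <- core_radius * sqrt(frac)
    ctr <- runif_disc(1, max(core_radius - niche_r, 0))
    inside <- which((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 <= niche_r^2)
    ncomp <- niche_spec$composition
    ncomp <- ncomp / sum(ncomp)
    if (length(inside)) {
      types[inside] <- sample(names(ncomp), length(inside), replace = TRUE,
                              prob = ncomp)
      in_niche[inside] <- TRUE
    }
  }
  for (at in attractions) {
    s <- at$strength %||% 0
    if (s <= 0) next
    ia <- which(types == at$a)
    pool <- which(types == at$b)
    if (!length(ia) || !length(pool)) next
    pool <- sample(pool)
    used <- 0
    for (a in ia) {
      if (used >= length(pool)) break
      if (runif(1) >= s) next
      used <- used + 1
      b <- pool[used]
      repeat {
        p <- xy[a, ] + runif_disc(1, at$radius)
        if (sum(p^2) <= core_radius^2) break
      }
      xy[b, ] <- p
    }
  }
  comp <- rep("stroma", n_cells)
  if (n_nests > 0) {
    d2 <- vapply(seq_len(n_nests), function(k) {
      (xy[, 1] - nests[k, 1])^2 + (xy[, 2] - nests[k, 2])^2
    }, numeric(n_cells))
    dmin <- sqrt(if (n_nests == 1) d2 else apply(d2, 1, min))
    comp[dmin <= nest_r + margin_distance] <- "margin"
    comp[dmin <= nest_r] <- "tumour"
  }
  list(cells = data.frame(x = xy[, 1], y = xy[, 2], type = types,
                          compartment = comp, in_niche = in_niche,
                          stringsAsFactors = FALSE),
       nests = nests)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(coefficients * features))`; censoring is drawn
#' independently per the censoring spec and the event indicator records
#' whether the event preceded censoring.
#'
#' @param features data.frame or matrix of per-sample feature values (columns
#'   named as in `spec$coefficients`); may be `NULL` when no coefficients.
#' @param spec survival spec, see [synth_config()].
#' @return data.frame with `os_days` and `event` (1 = death observed).
#' @export
simulate_outcomes <- function(features, spec) {
  h0 <- spec$baseline_hazard
  if (is.null(h0) || h0 <= 0) {
    stop("configuration error: baseline hazard must be positive")
  }
  cf <- spec$coefficients
  if (length(cf)) {
    missing <- setdiff(names(cf), colnames(features))
    if (length(missing)) {
      stop("configuration error: survival coefficients reference unknown ",
           "features: ", paste(missing, collapse = ", "))
    }
    lp <- as.matrix(features[, names(cf), drop = FALSE]) %*% cf
    n <- nrow(features)
  } else {
    if (is.null(features)) stop("features (or their row count) required")
    lp <- rep(0, nrow(features))
    n <- nrow(features)
  }
  haz <- h0 * exp(as.numeric(lp))
  tt <- rexp(n, rate = haz)
  cens <- spec$censoring %||% list(type = "none")
  cmax <- switch(cens$type,
    uniform = runif(n, cens$min, cens$max),
    exponential = rexp(n, rate = cens$rate),
    none = rep(Inf, n),
    always = rep(NA_real_, n),
    stop("unknown censoring type: ", cens$type))
  if (identical(cens$type, "always")) {
    ct <- runif(n, cens$min %||% 258, cens$max %||% 3243)
    return(data.frame(os_days = ct, event = 0L))
  }
  data.frame(os_days = pmin(tt, cmax), event = as.integer(tt <= cmax))
}

#' Generate a synthetic TMA cohort with ground truth
#'
#' Builds one cell table row per segmented cell (um coordinates inside the
#' core disc, nuclear area, median marker intensities = type signature mean x
#' per-core batch shift x lognormal noise), a clinical table (response group,
#' survival under the configured proportional-hazards model, covariates) and
#' a ground-truth object carrying true per-cell types/compartments and the
#' planted effects.
#'
#' @param config a [synth_config()].
#' @param markers simulate marker intensity columns (`TRUE`); power/recovery
#'   simulations that only consume true labels can skip them for speed. The
#'   placed geometry and labels are identical either way.
#' @return list with `cells`, `clinical`, `truth`.
#' @export
generate_cohort <- function(config, markers = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cores
  sample_ids <- sprintf("core_%02d", seq_len(n))
  response <- rep(c("R", "NR"), c(config$responders, n - config$responders))
  signatures <- default_signatures()
  tumour_types <- tumour_cell_types(signatures)
  prof <- type_marker_means()
  marker_names <- colnames(prof)

  cores <- vector("list", n)
  for (i in seq_len(n)) {
    g <- response[i]
    probs <- setNames(
      if (g == "R") config$cell_types$prop_R else config$cell_types$prop_NR,
      config$cell_types$type)
    atts <- lapply(config$attraction_spec, function(at) {
      list(a = at$a, b = at$b, radius = at$radius %||% 20,
           strength = if (g == "R") at$strength_R %||% 0
                      else at$strength_NR %||% 0)
    })
    niche <- NULL
    if (!is.null(config$niche_spec)) {
      ns <- config$niche_spec
      niche <- list(
        fraction = if (g == "R") ns$fraction_R %||% 0 else ns$fraction_NR %||% 0,
        composition = if (g == "R") ns$composition_R %||% ns$composition
                      else ns$composition_NR %||% ns$composition)
    }
    pc <- place_core(config$cells_per_core, probs, config$core_radius,
                     nest_spec = config$nest_spec, attractions = atts,
                     niche_spec = niche, tumour_types = tumour_types)
    cc <- pc$cells
    cc$sample_id <- sample_ids[i]
    cores[[i]] <- cc
  }
  all_cells <- do.call(rbind, cores)
  m <- nrow(all_cells)
  cell_id <- sprintf("%s_c%05d", all_cells$sample_id,
                     unlist(lapply(cores, function(cc) seq_len(nrow(cc)))))

  is_tum <- all_cells$type %in% tumour_types
  area <- exp(rnorm(m, mean = ifelse(is_tum, log(90), log(40)),
                    sd = 0.25))
  cells <- data.frame(cell_id = cell_id, sample_id = all_cells$sample_id,
                      x_um = all_cells$x, y_um = all_cells$y,
                      nuclear_area_um2 = area, stringsAsFactors = FALSE)
  if (markers) {
    batch <- matrix(rlnorm(n * (length(marker_names) + 1),
                           sdlog = config$batch_sdlog),
                    nrow = n,
                    dimnames = list(sample_ids, c("DAPI", marker_names)))
    core_idx <- match(cells$sample_id, sample_ids)
    noise <- function() rlnorm(m, sdlog = config$noise_sdlog)
    cells$DAPI <- 500 * batch[cbind(core_idx, 1L)] * noise()
    for (mk in marker_names) {
      mu <- prof[cbind(match(all_cells$type, rownames(prof)),
                       match(mk, marker_names))]
      cells[[mk]] <- mu * batch[cbind(core_idx, match(mk, marker_names) + 1L)] *
        noise()
    }
  }

  # true per-core type proportions drive the survival model
  tab <- table(all_cells$sample_id, all_cells$type)
  features_true <- as.data.frame.matrix(tab / rowSums(tab))
  features_true <- features_true[sample_ids, , drop = FALSE]
  features_std <- as.data.frame(lapply(features_true, zscore))
  rownames(features_std) <- sample_ids
  surv <- simulate_outcomes(features_std, config$survival_spec)
  clinical <- data.frame(
    sample_id = sample_ids, response = response,
    os_days = surv$os_days, event = surv$event,
    sex = sample(c("M", "F"), n, TRUE, prob = c(0.6, 0.4)),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                   prob = c(0.35, 0.17, 0.34, 0.14)),
    histology = sample(c("Adenocarcinoma", "Squamous Cell Carcinoma"), n,
                       TRUE, prob = c(0.69, 0.31)),
    agent = sample(c("NIVOLUMAB", "PEMBROLIZUMAB", "DURVALUMAB"), n, TRUE,
                   prob = c(0.8, 0.17, 0.03)),
    stringsAsFactors = FALSE)
  truth <- list(
    cells = data.frame(cell_id = cells$cell_id,
                       sample_id = cells$sample_id,
                       true_type = all_cells$type,
                       true_compartment = all_cells$compartment,
                       in_niche = all_cells$in_niche,
                       stringsAsFactors = FALSE),
    response = setNames(response, sample_ids),
    features_true = features_true,
    attraction_spec = config$attraction_spec,
    niche_spec = config$niche_spec,
    hazard_coefficients = config$survival_spec$coefficients)
  list(cells = cells, clinical = clinical, truth = truth)
}
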