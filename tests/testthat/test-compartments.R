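test_that("a single stamped cell falls below the 100 um2 nest threshold", {
  cells <- data.frame(cell_id = "1", sample_id = "s1", x_um = 0, y_um = 0,
                      nuclear_area_um2 = 50, cell_type = "Tumour CD44",
                      stringsAsFactors = FALSE)
  geom <- build_tumour_mask(cells, pipeline_config())
  # disc of radius 5 um has area ~78.5 < 100: dropped
  expect_false(any(geom$tumour))
  expect_equal(geom$params$n_components, 0)
})

test_that("a dense blob rasterizes to one component of the right area", {
  # cells to radius 95, stamped by 5 um -> tissue blob of radius ~100 um
  geom <- build_tumour_mask(disc_cells(95), pipeline_config())
  expect_equal(geom$params$n_components, 1)
  area <- sum(geom$tumour) * geom$px^2
  expect_lt(abs(area - pi * 100^2) / (pi * 100^2), 0.05)
})

test_that("distant blobs stay distinct components", {
  cells <- rbind(disc_cells(40), disc_cells(40, centre = c(500, 0)))
  cells$cell_id <- as.character(seq_len(nrow(cells)))
  geom <- build_tumour_mask(cells, pipeline_config())
  expect_equal(geom$params$n_components, 2)
})

test_that("margin band matches the annulus closed form", {
  cfg <- pipeline_config()
  geom <- expand_margin(build_tumour_mask(disc_cells(45), cfg), cfg)
  # tumour radius ~50; margin = annulus between 50 and 80
  marg_area <- sum(geom$margin) * geom$px^2
  expected <- pi * (80^2 - 50^2)
  expect_lt(abs(marg_area - expected) / expected, 0.05)
  expect_false(any(geom$tumour & geom$margin))
})

test_that("empty mask and zero dilation both give an empty margin", {
  cells <- disc_cells(40)
  cells$cell_type <- "Stroma"
  expect_warning(geom <- build_tumour_mask(cells, pipeline_config()),
                 "all-stroma")
  geom <- expand_margin(geom, pipeline_config())
  expect_false(any(geom$margin))
  cfg0 <- pipeline_config(margin_distance = 1e-9)
  geom0 <- expand_margin(build_tumour_mask(disc_cells(45), cfg0), cfg0)
  expect_false(any(geom0$margin))
})

test_that("cells are assigned by distance to the tumour mask", {
  cfg <- pipeline_config()
  base <- disc_cells(45)
  probes <- data.frame(cell_id = c("p1", "p2", "p3"), sample_id = "s1",
                       x_um = c(0, 65, 100), y_um = 0,
                       nuclear_area_um2 = 50, cell_type = "Stroma",
                       stringsAsFactors = FALSE)
  geom <- expand_margin(build_tumour_mask(base, cfg), cfg)
  # the farthest probe sits just beyond the raster extent: stroma by contract
  lab <- suppressWarnings(assign_compartments(probes, geom))
  # 0 = blob centre; 65 = 15 um beyond the ~50 um boundary; 100 = 50 um beyond
  expect_equal(lab, c("tumour", "margin", "stroma"))
  expect_warning(
    assign_compartments(data.frame(x_um = 1e5, y_um = 1e5), geom),
    "outside")
})

test_that("raster assignment equals an exact distance-to-mask oracle", {
  set.seed(8)
  cfg <- pipeline_config()
  cells <- random_cells(400, types = c("Tumour CD44", "Stroma"), radius = 250)
  geom <- expand_margin(build_tumour_mask(cells, cfg), cfg)
  probes <- random_cells(1000, types = "Stroma", radius = 300)
  lab <- suppressWarnings(assign_compartments(probes, geom))
  # oracle: exact Euclidean distance from each probe's pixel centre to the
  # nearest tumour pixel centre
  tum_idx <- which(geom$tumour, arr.ind = TRUE)
  ty <- geom$origin["y"] + (tum_idx[, 1] - 1) * geom$px
  tx <- geom$origin["x"] + (tum_idx[, 2] - 1) * geom$px
  pi_ <- round((probes$y_um - geom$origin["y"]) / geom$px)
  pj_ <- round((probes$x_um - geom$origin["x"]) / geom$px)
  py <- geom$origin["y"] + pi_ * geom$px
  px_ <- geom$origin["x"] + pj_ * geom$px
  dmin <- vapply(seq_len(nrow(probes)), function(i) {
    sqrt(min((px_[i] - tx)^2 + (py[i] - ty)^2))
  }, numeric(1))
  oracle <- ifelse(dmin == 0, "tumour",
                   ifelse(dmin <= cfg$margin_distance, "margin", "stroma"))
  expect_equal(lab, oracle)
  # compartment labels partition the cells
  expect_true(all(lab %in% c("tumour", "margin", "stroma")))
})

test_that("halving the raster pixel changes few labels", {
  # nested tumour geometry (the realistic case); disagreement is confined to
  # an O(pixel)-wide band along the mask and margin contours
  rates <- vapply(1:6, function(seed) {
    set.seed(seed)
    pc <- place_core(1000, c("Tumour CD44" = 0.3, "Stroma" = 0.7),
                     core_radius = 500)
    cells <- data.frame(cell_id = as.character(1:1000), sample_id = "s1",
                        x_um = pc$cells$x, y_um = pc$cells$y,
                        nuclear_area_um2 = 50, cell_type = pc$cells$type,
                        stringsAsFactors = FALSE)
    l2 <- compartmentalize(cells, pipeline_config(raster_pixel = 2))$cells$compartment
    l1 <- compartmentalize(cells, pipeline_config(raster_pixel = 1))$cells$compartment
    mean(l1 != l2)
  }, numeric(1))
  expect_lt(mean(rates), 0.01)
})

test_that("geojson export is a valid FeatureCollection", {
  cfg <- pipeline_config()
  geom <- expand_margin(build_tumour_mask(disc_cells(45), cfg), cfg)
  path <- tempfile(fileext = ".geojson")
  compartment_to_geojson(geom, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  ring <- f1$geometry$coordinates[[1]]
  expect_identical(ring[[1]], ring[[length(ring)]])  # closed ring
})
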