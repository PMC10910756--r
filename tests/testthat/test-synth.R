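test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_cores = 4, responders = 2, cells_per_core = 300,
                      seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("invalid synthetic configurations are rejected", {
  ct <- synth_cell_types()
  ct$prop_R[1] <- ct$prop_R[1] + 0.1
  expect_error(synth_config(cell_types = ct), "sum to 1")
  expect_error(synth_config(n_cores = 0), "counts")
  expect_error(synth_config(attraction_spec = list(
    list(a = "Treg", b = "Monocyte", strength_NR = 1.5))), "strength")
  expect_error(
    synth_config(survival_spec = list(baseline_hazard = -1,
                                      coefficients = c(),
                                      censoring = list(type = "none"))),
    "hazard")
  expect_error(
    place_core(1e7, c(A = 1), core_radius = 100),
    "packing")
})

test_that("nest geometry confines tumour cells and defines compartments", {
  set.seed(5)
  pc <- place_core(500, c("Tumour CD44" = 0.5, "Stroma" = 0.5),
                   core_radius = 500,
                   nest_spec = list(n_nests = 1, radius = 100,
                                    tumour_fraction = 1))
  tum <- pc$cells[pc$cells$type == "Tumour CD44", ]
  d <- sqrt((tum$x - pc$nests[1, 1])^2 + (tum$y - pc$nests[1, 2])^2)
  expect_true(all(d <= 100 + 1e-9))
  expect_true(all(pc$cells$compartment[pc$cells$type == "Tumour CD44"] == "tumour"))
  far <- sqrt((pc$cells$x - pc$nests[1, 1])^2 +
              (pc$cells$y - pc$nests[1, 2])^2) > 130
  expect_true(all(pc$cells$compartment[far] == "stroma"))
})

test_that("attraction strength 1 places a partner within radius of every target", {
  set.seed(7)
  pc <- place_core(1000, c(Treg = 0.05, Monocyte = 0.4, Stroma = 0.55),
                   core_radius = 500,
                   nest_spec = list(n_nests = 0, radius = 0,
                                    tumour_fraction = 0),
                   attractions = list(list(a = "Treg", b = "Monocyte",
                                           radius = 20, strength = 1)))
  tr <- pc$cells[pc$cells$type == "Treg", ]
  mo <- pc$cells[pc$cells$type == "Monocyte", ]
  has_nb <- vapply(seq_len(nrow(tr)), function(i) {
    any(sqrt((tr$x[i] - mo$x)^2 + (tr$y[i] - mo$y)^2) <= 20 + 1e-9)
  }, logical(1))
  expect_true(all(has_nb))
  expect_true(all(pc$cells$x^2 + pc$cells$y^2 <= 500^2 + 1e-6))
})

test_that("attraction strength behaves as a binomial thinning probability", {
  set.seed(42)
  frac_with_nb <- function(strength) {
    pc <- place_core(2000, c(Treg = 0.1, Monocyte = 0.3, Stroma = 0.6),
                     core_radius = 500,
                     nest_spec = list(n_nests = 0, radius = 0,
                                      tumour_fraction = 0),
                     attractions = list(list(a = "Treg", b = "Monocyte",
                                             radius = 20, strength = strength)))
    tr <- pc$cells[pc$cells$type == "Treg", ]
    mo <- pc$cells[pc$cells$type == "Monocyte", ]
    has <- vapply(seq_len(nrow(tr)), function(i) {
      any((tr$x[i] - mo$x)^2 + (tr$y[i] - mo$y)^2 <= 400)
    }, logical(1))
    c(hits = sum(has), n = length(has))
  }
  reps0 <- vapply(1:20, function(i) frac_with_nb(0), numeric(2))
  reps5 <- vapply(1:20, function(i) frac_with_nb(0.5), numeric(2))
  bg <- sum(reps0["hits", ]) / sum(reps0["n", ])
  p_obs <- sum(reps5["hits", ]) / sum(reps5["n", ])
  p_exp <- 0.5 + 0.5 * bg  # planted 50% plus background among the rest
  se <- sqrt(p_exp * (1 - p_exp) / sum(reps5["n", ]) +
             bg * (1 - bg) / sum(reps0["n", ]))
  expect_lt(abs(p_obs - p_exp), 3 * se + 0.01)
})

test_that("survival simulation honours its null, planted and degenerate modes", {
  set.seed(9)
  # null model: log-rank p over median splits of an unrelated feature is
  # roughly uniform
  ps <- replicate(30, {
    f <- data.frame(f = rnorm(40))
    cl <- cbind(simulate_outcomes(f, list(baseline_hazard = 1 / 500,
                                          coefficients = c(),
                                          censoring = list(type = "none"))),
                sample_id = as.character(1:40))
    km_median_split(f$f, cl)$logrank_p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.25)
  # degenerate: everything censored, downstream survival refuses
  cl <- cbind(simulate_outcomes(data.frame(f = rnorm(20)),
                                list(baseline_hazard = 1 / 500,
                                     coefficients = c(),
                                     censoring = list(type = "always"))),
              sample_id = as.character(1:20))
  expect_true(all(cl$event == 0))
  expect_error(cox_continuous(rnorm(20), cl), "no events")
  # unknown coefficient names are a configuration error
  expect_error(
    simulate_outcomes(data.frame(f = rnorm(5)),
                      list(baseline_hazard = 1, coefficients = c(g = 1),
                           censoring = list(type = "none"))),
    "unknown")
})

test_that("generated marker intensities carry the planted signatures", {
  coh <- generate_cohort(synth_config(n_cores = 2, responders = 1,
                                      cells_per_core = 500, seed = 2))
  truth <- coh$truth$cells
  cells <- coh$cells
  treg <- truth$true_type == "Treg"
  expect_gt(median(cells$FoxP3[treg]), 5 * median(cells$FoxP3[!treg]))
  tum <- truth$true_type %in% tumour_cell_types()
  expect_gt(median(cells$PanCK[tum]), 5 * median(cells$PanCK[!tum]))
  # tumour nuclei are systematically larger
  expect_gt(median(cells$nuclear_area_um2[tum]),
            median(cells$nuclear_area_um2[!tum]))
})
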