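test_that("windows of a homogeneous field are pure and rows sum to 1", {
  set.seed(1)
  cells <- random_cells(60, types = "T")
  win <- compute_windows(cells, window_k = 10)
  expect_true(all(win[, "T"] == 1))
  set.seed(2)
  mixed <- random_cells(200)
  w <- compute_windows(mixed, window_k = 10)
  expect_equal(unname(rowSums(w)), rep(1, 200))
})

test_that("windows equal the brute-force sorted-distance oracle", {
  set.seed(3)
  cells <- random_cells(500)
  types <- sort(unique(cells$cell_type))
  w <- compute_windows(cells, window_k = 10, types = types)
  expect_equal(unname(w), unname(brute_windows(cells, 10, types)))
  # exclude-self variant
  w2 <- compute_windows(cells, window_k = 10, types = types,
                        include_self = FALSE)
  expect_equal(unname(w2),
               unname(brute_windows(cells, 10, types, include_self = FALSE)))
})

test_that("windows never cross sample boundaries and handle small samples", {
  set.seed(4)
  a <- random_cells(50, types = "A", sample_id = "a")
  b <- random_cells(50, types = "B", sample_id = "b")
  b$x_um <- b$x_um + 5  # overlap the cores spatially
  both <- rbind(a, b)
  w <- compute_windows(both, window_k = 10, types = c("A", "B"))
  expect_true(all(w[both$sample_id == "a", "A"] == 1))
  expect_true(all(w[both$sample_id == "b", "B"] == 1))
  tiny <- random_cells(5, types = c("A", "B"), sample_id = "tiny")
  expect_warning(wt <- compute_windows(tiny, window_k = 10,
                                       types = c("A", "B")),
                 "fewer cells")
  expect_equal(unname(rowSums(wt)), rep(1, 5))
})

test_that("separable compositions are clustered perfectly and deterministically", {
  set.seed(5)
  r1 <- random_cells(300, types = c("A", "B"), sample_id = "s1")
  r2 <- random_cells(300, types = c("C", "D"), sample_id = "s2")
  cells <- rbind(r1, r2)
  w <- compute_windows(cells, window_k = 10,
                       types = c("A", "B", "C", "D"))
  cl <- cluster_neighbourhoods(w, n_clusters = 2, seed = 7)
  expect_equal(adjusted_rand_index(cl$labels, cells$sample_id), 1)
  cl2 <- cluster_neighbourhoods(w, n_clusters = 2, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  expect_equal(unname(rowSums(cl$centroids)), rep(1, 2), tolerance = 1e-9)
})

test_that("identical windows collapse to one occupied cluster", {
  w <- matrix(rep(c(0.5, 0.5), each = 30), 30, 2,
              dimnames = list(NULL, c("A", "B")))
  expect_warning(cl <- cluster_neighbourhoods(w, n_clusters = 3), "identical")
  expect_equal(unique(cl$labels), 1L)
})

test_that("neighbourhood frequencies are per-sample fractions", {
  labels <- c(1, 1, 2, 2, 2, 1)
  sample_id <- c("a", "a", "a", "b", "b", "b")
  fm <- neighbourhood_frequencies(labels, sample_id, n_clusters = 3)
  expect_equal(fm[fm$sample_id == "a", "cn|1"], 2 / 3)
  expect_equal(fm[fm$sample_id == "b", "cn|2"], 2 / 3)
  expect_equal(unname(rowSums(fm[, -1])), c(1, 1))
  one <- neighbourhood_frequencies(rep(1L, 5), rep("a", 5), n_clusters = 1)
  expect_equal(one[["cn|1"]], 1)
})

test_that("enrichment is finite with the pseudofrequency and null-calibrated", {
  set.seed(6)
  cells <- do.call(rbind, lapply(sprintf("s%02d", 1:12), function(s)
    random_cells(200, sample_id = s)))
  labels <- sample(1:3, nrow(cells), replace = TRUE)
  groups <- setNames(rep(c("R", "NR"), each = 6), sprintf("s%02d", 1:12))
  res <- differential_enrichment(cells, labels, groups, eps = 1e-3)
  expect_true(all(is.finite(res$coefficient)))
  expect_true(all(res$p > 0 & res$p <= 1))
  # random labels: no systematic enrichment differences
  expect_lt(mean(abs(res$coefficient)), 0.5)
  expect_lt(mean(res$p < 0.05), 0.25)
})

test_that("permuting response labels destroys a planted enrichment signal", {
  detect <- function(seed, permute) {
    cfg <- synth_config(
      n_cores = 12, responders = 6, cells_per_core = 800,
      niche_spec = list(fraction_R = 0.2, fraction_NR = 0.2,
                        composition_R = niche_mix(cd4 = 0.10, cd8 = 0.30),
                        composition_NR = niche_mix()),
      seed = seed)
    coh <- generate_cohort(cfg, markers = FALSE)
    tr <- coh$truth$cells
    cells <- data.frame(cell_id = tr$cell_id, sample_id = tr$sample_id,
                        x_um = coh$cells$x_um, y_um = coh$cells$y_um,
                        cell_type = tr$true_type, stringsAsFactors = FALSE)
    groups <- coh$truth$response
    if (permute) {
      set.seed(seed + 100)
      groups <- setNames(sample(groups), names(groups))
    }
    labels <- ifelse(tr$in_niche, 2L, 1L)
    res <- differential_enrichment(cells, labels, groups)
    row <- res[res$neighbourhood == 2 & res$cell_type == "CD8 T cell", ]
    abs(row$coefficient)
  }
  planted <- vapply(1:5, detect, numeric(1), permute = FALSE)
  permuted <- vapply(1:5, detect, numeric(1), permute = TRUE)
  expect_gt(mean(planted), mean(permuted))
  expect_gt(mean(planted), 0.3)
})
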