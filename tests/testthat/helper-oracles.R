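# Brute-force oracles and small fixtures shared across test files.
# Oracles are deliberately naive O(n^2) implementations, independent of the
# package's spatial-index code paths.

random_cells <- function(n, types = c("A", "B", "C", "D"), radius = 300,
                         sample_id = "s1") {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(cell_id = sprintf("%s_%04d", sample_id, seq_len(n)),
             sample_id = sample_id,
             x_um = r * cos(th), y_um = r * sin(th),
             nuclear_area_um2 = runif(n, 20, 100),
             cell_type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# dense grid of tumour cells filling a disc, for rasterization fixtures
disc_cells <- function(r_inner, spacing = 4, type = "Tumour CD44",
                       centre = c(0, 0)) {
  g <- expand.grid(x = seq(-r_inner, r_inner, by = spacing),
                   y = seq(-r_inner, r_inner, by = spacing))
  g <- g[g$x^2 + g$y^2 <= r_inner^2, ]
  data.frame(cell_id = as.character(seq_len(nrow(g))), sample_id = "s1",
             x_um = g$x + centre[1], y_um = g$y + centre[2],
             nuclear_area_um2 = 50, cell_type = type,
             stringsAsFactors = FALSE)
}

# unordered close-pair count and density by exhaustive double loop
brute_pair_density <- function(cells, a, b, r) {
  ia <- which(cells$cell_type == a)
  ib <- which(cells$cell_type == b)
  if (!length(ia) || !length(ib)) return(NA_real_)
  d <- sqrt(outer(cells$x_um[ia], cells$x_um[ib], "-")^2 +
            outer(cells$y_um[ia], cells$y_um[ib], "-")^2)
  if (a == b) {
    cnt <- sum(d[upper.tri(d)] <= r)
    den <- length(ia)
  } else {
    cnt <- sum(d <= r)
    den <- length(ia) + length(ib)
  }
  cnt / den
}

# window compositions by full distance sort, ties broken by index
brute_windows <- function(cells, k, types, include_self = TRUE) {
  n <- nrow(cells)
  d <- sqrt(outer(cells$x_um, cells$x_um, "-")^2 +
            outer(cells$y_um, cells$y_um, "-")^2)
  out <- matrix(0, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])
    nb <- (seq_len(n)[-i])[ord]
    members <- if (include_self) c(i, nb[seq_len(k - 1)]) else nb[seq_len(k)]
    tt <- table(factor(cells$cell_type[members], levels = types))
    out[i, ] <- tt / length(members)
  }
  out
}

brute_spatial_score <- function(cells, center, partner, reference,
                                floor_d = 0.2) {
  ic <- which(cells$cell_type == center)
  ip <- which(cells$cell_type == partner)
  it <- which(cells$cell_type %in% reference)
  if (!length(ic) || !length(ip) || !length(it)) return(NA_real_)
  ratios <- vapply(ic, function(i) {
    dp <- sqrt((cells$x_um[i] - cells$x_um[ip])^2 +
               (cells$y_um[i] - cells$y_um[ip])^2)
    dp <- dp[ip != i]
    dt <- sqrt((cells$x_um[i] - cells$x_um[it])^2 +
               (cells$y_um[i] - cells$y_um[it])^2)
    dt <- dt[it != i]
    max(min(dt), floor_d) / max(min(dp), floor_d)
  }, numeric(1))
  mean(ratios)
}

# clinical table reproducing the published cohort's marginal counts:
# 14 responders (13 alive; 9 M; 12 adenocarcinoma; 1 DURVALUMAB, 10
# NIVOLUMAB, 3 PEMBROLIZUMAB) and 21 non-responders (8 alive; 12 M; 12
# adenocarcinoma; 18 NIVOLUMAB, 3 PEMBROLIZUMAB)
table1_clinical <- function() {
  data.frame(
    sample_id = sprintf("p%02d", 1:35),
    response = rep(c("R", "NR"), c(14, 21)),
    os_days = rep(1000, 35),
    event = c(rep(0, 13), 1, rep(0, 8), rep(1, 13)),
    sex = c(rep("M", 9), rep("F", 5), rep("M", 12), rep("F", 9)),
    stage = c(rep(c("I", "II", "III", "IV"), c(4, 3, 5, 2)),
              rep(c("I", "II", "III", "IV"), c(8, 3, 7, 3))),
    histology = c(rep(c("Adenocarcinoma", "Squamous Cell Carcinoma"), c(12, 2)),
                  rep(c("Adenocarcinoma", "Squamous Cell Carcinoma"), c(12, 9))),
    agent = c(rep(c("DURVALUMAB", "NIVOLUMAB", "PEMBROLIZUMAB"), c(1, 10, 3)),
              rep(c("NIVOLUMAB", "PEMBROLIZUMAB"), c(18, 3))),
    stringsAsFactors = FALSE)
}

# planted-effect synthetic configs used by recovery tests
config_treg_doubled <- function(n_cores = 32, cells = 3000, seed = 1) {
  ct <- synth_cell_types()
  ct$prop_NR[ct$type == "Treg"] <- 0.04
  ct$prop_NR[ct$type == "Stroma"] <- 0.13
  synth_config(n_cores = n_cores, responders = n_cores / 2,
               cells_per_core = cells, cell_types = ct, seed = seed)
}

config_attraction <- function(a = "Treg", b = "Monocyte", strength_NR = 0.6,
                              n_cores = 32, cells = 2000, seed = 1) {
  synth_config(n_cores = n_cores, responders = n_cores / 2,
               cells_per_core = cells,
               attraction_spec = list(list(a = a, b = b, radius = 20,
                                           strength_R = 0,
                                           strength_NR = strength_NR)),
               seed = seed)
}

niche_mix <- function(cd4 = 0.25, cd8 = 0.15) {
  c("CD4 T cell" = cd4, "CD8 T cell" = cd8, "Macrophage" = 0.2,
    "B cell" = 0.2, "Lymphocyte" = 0.4 - cd4 - cd8 + 0.2)
}
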