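#' Proximity-density interaction score for one type pair in one sample
#'
#' Counts unordered pairs of cells (one of type `a`, one of type `b`,
#' distinct cells) whose Euclidean distance is at most `radius` (boundary
#' inclusive), and normalizes by the number of cells of the pair's types:
#' `|A| + |B|` for distinct types, `|A|` for a same-type pair (self-pairs
#' excluded, each unordered pair counted once). Computed with a grid spatial
#' index but contractually equal to the O(n^2) scan.
#'
#' @param cells cell table of one sample with `x_um`, `y_um`, `cell_type`.
#' @param a,b cell-type names.
#' @param radius interaction radius in um.
#' @return list with `pair_count`, `denominator`, `density` (`NA` with a flag
#'   when either type is absent).
#' @export
proximity_density <- function(cells, a, b, radius = 20) {
  ia <- which(cells$cell_type == a)
  ib <- which(cells$cell_type == b)
  if (!length(ia) || !length(ib)) {
    return(list(pair_count = NA_integer_, denominator = 0L,
                density = NA_real_, flag = "missing_type"))
  }
  if (a == b) {
    pr <- cpp_close_pairs(cells$x_um[ia], cells$y_um[ia], radius)
    pair_count <- nrow(pr)
    denominator <- length(ia)
  } else {
    idx <- c(ia, ib)
    pr <- cpp_close_pairs(cells$x_um[idx], cells$y_um[idx], radius)
    na <- length(ia)
    # a pair qualifies when its members land on opposite sides of the split
    cross <- (pr$i <= na) != (pr$j <= na)
    pair_count <- sum(cross)
    denominator <- length(ia) + length(ib)
  }
  list(pair_count = as.integer(pair_count), denominator = as.integer(denominator),
       density = pair_count / denominator, flag = NA_character_)
}

#' Proximity densities for all type pairs across samples
#'
#' One feature per unordered type pair (including same-type pairs) per
#' sample, named `int|<a>|<b>`; missing scores (absent types) propagate as
#' `NA`. The output feeds [differential_abundance()] and the outcome models.
#'
#' @param cells labelled cell table for all samples.
#' @param types type universe; defaults to types present.
#' @param cfg a [pipeline_config()]; uses `interaction_radius`.
#' @return data.frame feature matrix with `sample_id` column.
#' @export
all_pair_scores <- function(cells, types = NULL, cfg = pipeline_config()) {
  cells <- cells[cells$cell_type != "unclassified", , drop = FALSE]
  types <- types %||% sort(unique(cells$cell_type))
  samples <- sort(unique(cells$sample_id))
  pairs <- list()
  for (i in seq_along(types)) {
    for (j in i:length(types)) pairs[[length(pairs) + 1]] <- c(types[i], types[j])
  }
  r <- cfg$interaction_radius
  out <- matrix(NA_real_, length(samples), length(pairs),
                dimnames = list(samples, vapply(pairs, function(p)
                  paste("int", p[1], p[2], sep = "|"), character(1))))
  for (s in samples) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    # enumerate close pairs once per sample, then tabulate by type pair
    pr <- cpp_close_pairs(sub$x_um, sub$y_um, r)
    t1 <- sub$cell_type[pr$i]; t2 <- sub$cell_type[pr$j]
    key <- ifelse(t1 <= t2, paste("int", t1, t2, sep = "|"),
                  paste("int", t2, t1, sep = "|"))
    counts <- table(key)
    ntype <- table(factor(sub$cell_type, levels = types))
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      na <- ntype[p[1]]; nb <- ntype[p[2]]
      if (na == 0 || nb == 0) next
      den <- if (p[1] == p[2]) na else na + nb
      cnt <- counts[colnames(out)[k]]
      out[s, k] <- (if (is.na(cnt)) 0 else cnt) / den
    }
  }
  data.frame(sample_id = samples, as.data.frame(out), check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
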