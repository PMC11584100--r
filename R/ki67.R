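#' Per-hexagon Ki67 positivity with minimum-cell filter
#'
#' Hexagons with fewer than `min_cells` tumor cells are considered
#' insufficiently sampled and excluded (default 50).
#'
#' @param counts data.frame with `q`, `r`, `n_tumor`, `n_tumor_pos`
#'   (e.g. from [assign_cells()]).
#' @param min_cells minimum tumor-cell count for inclusion.
#' @return data.frame `q`, `r`, `n_tumor`, `n_tumor_pos`, `percent`
#'   restricted to retained hexagons.
#' @export
hexagon_positivity <- function(counts, min_cells = 50L) {
  keep <- counts$n_tumor >= min_cells
  if (!any(keep))
    stop("insufficient tumor sampling: no hexagon reaches ", min_cells,
         " cells")
  out <- counts[keep, c("q", "r", "n_tumor", "n_tumor_pos")]
  out$percent <- 100 * out$n_tumor_pos / out$n_tumor
  rownames(out) <- NULL
  out
}

#' Rank Ki67 percentages into 10 intervals
#'
#' Interval 1 is [0, 10]; interval k >= 2 is (10(k-1), 10k] — i.e.
#' 0%-10%, >10%-20%, >20%-30%, and so on.
#'
#' @param percent numeric vector in [0, 100].
#' @return integer ranks in 1..10.
#' @export
rank_percentages <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE) || any(is.na(percent)))
    stop("percentages must lie in [0, 100]")
  pmax(1L, as.integer(ceiling(percent / 10)))
}

#' Rank co-occurrence matrix over adjacent hexagons
#'
#' For every unordered pair of included hexagons within hexagonal distance
#' `distance` (default 1, the 6-neighbour adjacency) with ranks (i, j), the
#' entries (i, j) and (j, i) are both incremented; the matrix is then
#' normalized to sum to 1. Pairs involving excluded (filtered-out) hexagons
#' never contribute.
#'
#' @param field data.frame with `q`, `r` and `rank` (1..`n_levels`) for the
#'   included hexagons.
#' @param n_levels number of rank levels (default 10).
#' @param distance neighbourhood radius in hexagon steps (default 1).
#' @return `n_levels` x `n_levels` symmetric matrix summing to 1.
#' @export
cooccurrence_matrix <- function(field, n_levels = 10L, distance = 1L) {
  stopifnot(all(c("q", "r", "rank") %in% names(field)))
  n <- nrow(field)
  if (n < 2L) stop("no adjacent hexagon pairs: co-occurrence undefined")
  P <- matrix(0, n_levels, n_levels)
  key <- new.env(parent = emptyenv(), size = n)
  for (i in seq_len(n)) assign(paste(field$q[i], field$r[i]), i, envir = key)
  offs <- if (distance == 1L) hex_neighbor_offsets() else {
    g <- expand.grid(q = -distance:distance, r = -distance:distance)
    g <- g[hex_distance(g$q, g$r, 0L, 0L) %in% seq_len(distance), ]
    as.matrix(g)
  }
  for (i in seq_len(n)) {
    for (k in seq_len(nrow(offs))) {
      qn <- field$q[i] + offs[k, 1]; rn <- field$r[i] + offs[k, 2]
      j <- mget(paste(qn, rn), envir = key, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) {   # each unordered pair once
        a <- field$rank[i]; b <- field$rank[j]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  tot <- sum(P)
  if (tot == 0) stop("no adjacent hexagon pairs: co-occurrence undefined")
  P / tot
}

#' Haralick texture indicators of a co-occurrence matrix
#'
#' entropy = -sum p log p (0 log 0 := 0); contrast = sum (i-j)^2 p;
#' dissimilarity = sum |i-j| p; homogeneity (inverse difference moment) =
#' sum p / (1 + (i-j)^2); energy = sum p^2.
#'
#' @param P normalized co-occurrence matrix (entries >= 0, summing to 1).
#' @param base logarithm base for entropy; default `exp(1)` (natural log),
#'   giving a maximum of log(100) ~ 4.605 for a 10x10 matrix.
#' @return named list with `entropy`, `homogeneity`, `contrast`,
#'   `dissimilarity`, `energy`.
#' @export
haralick_indicators <- function(P, base = exp(1)) {
  if (any(P < 0)) stop("co-occurrence matrix must be nonnegative")
  if (abs(sum(P) - 1) > 1e-9) stop("co-occurrence matrix must sum to 1")
  idx <- seq_len(nrow(P))
  D <- outer(idx, idx, "-")
  nz <- P > 0
  list(
    entropy = -sum(P[nz] * log(P[nz], base = base)),
    homogeneity = sum(P / (1 + D^2)),
    contrast = sum(D^2 * P),
    dissimilarity = sum(abs(D) * P),
    energy = sum(P^2))
}

#' Ki67 heterogeneity indicators for one slide
#'
#' Composes the per-hexagon positivity filter, 10-interval ranking,
#' neighbour co-occurrence and Haralick indicators; also reports the global
#' (pooled over retained hexagons) Ki67 percentage.
#'
#' @param counts per-hexagon counts from [assign_cells()].
#' @param min_cells minimum tumor cells per hexagon (default 50).
#' @param base entropy logarithm base.
#' @param distance co-occurrence neighbourhood radius.
#' @return one-row data.frame: `ki67_pct_global`, `ki67_entropy`,
#'   `ki67_homogeneity`, `ki67_contrast`, `ki67_dissimilarity`,
#'   `ki67_energy`, `n_hexagons_included`.
#' @export
ki67_heterogeneity <- function(counts, min_cells = 50L, base = exp(1),
                               distance = 1L) {
  pos <- hexagon_positivity(counts, min_cells = min_cells)
  pos$rank <- rank_percentages(pos$percent)
  P <- cooccurrence_matrix(pos, n_levels = 10L, distance = distance)
  h <- haralick_indicators(P, base = base)
  data.frame(
    ki67_pct_global = 100 * sum(pos$n_tumor_pos) / sum(pos$n_tumor),
    ki67_entropy = h$entropy, ki67_homogeneity = h$homogeneity,
    ki67_contrast = h$contrast, ki67_dissimilarity = h$dissimilarity,
    ki67_energy = h$energy, n_hexagons_included = nrow(pos))
}
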