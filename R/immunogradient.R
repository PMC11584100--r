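#' Edge-detection configuration for the tumor-stroma interface
#'
#' @param tau abrupt-change threshold on the tumor-area-fraction difference
#'   between a hexagon's two opposite neighbours along one of the three grid
#'   axes (default 0.5).
#' @param half_width interface-zone half-width in ranks (default 4; with the
#'   one-rank-wide edge this gives a nine-hexagon-wide zone, ranks -4..+4).
#' @param max_background background-area fraction above which a hexagon is
#'   excluded from ranking (default 0.5).
#' @param min_edge_tumor_frac minimum tumor fraction an edge hexagon itself
#'   must contain (default 0 = no constraint).
#' @param cap value reported for the immunodrop when its denominator is zero
#'   but the numerator is positive.
#' @return object of class `edge_config`.
#' @export
edge_config <- function(tau = 0.5, half_width = 4L, max_background = 0.5,
                        min_edge_tumor_frac = 0, cap = 100) {
  if (tau <= 0 || tau > 1) stop("`tau` must lie in (0, 1]")
  if (half_width < 1) stop("`half_width` must be >= 1")
  structure(list(tau = tau, half_width = as.integer(half_width),
                 max_background = max_background,
                 min_edge_tumor_frac = min_edge_tumor_frac, cap = cap),
            class = "edge_config")
}

# named lookup q,r -> row index
hex_index_env <- function(q, r) {
  env <- new.env(parent = emptyenv(), size = length(q))
  for (i in seq_along(q)) assign(paste(q[i], r[i]), i, envir = env)
  env
}

hex_lookup <- function(env, q, r) {
  v <- mget(paste(q, r), envir = env, ifnotfound = list(NA_integer_))
  unlist(v, use.names = FALSE)
}

#' Detect tumor-edge hexagons from hexagon-level tissue composition
#'
#' A hexagon is flagged when, along at least one of the three grid axes, the
#' tumor-area-fraction difference between its two opposite neighbours
#' exceeds `tau` AND the magnitude of that difference is a local maximum
#' along the same axis (non-maximum suppression, keeping the edge band one
#' hexagon thick). Flagged hexagons are then classified by the tissue on
#' the low-tumor side: only tumor-stroma transitions are retained as edge
#' (tumor-background transitions, e.g. at the section border, are
#' discarded).
#'
#' @param hexes data.frame from [tissue_fractions()] (needs `q`, `r`,
#'   `frac_tumor`, `frac_stroma`, `frac_background`).
#' @param config an [edge_config()].
#' @return logical vector over rows of `hexes`: edge membership.
#' @export
detect_tumor_edge <- function(hexes, config = edge_config()) {
  dominant <- dominant_class(hexes, config)
  if (!any(dominant == "tumor") || !any(dominant == "stroma"))
    stop("no interface: tissue map lacks tumor or stroma hexagons")
  env <- hex_index_env(hexes$q, hexes$r)
  offs <- hex_neighbor_offsets()
  n <- nrow(hexes)
  nb <- matrix(NA_integer_, n, 6)
  for (k in 1:6)
    nb[, k] <- hex_lookup(env, hexes$q + offs[k, 1], hexes$r + offs[k, 2])
  ft <- hexes$frac_tumor
  edge <- rep(FALSE, n)
  low_side_stroma <- rep(FALSE, n)
  for (axis in 1:3) {
    a <- nb[, 2 * axis - 1]; b <- nb[, 2 * axis]
    ok <- !is.na(a) & !is.na(b)
    diffs <- rep(NA_real_, n)
    diffs[ok] <- ft[a[ok]] - ft[b[ok]]
    mag <- abs(diffs)
    # non-maximum suppression along the axis: a missing or NA-diff
    # neighbour never outranks the hexagon
    mag_a <- ifelse(is.na(a), -Inf, mag[ifelse(is.na(a), 1L, a)])
    mag_a[is.na(mag_a)] <- -Inf
    mag_b <- ifelse(is.na(b), -Inf, mag[ifelse(is.na(b), 1L, b)])
    mag_b[is.na(mag_b)] <- -Inf
    hit <- ok & mag > config$tau & mag >= mag_a & mag >= mag_b
    if (!any(hit)) next
    low <- ifelse(diffs >= 0, b, a)  # neighbour on the low-tumor side
    ls <- hit & hexes$frac_stroma[low] >= hexes$frac_background[low]
    edge <- edge | hit
    low_side_stroma <- low_side_stroma | (ls %in% TRUE)
  }
  # keep only tumor-stroma transitions, drop background-dominant hexagons
  edge <- edge & low_side_stroma & dominant != "background" &
    hexes$frac_tumor >= config$min_edge_tumor_frac
  if (!any(edge))
    stop("no interface: no tumor-stroma transition detected")
  edge
}

dominant_class <- function(hexes, config) {
  out <- ifelse(hexes$frac_background > config$max_background, "background",
                ifelse(hexes$frac_tumor >= hexes$frac_stroma,
                       "tumor", "stroma"))
  out
}

#' Assign signed interface ranks by hexagonal distance from the edge
#'
#' |rank| is the breadth-first-search distance to the nearest edge hexagon
#' over the 6-neighbour adjacency among non-background hexagons; the sign
#' comes from the hexagon's dominant tissue class (tumor positive, stroma
#' negative); edge hexagons have rank 0. Background-dominant hexagons and
#' hexagons unreachable from the edge are excluded (rank NA).
#'
#' @param hexes data.frame from [tissue_fractions()].
#' @param edge logical edge membership over rows of `hexes` (from
#'   [detect_tumor_edge()]).
#' @param config an [edge_config()].
#' @return integer vector of ranks over rows of `hexes` (NA = excluded).
#' @export
assign_ranks <- function(hexes, edge, config = edge_config()) {
  if (!any(edge)) stop("empty edge set")
  n <- nrow(hexes)
  dominant <- dominant_class(hexes, config)
  include <- dominant != "background"
  env <- hex_index_env(hexes$q, hexes$r)
  offs <- hex_neighbor_offsets()
  dist <- rep(NA_integer_, n)
  frontier <- which(edge)
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0) {
    nxt <- integer()
    for (k in 1:6) {
      cand <- hex_lookup(env, hexes$q[frontier] + offs[k, 1],
                         hexes$r[frontier] + offs[k, 2])
      cand <- cand[!is.na(cand)]
      cand <- cand[include[cand] & is.na(dist[cand])]
      if (length(cand)) { dist[cand] <- d + 1L; nxt <- c(nxt, cand) }
    }
    frontier <- unique(nxt)
    d <- d + 1L
  }
  sign <- ifelse(dominant == "tumor", 1L, -1L)
  rank <- ifelse(edge, 0L, sign * dist)
  rank[!include] <- NA_integer_
  rank
}

#' CD8+ cell density of hexagons (cells per mm^2 of analyzed tissue)
#'
#' The denominator is the analyzed tissue area (tumor + stroma), so
#' background-heavy hexagons are not artificially diluted. Hexagons with
#' zero analyzed area get NA.
#'
#' @param n_cd8 CD8+ cell counts.
#' @param tissue_area_mm2 analyzed-tissue areas in mm^2.
#' @return densities in cells/mm^2.
#' @export
cd8_density <- function(n_cd8, tissue_area_mm2) {
  ifelse(tissue_area_mm2 > 0, n_cd8 / tissue_area_mm2, NA_real_)
}

#' Extract the interface zone from ranked hexagons
#'
#' Retains hexagons with |rank| <= `half_width` (default 4: a nine-rank-wide
#' zone, the central edge being one rank wide) and attaches CD8 densities.
#'
#' @param hexes data.frame from [tissue_fractions()] merged with CD8 counts
#'   (column `n_cd8`; see [hex_aggregate()]).
#' @param rank integer ranks from [assign_ranks()].
#' @param config an [edge_config()].
#' @return object of class `interface_zone`: data.frame `q`, `r`, `rank`,
#'   `cd8_count`, `tissue_area_mm2`, `density`, with the config attached.
#' @export
extract_interface_zone <- function(hexes, rank, config = edge_config()) {
  keep <- !is.na(rank) & abs(rank) <= config$half_width &
    hexes$tissue_area_mm2 > 0
  iz <- data.frame(q = hexes$q[keep], r = hexes$r[keep], rank = rank[keep],
                   cd8_count = hexes$n_cd8[keep],
                   tissue_area_mm2 = hexes$tissue_area_mm2[keep])
  iz$density <- cd8_density(iz$cd8_count, iz$tissue_area_mm2)
  missing_ranks <- setdiff(-config$half_width:config$half_width, iz$rank)
  if (length(missing_ranks))
    warning("interface zone rank classes absent: ",
            paste(missing_ranks, collapse = ", "))
  structure(iz, class = c("interface_zone", "data.frame"), config = config)
}

#' Aspect mean/SD indicators of the interface zone
#'
#' Means and standard deviations of per-hexagon CD8+ density over the three
#' aspects: stroma (ranks -half_width..-1), tumor edge (rank 0), tumor
#' (ranks 1..half_width).
#'
#' @param iz an [extract_interface_zone()] result.
#' @return named list `CD8_m_S`, `CD8_sd_S`, `CD8_m_TE`, `CD8_sd_TE`,
#'   `CD8_m_T`, `CD8_sd_T` (NA where an aspect has no hexagons; SD is 0 for
#'   singleton aspects).
#' @export
aspect_statistics <- function(iz) {
  stat <- function(d) {
    if (length(d) == 0) return(c(NA_real_, NA_real_))
    c(mean(d), if (length(d) > 1) stats::sd(d) else 0)
  }
  s <- stat(iz$density[iz$rank < 0])
  e <- stat(iz$density[iz$rank == 0])
  t <- stat(iz$density[iz$rank > 0])
  list(CD8_m_S = s[1], CD8_sd_S = s[2], CD8_m_TE = e[1], CD8_sd_TE = e[2],
       CD8_m_T = t[1], CD8_sd_T = t[2])
}

#' Immunodrop: density ratio across the tumor edge
#'
#' Ratio of the mean CD8+ density at rank -1 (stroma aspect) to the mean
#' density at rank +1 (tumor aspect). A zero denominator with positive
#' numerator returns the configured cap; 0/0 returns 1. Both degenerate
#' cases carry a `flag` attribute.
#'
#' @param iz an [extract_interface_zone()] result.
#' @return the immunodrop ratio (unitless).
#' @export
immunodrop <- function(iz) {
  cfg <- attr(iz, "config")
  num <- mean(iz$density[iz$rank == -1L])
  den <- mean(iz$density[iz$rank == 1L])
  if (is.nan(num) || is.nan(den))
    stop("immunodrop undefined: rank -1 or +1 class is empty")
  if (den == 0 && num == 0) return(structure(1, flag = "both_zero"))
  if (den == 0) return(structure(cfg$cap, flag = "capped"))
  num / den
}

#' Center of mass of the CD8+ density profile
#'
#' Density-weighted mean rank: CM = sum(r * Dbar_r) / sum(Dbar_r) where
#' Dbar_r is the mean per-hexagon density at rank r; rank classes with no
#' hexagons are omitted from both sums. Negative values indicate
#' stroma-concentrated infiltrates.
#'
#' @param iz an [extract_interface_zone()] result.
#' @return CM in [-half_width, +half_width].
#' @export
center_of_mass <- function(iz) {
  prof <- tapply(iz$density, iz$rank, mean)
  ranks <- as.integer(names(prof))
  tot <- sum(prof)
  if (tot <= 0) return(structure(NA_real_, flag = "zero_mass"))
  sum(ranks * prof) / tot
}

#' All eight CD8 immunogradient indicators for one interface zone
#'
#' @param iz an [extract_interface_zone()] result.
#' @return one-row data.frame with columns `CD8_m_S`, `CD8_sd_S`,
#'   `CD8_m_TE`, `CD8_sd_TE`, `CD8_m_T`, `CD8_sd_T`, `CD8_CM`, `CD8_ID`.
#' @export
immunogradient_indicators <- function(iz) {
  a <- aspect_statistics(iz)
  data.frame(CD8_m_S = a$CD8_m_S, CD8_sd_S = a$CD8_sd_S,
             CD8_m_TE = a$CD8_m_TE, CD8_sd_TE = a$CD8_sd_TE,
             CD8_m_T = a$CD8_m_T, CD8_sd_T = a$CD8_sd_T,
             CD8_CM = as.numeric(center_of_mass(iz)),
             CD8_ID = as.numeric(immunodrop(iz)))
}
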