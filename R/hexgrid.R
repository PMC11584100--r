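#' Hexagonal grid configuration
#'
#' Defines a pointy-top hexagonal tessellation used to subsample digital
#' image analysis output. Defaults correspond to 0.5 um/pixel scans: the
#' Ki67 grid uses hexagons with a 1050-pixel circumcircle diameter (side
#' 525 px = 262.5 um) and the CD8 grid a 260-pixel diameter (side 130 px =
#' 65 um). "Diameter" is read as the circumcircle diameter, i.e. twice the
#' side length; this is the only reading under which the stated pixel and
#' micrometre figures are mutually consistent at 0.5 um/pixel.
#'
#' The grid origin is offset by a uniform random shift within one hexagon
#' pitch, drawn from `seed`, so that indicator statistics do not depend on
#' a privileged alignment between grid and tissue.
#'
#' @param side_px hexagon side length (= circumcircle radius) in pixels.
#' @param resolution_um_px image resolution in micrometres per pixel.
#' @param seed integer seed controlling the random origin offset.
#' @return an object of class `hex_config`.
#' @export
hex_config <- function(side_px = 130, resolution_um_px = 0.5, seed = 1L) {
  if (!is.numeric(side_px) || length(side_px) != 1L || !is.finite(side_px) || side_px <= 0)
    stop("`side_px` must be a single positive number")
  if (!is.numeric(resolution_um_px) || resolution_um_px <= 0)
    stop("`resolution_um_px` must be positive")
  structure(
    list(side_px = side_px, resolution_um_px = resolution_um_px,
         seed = as.integer(seed)),
    class = "hex_config"
  )
}

#' Side length in micrometres implied by a grid configuration
#' @param config a `hex_config`.
#' @return side length in um.
#' @export
hex_side_um <- function(config) config$side_px * config$resolution_um_px

#' Physical area of one full hexagon in mm^2
#'
#' Closed form (3*sqrt(3)/2) * side^2 with side in um; for a 65-um side this
#' is about 0.010977 mm^2.
#' @param config a `hex_config`.
#' @return area in mm^2.
#' @export
hex_area_mm2 <- function(config) {
  s_um <- hex_side_um(config)
  (3 * sqrt(3) / 2) * s_um^2 / 1e6
}

# Pointy-top axial layout: center(q, r) = origin + s * (sqrt(3)*(q + r/2), 1.5*r)
axial_to_xy <- function(q, r, side, origin) {
  list(x = origin[1] + side * sqrt(3) * (q + r / 2),
       y = origin[2] + side * 1.5 * r)
}

# Fractional axial coordinates of points, then cube rounding: maps every
# point of the plane to exactly one hexagon (half-open boundary behaviour
# follows from deterministic rounding ties).
xy_to_axial <- function(x, y, side, origin) {
  px <- (x - origin[1]) / side
  py <- (y - origin[2]) / side
  qf <- sqrt(3) / 3 * px - py / 3
  rf <- 2 / 3 * py
  cube_round(qf, rf)
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

#' Build a randomized hexagonal grid covering a pixel rectangle
#'
#' Enumerates all hexagons whose centers can cover any part of the rectangle
#' `[0, width] x [0, height]` (one extra ring of margin is kept so boundary
#' pixels are always covered). The origin offset is drawn uniformly within
#' one hexagon pitch from `config$seed`.
#'
#' @param width_px,height_px rectangle dimensions in pixels.
#' @param config a [hex_config()].
#' @return an object of class `hex_grid`: list with the config, the origin,
#'   and a data.frame `hexes` with columns `q`, `r`, `center_x_px`,
#'   `center_y_px`.
#' @export
make_grid <- function(width_px, height_px, config) {
  if (width_px <= 0 || height_px <= 0) stop("grid bounds must be nonempty")
  s <- config$side_px
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(config$seed)
    stats::runif(2)
  })
  origin <- c(rng[1] * sqrt(3) * s, rng[2] * 1.5 * s)

  # enumerate candidate axial range with a one-hex margin
  r_min <- floor((0 - origin[2]) / (1.5 * s)) - 1L
  r_max <- ceiling((height_px - origin[2]) / (1.5 * s)) + 1L
  rows <- seq.int(r_min, r_max)
  hex_list <- lapply(rows, function(r) {
    q_min <- floor((0 - origin[1]) / (sqrt(3) * s) - r / 2) - 1L
    q_max <- ceiling((width_px - origin[1]) / (sqrt(3) * s) - r / 2) + 1L
    q <- seq.int(q_min, q_max)
    data.frame(q = q, r = r)
  })
  hexes <- do.call(rbind, hex_list)
  ctr <- axial_to_xy(hexes$q, hexes$r, s, origin)
  hexes$center_x_px <- ctr$x
  hexes$center_y_px <- ctr$y
  # keep only hexagons that can intersect the bounds (center within half a
  # hexagon width/height of the rectangle)
  keep <- hexes$center_x_px >= -sqrt(3) / 2 * s &
    hexes$center_x_px <= width_px + sqrt(3) / 2 * s &
    hexes$center_y_px >= -s & hexes$center_y_px <= height_px + s
  hexes <- hexes[keep, , drop = FALSE]
  rownames(hexes) <- NULL

  structure(
    list(config = config, origin = origin,
         width_px = width_px, height_px = height_px, hexes = hexes),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: side %g px (%g um), %d hexagons over %g x %g px\n",
              x$config$side_px, hex_side_um(x$config), nrow(x$hexes),
              x$width_px, x$height_px))
  invisible(x)
}

#' Map point coordinates to axial hexagon coordinates
#'
#' @param grid a [make_grid()] result.
#' @param x,y point coordinates in pixels.
#' @return list with integer vectors `q`, `r`.
#' @export
locate_hex <- function(grid, x, y) {
  xy_to_axial(x, y, grid$config$side_px, grid$origin)
}

#' Hexagonal lattice distance between axial coordinates
#'
#' Shortest path length over the 6-neighbour adjacency.
#' @param q1,r1,q2,r2 axial coordinates (vectorized).
#' @return integer distances.
#' @export
hex_distance <- function(q1, r1, q2, r2) {
  dq <- q1 - q2; dr <- r1 - r2
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

# The six axial neighbour offsets, ordered as three opposite pairs:
# rows (1,2), (3,4), (5,6) are the three grid axes.
hex_neighbor_offsets <- function() {
  cbind(q = c(1L, -1L, 0L, 0L, 1L, -1L),
        r = c(0L, 0L, 1L, -1L, -1L, 1L))
}

#' Assign cells to hexagons and count per class / positivity
#'
#' Every cell is assigned to exactly one hexagon (the tessellation is a
#' partition of the plane); totals are conserved.
#'
#' @param cells a cell table with columns `x_px`, `y_px`, `marker`
#'   (`"tumor_ki67"` or `"cd8"`) and `positive` (0/1).
#' @param grid a [make_grid()] result.
#' @return data.frame keyed by `q`, `r` with columns `n_tumor`,
#'   `n_tumor_pos`, `n_cd8`; one row per hexagon containing at least one
#'   cell.
#' @export
assign_cells <- function(cells, grid) {
  stopifnot(all(c("x_px", "y_px", "marker", "positive") %in% names(cells)))
  if (nrow(cells) == 0L) {
    return(data.frame(q = integer(), r = integer(), n_tumor = integer(),
                      n_tumor_pos = integer(), n_cd8 = integer()))
  }
  bad <- cells$x_px < 0 | cells$x_px > grid$width_px |
    cells$y_px < 0 | cells$y_px > grid$height_px
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("cell outside grid bounds at (%.1f, %.1f)",
                 cells$x_px[i], cells$y_px[i]))
  }
  ax <- locate_hex(grid, cells$x_px, cells$y_px)
  key <- paste(ax$q, ax$r)
  is_tumor <- cells$marker == "tumor_ki67"
  is_cd8 <- cells$marker == "cd8"
  n_tumor <- tapply(as.integer(is_tumor), key, sum)
  n_pos <- tapply(as.integer(is_tumor & cells$positive == 1), key, sum)
  n_cd8 <- tapply(as.integer(is_cd8), key, sum)
  keys <- names(n_tumor)
  qr <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  data.frame(q = as.integer(qr[, 1]), r = as.integer(qr[, 2]),
             n_tumor = as.integer(n_tumor),
             n_tumor_pos = as.integer(n_pos),
             n_cd8 = as.integer(n_cd8))
}

#' Per-hexagon tissue-class area fractions
#'
#' Fractions are computed by rasterized pixel membership: every pixel centre
#' of the label map is assigned to its hexagon and tabulated by class. The
#' analyzed-tissue area of a hexagon is its tumor + stroma pixel count
#' converted to mm^2; for hexagons fully inside the raster this equals
#' (tumor + stroma fraction) x full hexagon area.
#'
#' @param tissue a [tissue_map()] (integer matrix, 0 = background,
#'   1 = stroma, 2 = tumor, with a `resolution_um_px` attribute).
#' @param grid a [make_grid()] result whose bounds match the raster.
#' @return data.frame with `q`, `r`, `center_x_px`, `center_y_px`,
#'   `frac_tumor`, `frac_stroma`, `frac_background`, `n_px`,
#'   `tissue_area_mm2`. Only hexagons overlapping the raster appear.
#' @export
tissue_fractions <- function(tissue, grid) {
  res <- attr(tissue, "resolution_um_px")
  if (is.null(res)) stop("tissue map lacks a resolution_um_px attribute")
  nr <- nrow(tissue); nc <- ncol(tissue)
  s <- grid$config$side_px
  px_area_mm2 <- (res^2) / 1e6

  # integer keyspace over the enumerated axial range (covers the raster)
  qlo <- min(grid$hexes$q) - 1L; qhi <- max(grid$hexes$q) + 1L
  rlo <- min(grid$hexes$r) - 1L; rhi <- max(grid$hexes$r) + 1L
  nq <- qhi - qlo + 1L
  nkey <- nq * (rhi - rlo + 1L)
  counts <- matrix(0L, nrow = nkey, ncol = 3L)  # bg / stroma / tumor

  # accumulate per-(hex, class) pixel counts in row chunks to bound memory
  chunk <- max(1L, floor(4e6 / nc))
  for (start in seq.int(1L, nr, by = chunk)) {
    rows <- start:min(nr, start + chunk - 1L)
    # pixel centre of matrix element [i, j] is (x, y) = (j - 0.5, i - 0.5)
    xs <- rep(seq_len(nc) - 0.5, each = length(rows))
    ys <- rep(rows - 0.5, times = nc)
    ax <- locate_hex(grid, xs, ys)
    lab <- as.integer(tissue[rows, , drop = FALSE])
    key <- (ax$r - rlo) * nq + (ax$q - qlo) + 1L
    for (cl in 0:2) {
      t1 <- tabulate(key[lab == cl], nbins = nkey)
      counts[, cl + 1L] <- counts[, cl + 1L] + t1
    }
  }
  n_all <- rowSums(counts)
  hit <- which(n_all > 0L)
  n_bg <- counts[hit, 1L]; n_st <- counts[hit, 2L]; n_tu <- counts[hit, 3L]
  n_all <- n_all[hit]
  qq <- as.integer((hit - 1L) %% nq) + qlo
  rr <- as.integer((hit - 1L) %/% nq) + rlo
  ctr <- axial_to_xy(qq, rr, s, grid$origin)
  out <- data.frame(
    q = qq, r = rr, center_x_px = ctr$x, center_y_px = ctr$y,
    frac_tumor = n_tu / n_all, frac_stroma = n_st / n_all,
    frac_background = n_bg / n_all, n_px = n_all,
    tissue_area_mm2 = (n_tu + n_st) * px_area_mm2)
  out[order(out$r, out$q), , drop = FALSE]
}

#' Merge cell counts and tissue fractions into hexagon aggregates
#'
#' @param fractions output of [tissue_fractions()].
#' @param counts output of [assign_cells()] (may cover a subset of hexagons).
#' @return data.frame with one row per hexagon of `fractions`, zero counts
#'   where no cells fell.
#' @export
hex_aggregate <- function(fractions, counts) {
  key_f <- paste(fractions$q, fractions$r)
  key_c <- paste(counts$q, counts$r)
  m <- match(key_f, key_c)
  out <- fractions
  out$n_tumor <- ifelse(is.na(m), 0L, counts$n_tumor[m])
  out$n_tumor_pos <- ifelse(is.na(m), 0L, counts$n_tumor_pos[m])
  out$n_cd8 <- ifelse(is.na(m), 0L, counts$n_cd8[m])
  out
}
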