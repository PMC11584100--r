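#' Export per-hexagon aggregates as CSV
#'
#' Schema: `q,r,center_x_px,center_y_px,n_cells,n_pos,frac_tumor,
#' frac_stroma,frac_background,tissue_area_mm2`, where `n_cells`/`n_pos`
#' are the tumor-cell totals from the Ki67 arm (CD8 counts are exported via
#' [write_interface_zone()]).
#'
#' @param agg data.frame from [hex_aggregate()].
#' @param path CSV path.
#' @export
write_hex_aggregates <- function(agg, path) {
  out <- data.frame(q = agg$q, r = agg$r,
                    center_x_px = agg$center_x_px,
                    center_y_px = agg$center_y_px,
                    n_cells = agg$n_tumor, n_pos = agg$n_tumor_pos,
                    frac_tumor = agg$frac_tumor,
                    frac_stroma = agg$frac_stroma,
                    frac_background = agg$frac_background,
                    tissue_area_mm2 = agg$tissue_area_mm2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an interface zone as CSV
#'
#' Schema: `q,r,rank,cd8_count,tissue_area_mm2,density`.
#' @param iz an [extract_interface_zone()] result.
#' @param path CSV path.
#' @export
write_interface_zone <- function(iz, path) {
  utils::write.csv(
    iz[, c("q", "r", "rank", "cd8_count", "tissue_area_mm2", "density")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rasterize interface-zone ranks for visual QC
#'
#' Produces an integer raster over the tissue-map canvas where each pixel
#' carries its hexagon's interface rank shifted to be nonnegative
#' (rank + half_width + 1), with 0 marking pixels outside the zone —
#' mirroring the usual rank-colour overlay of the interface zone.
#'
#' @param tissue a [tissue_map()] (defines the canvas).
#' @param grid the CD8 [make_grid()] used for the interface zone.
#' @param iz an [extract_interface_zone()] result.
#' @return integer matrix of the same dimension as `tissue`.
#' @export
rank_overlay <- function(tissue, grid, iz) {
  cfg <- attr(iz, "config")
  nr <- nrow(tissue); nc <- ncol(tissue)
  out <- matrix(0L, nr, nc)
  key_iz <- paste(iz$q, iz$r)
  chunk <- max(1L, floor(4e6 / nc))
  for (start in seq.int(1L, nr, by = chunk)) {
    rows <- start:min(nr, start + chunk - 1L)
    xs <- rep(seq_len(nc) - 0.5, each = length(rows))
    ys <- rep(rows - 0.5, times = nc)
    ax <- locate_hex(grid, xs, ys)
    m <- match(paste(ax$q, ax$r), key_iz)
    v <- ifelse(is.na(m), 0L, iz$rank[m] + cfg$half_width + 1L)
    out[rows, ] <- matrix(v, nrow = length(rows))
  }
  out
}
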