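#' Tissue scenario: geometry of a synthetic slide
#'
#' Describes a label map over {background, stroma, tumor} emulating pixelwise
#' tumor-versus-stroma segmentation of a stained section at a stated
#' resolution (default 0.5 um/pixel, i.e. 20x scans).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param resolution_um_px micrometres per pixel.
#' @param geometry one of:
#'   * `list(type = "half_plane", boundary_x_px =)` — tumor where
#'     x >= boundary, stroma elsewhere;
#'   * `list(type = "disk", center_px = c(x, y), radius_px =)` — tumor disk
#'     in a stroma field;
#'   * `list(type = "blobs", centers_px = 2-col matrix, radii_px =)` —
#'     union of tumor disks (disjoint nests allowed);
#'   * `list(type = "uniform", class = "tumor"|"stroma")` — degenerate
#'     single-class canvas for edge-case tests.
#' @param margin_px width of a background frame around the canvas border
#'   (0 = none).
#' @return an object of class `tissue_scenario`.
#' @export
tissue_scenario <- function(width_px, height_px, geometry,
                            resolution_um_px = 0.5, margin_px = 0) {
  stopifnot(width_px >= 1, height_px >= 1, resolution_um_px > 0, margin_px >= 0)
  if (is.null(geometry$type)) stop("geometry must have a `type` field")
  if (geometry$type == "disk") {
    c0 <- geometry$center_px; r0 <- geometry$radius_px
    if (c0[1] - r0 < 0 || c0[1] + r0 > width_px ||
        c0[2] - r0 < 0 || c0[2] + r0 > height_px)
      stop("disk geometry exceeds the canvas")
  }
  if (geometry$type == "blobs") {
    if (nrow(geometry$centers_px) != length(geometry$radii_px))
      stop("blobs: one radius per center required")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 geometry = geometry, resolution_um_px = resolution_um_px,
                 margin_px = margin_px),
            class = "tissue_scenario")
}

#' Generate a tissue label map from a scenario
#'
#' Deterministic: the geometry is analytic, so the raster depends only on the
#' scenario. Labels: 0 = background, 1 = stroma, 2 = tumor. The raster is an
#' integer matrix with rows indexing y and columns indexing x; element
#' `[i, j]` is the pixel whose centre is at (j - 0.5, i - 0.5).
#'
#' @param scenario a [tissue_scenario()].
#' @return integer matrix of class `tissue_map` with attribute
#'   `resolution_um_px`.
#' @export
generate_tissue_map <- function(scenario) {
  w <- scenario$width_px; h <- scenario$height_px
  g <- scenario$geometry
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  lab <- matrix(1L, nrow = h, ncol = w)  # stroma default
  if (g$type == "half_plane") {
    lab[xs >= g$boundary_x_px] <- 2L
  } else if (g$type == "disk") {
    d2 <- (xs - g$center_px[1])^2 + (ys - g$center_px[2])^2
    lab[d2 <= g$radius_px^2] <- 2L
  } else if (g$type == "blobs") {
    for (k in seq_along(g$radii_px)) {
      d2 <- (xs - g$centers_px[k, 1])^2 + (ys - g$centers_px[k, 2])^2
      lab[d2 <= g$radii_px[k]^2] <- 2L
    }
  } else if (g$type == "uniform") {
    lab[] <- if (g$class == "tumor") 2L else 1L
  } else stop("unknown geometry type: ", g$type)
  m <- scenario$margin_px
  if (m > 0) {
    lab[c(seq_len(m), h - seq_len(m) + 1L), ] <- 0L
    lab[, c(seq_len(m), w - seq_len(m) + 1L)] <- 0L
  }
  structure(lab, class = c("tissue_map", "matrix"),
            resolution_um_px = scenario$resolution_um_px)
}

#' Construct a tissue map from a raw label matrix
#' @param labels integer matrix over {0, 1, 2}.
#' @param resolution_um_px micrometres per pixel.
#' @return a `tissue_map`.
#' @export
tissue_map <- function(labels, resolution_um_px = 0.5) {
  stopifnot(all(labels %in% 0:2))
  structure(matrix(as.integer(labels), nrow = nrow(labels)),
            class = c("tissue_map", "matrix"),
            resolution_um_px = resolution_um_px)
}

#' Tumor area of a tissue map in mm^2
#' @param tissue a `tissue_map`.
#' @return tumor pixel count times pixel area, in mm^2.
#' @export
tumor_area_mm2 <- function(tissue) {
  res <- attr(tissue, "resolution_um_px")
  sum(tissue == 2L) * res^2 / 1e6
}

#' Write / read a tissue map as a PNG label image plus JSON sidecar
#'
#' Grayscale PNG with levels 0 (background), 1 (stroma), 2 (tumor) stored as
#' intensities k/255; the sidecar records the resolution.
#'
#' @param tissue a `tissue_map`.
#' @param path PNG path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(tissue, path) {
  png::writePNG(unclass(tissue) / 255, target = path)
  jsonlite::write_json(
    list(resolution_um_px = attr(tissue, "resolution_um_px"),
         labels = list(background = 0, stroma = 1, tumor = 2)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tissue_map
#' @export
read_tissue_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tissue_map(round(img * 255), resolution_um_px = meta$resolution_um_px)
}
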