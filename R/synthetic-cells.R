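#' Cell scenario: point-process parameters for a synthetic slide
#'
#' Cells are drawn as Poisson point processes on the tissue label map,
#' standing in for digital cell detection. Tumor cells are homogeneous on
#' the tumor region, with Ki67 positivity assigned by a spatial patch mosaic
#' (0 patchiness = spatially uniform Bernoulli positivity). CD8+ cells are
#' inhomogeneous: intensity `lambda_s` in stroma and
#' `lambda_s / kappa * exp(-depth / decay)` inside tumor, where depth is the
#' Euclidean distance (um) to the tumor boundary — so `kappa >= 1` is the
#' stroma-to-tumor density ratio at the boundary and `decay` sets how fast
#' infiltration fades toward the tumor core.
#'
#' @param tumor_cell_density_mm2 tumor cells per mm^2 of tumor tissue.
#' @param ki67_base positivity fraction in [0, 1].
#' @param ki67_patch_um Ki67 patch diameter in um (mosaic cell scale).
#' @param ki67_patch_spread half-width of the uniform per-patch positivity
#'   perturbation; 0 means spatially uniform positivity.
#' @param cd8_lambda_s_mm2 CD8+ intensity in stroma (cells/mm^2).
#' @param cd8_kappa stromal-to-tumor intensity ratio at the boundary (>= 1).
#' @param cd8_decay_um intratumoral exponential decay length (um); large
#'   values give a flat intratumoral profile at `lambda_s / kappa`.
#' @param seed integer seed; generation is a pure function of
#'   (tissue, scenario, seed).
#' @return an object of class `cell_scenario`.
#' @export
cell_scenario <- function(tumor_cell_density_mm2 = 2000,
                          ki67_base = 0.3,
                          ki67_patch_um = 400,
                          ki67_patch_spread = 0,
                          cd8_lambda_s_mm2 = 500,
                          cd8_kappa = 1,
                          cd8_decay_um = 2000,
                          seed = 1L) {
  vals <- c(tumor_cell_density_mm2, cd8_lambda_s_mm2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("cell intensities must be finite and >= 0")
  if (cd8_kappa < 1) stop("`cd8_kappa` must be >= 1")
  if (ki67_base < 0 || ki67_base > 1) stop("`ki67_base` must lie in [0, 1]")
  if (ki67_patch_spread < 0) stop("`ki67_patch_spread` must be >= 0")
  structure(list(tumor_cell_density_mm2 = tumor_cell_density_mm2,
                 ki67_base = ki67_base, ki67_patch_um = ki67_patch_um,
                 ki67_patch_spread = ki67_patch_spread,
                 cd8_lambda_s_mm2 = cd8_lambda_s_mm2,
                 cd8_kappa = cd8_kappa, cd8_decay_um = cd8_decay_um,
                 seed = as.integer(seed)),
            class = "cell_scenario")
}

# Sample n points uniformly over the pixels whose linear indices are `idx`
# (optionally with per-pixel weights), jittered within each pixel.
sample_pixel_points <- function(tissue, idx, n, weights = NULL) {
  if (n == 0L || length(idx) == 0L)
    return(data.frame(x_px = numeric(), y_px = numeric()))
  pick <- if (is.null(weights)) sample.int(length(idx), n, replace = TRUE)
  else sample.int(length(idx), n, replace = TRUE, prob = weights)
  lin <- idx[pick]
  h <- nrow(tissue)
  i <- ((lin - 1L) %% h) + 1L        # row -> y
  j <- ((lin - 1L) %/% h) + 1L      # col -> x
  data.frame(x_px = j - stats::runif(n), y_px = i - stats::runif(n))
}

#' Generate a per-slide cell table from a tissue map and a cell scenario
#'
#' @param tissue a [tissue_map()].
#' @param scenario a [cell_scenario()].
#' @return data.frame with columns `cell_id`, `x_px`, `y_px`, `marker`
#'   (`"tumor_ki67"` / `"cd8"`), `positive` (0/1). CD8 rows are all
#'   positive = 1 (only marker-positive lymphocytes are modelled).
#' @export
generate_cells <- function(tissue, scenario) {
  stopifnot(inherits(scenario, "cell_scenario"))
  if (length(tissue) == 0L)
    return(data.frame(cell_id = integer(), x_px = numeric(), y_px = numeric(),
                      marker = character(), positive = integer()))
  res <- attr(tissue, "resolution_um_px")
  px_mm2 <- res^2 / 1e6

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(scenario$seed)

  tumor_idx <- which(tissue == 2L)
  stroma_idx <- which(tissue == 1L)

  # --- tumor cells: homogeneous Poisson on the tumor region
  n_tum <- stats::rpois(1, scenario$tumor_cell_density_mm2 *
                          length(tumor_idx) * px_mm2)
  tum <- sample_pixel_points(tissue, tumor_idx, n_tum)

  # Ki67 positivity via patch mosaic: patch seeds are a Poisson process with
  # about one seed per patch-diameter-sized disk; each patch perturbs the
  # base positivity by Uniform(-spread, +spread), clamped to [0, 1]; cells
  # take the probability of their nearest patch seed.
  p_cell <- rep(scenario$ki67_base, n_tum)
  if (scenario$ki67_patch_spread > 0 && n_tum > 0) {
    patch_area_mm2 <- pi * (scenario$ki67_patch_um / 2 / 1000)^2
    area_mm2 <- length(tumor_idx) * px_mm2
    k <- max(1L, stats::rpois(1, area_mm2 / patch_area_mm2))
    seeds <- sample_pixel_points(tissue, tumor_idx, k)
    p_patch <- pmin(1, pmax(0, scenario$ki67_base +
      stats::runif(k, -scenario$ki67_patch_spread, scenario$ki67_patch_spread)))
    # nearest seed per cell, chunked to bound the distance matrix
    chunk <- max(1L, floor(4e6 / k))
    nearest <- integer(n_tum)
    for (start in seq.int(1L, n_tum, by = chunk)) {
      ii <- start:min(n_tum, start + chunk - 1L)
      d2 <- outer(tum$x_px[ii], seeds$x_px, "-")^2 +
        outer(tum$y_px[ii], seeds$y_px, "-")^2
      nearest[ii] <- max.col(-d2, ties.method = "first")
    }
    p_cell <- p_patch[nearest]
  }
  tum_pos <- if (n_tum > 0) stats::rbinom(n_tum, 1L, p_cell) else integer()

  # --- CD8 cells: homogeneous lambda_s in stroma
  n_cd8_s <- stats::rpois(1, scenario$cd8_lambda_s_mm2 *
                            length(stroma_idx) * px_mm2)
  cd8_s <- sample_pixel_points(tissue, stroma_idx, n_cd8_s)

  # --- CD8 cells in tumor: inhomogeneous, lambda_s/kappa * exp(-depth/decay)
  cd8_t <- data.frame(x_px = numeric(), y_px = numeric())
  if (length(tumor_idx) > 0 && scenario$cd8_lambda_s_mm2 > 0) {
    depth_um <- tumor_depth_um(tissue)[tumor_idx]
    lam <- scenario$cd8_lambda_s_mm2 / scenario$cd8_kappa *
      exp(-depth_um / scenario$cd8_decay_um)
    n_cd8_t <- stats::rpois(1, sum(lam) * px_mm2)
    cd8_t <- sample_pixel_points(tissue, tumor_idx, n_cd8_t, weights = lam)
  }

  out <- rbind(
    if (n_tum > 0) data.frame(x_px = tum$x_px, y_px = tum$y_px,
                              marker = "tumor_ki67", positive = tum_pos)
    else NULL,
    if (nrow(cd8_s) > 0) data.frame(x_px = cd8_s$x_px, y_px = cd8_s$y_px,
                                    marker = "cd8", positive = 1L) else NULL,
    if (nrow(cd8_t) > 0) data.frame(x_px = cd8_t$x_px, y_px = cd8_t$y_px,
                                    marker = "cd8", positive = 1L) else NULL)
  if (is.null(out))
    out <- data.frame(x_px = numeric(), y_px = numeric(),
                      marker = character(), positive = integer())
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Euclidean distance (um) from each tumor pixel to the tumor boundary
#'
#' Distance-transform of the tumor mask: zero outside tumor, and inside the
#' tumor the distance to the nearest non-tumor pixel.
#'
#' @param tissue a `tissue_map`.
#' @return numeric matrix of depths in micrometres.
#' @export
tumor_depth_um <- function(tissue) {
  res <- attr(tissue, "resolution_um_px")
  mask <- unclass(tissue) == 2L
  if (!any(mask)) return(matrix(0, nrow(tissue), ncol(tissue)))
  if (all(mask)) {
    # no boundary inside the canvas; treat the canvas border as the boundary
    d <- EBImage::distmap(EBImage::Image(mask * 1))
    return(as.matrix(EBImage::imageData(d)) * res)
  }
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  as.matrix(EBImage::imageData(d)) * res
}

#' Write / read a cell table CSV
#'
#' Schema: `cell_id,x_px,y_px,marker,positive` with marker in
#' {tumor_ki67, cd8} and positive in {0, 1}.
#' @param cells a cell table.
#' @param path CSV path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells[, c("cell_id", "x_px", "y_px", "marker", "positive")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_px", "y_px", "marker", "positive")
  if (!all(need %in% names(df)))
    stop("cell table must have columns ", paste(need, collapse = ","))
  df
}
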