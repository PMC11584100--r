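#' Analysis configuration for the full per-slide / per-cohort pipeline
#'
#' Defaults follow the 0.5 um/pixel (20x) imaging setting: Ki67 grid
#' hexagons of side 262.5 um (525 px), CD8 grid hexagons of side 65 um
#' (130 px), a 50-cell minimum per Ki67 hexagon, interface-zone half-width 4
#' (nine rank classes) and a 6 mm^2 minimum tumor content for slide QC.
#'
#' @param resolution_um_px micrometres per pixel.
#' @param ki67_side_px,cd8_side_px hexagon side lengths in pixels.
#' @param min_cells minimum tumor cells per Ki67 hexagon.
#' @param tau edge-detection threshold.
#' @param half_width interface-zone half-width in ranks.
#' @param min_tumor_mm2 QC threshold on slide tumor content.
#' @param grid_seed seed for the random grid origin offsets.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(resolution_um_px = 0.5,
                            ki67_side_px = 525, cd8_side_px = 130,
                            min_cells = 50L, tau = 0.5, half_width = 4L,
                            min_tumor_mm2 = 6, grid_seed = 1L) {
  stopifnot(resolution_um_px > 0, ki67_side_px > 0, cd8_side_px > 0,
            min_tumor_mm2 > 0)
  structure(list(resolution_um_px = resolution_um_px,
                 ki67_side_px = ki67_side_px, cd8_side_px = cd8_side_px,
                 min_cells = as.integer(min_cells), tau = tau,
                 half_width = as.integer(half_width),
                 min_tumor_mm2 = min_tumor_mm2,
                 grid_seed = as.integer(grid_seed)),
            class = "analysis_config")
}

#' Slide quality control on tumor content
#'
#' Slides with less than `min_tumor_mm2` of tumor tissue (default 6 mm^2)
#' fail QC and are excluded from indicator computation.
#'
#' @param tissue a [tissue_map()].
#' @param config an [analysis_config()].
#' @return list `pass` (logical), `tumor_area_mm2`, `threshold_mm2`.
#' @export
qc_slide <- function(tissue, config = analysis_config()) {
  if (is.null(attr(tissue, "resolution_um_px")))
    stop("tissue map lacks a resolution")
  area <- tumor_area_mm2(tissue)
  list(pass = area >= config$min_tumor_mm2, tumor_area_mm2 = area,
       threshold_mm2 = config$min_tumor_mm2)
}

#' Compute all slide-level indicators (Ki67 heterogeneity + CD8 gradient)
#'
#' Runs the full per-slide pipeline: randomized Ki67 grid + cell assignment
#' + minimum-cell filter + ranking + co-occurrence entropy, then the CD8
#' grid + tissue fractions + edge detection + signed ranks + interface-zone
#' indicators.
#'
#' @param cells cell table covering both markers (columns `x_px`, `y_px`,
#'   `marker`, `positive`).
#' @param tissue a [tissue_map()].
#' @param config an [analysis_config()].
#' @param run_qc refuse slides failing tumor-content QC (default TRUE).
#' @param arms which indicator families to compute (default both).
#' @return list of class `slide_result`: `ki67` (one-row data.frame),
#'   `cd8` (one-row data.frame), `iz` (interface zone), `qc`, `config`.
#' @export
run_slide <- function(cells, tissue, config = analysis_config(),
                      run_qc = TRUE, arms = c("ki67", "cd8")) {
  qc <- qc_slide(tissue, config)
  if (run_qc && !qc$pass)
    stop(sprintf("slide failed QC: tumor content %.2f mm^2 < %.2f mm^2",
                 qc$tumor_area_mm2, qc$threshold_mm2))
  w <- ncol(tissue); h <- nrow(tissue)
  ki67 <- cd8 <- iz <- NULL

  if ("ki67" %in% arms) {
    # Ki67 arm: large-hexagon grid over tumor cells
    grid_k <- make_grid(w, h, hex_config(config$ki67_side_px,
                                         config$resolution_um_px,
                                         seed = config$grid_seed))
    counts_k <- assign_cells(cells, grid_k)
    ki67 <- ki67_heterogeneity(counts_k, min_cells = config$min_cells)
  }

  if ("cd8" %in% arms) {
    # CD8 arm: small-hexagon grid, tissue fractions, interface zone
    grid_c <- make_grid(w, h, hex_config(config$cd8_side_px,
                                         config$resolution_um_px,
                                         seed = config$grid_seed + 1L))
    frac <- tissue_fractions(tissue, grid_c)
    counts_c <- assign_cells(cells[cells$marker == "cd8", , drop = FALSE],
                             grid_c)
    agg <- hex_aggregate(frac, counts_c)
    ecfg <- edge_config(tau = config$tau, half_width = config$half_width)
    edge <- detect_tumor_edge(agg, ecfg)
    rank <- assign_ranks(agg, edge, ecfg)
    iz <- extract_interface_zone(agg, rank, ecfg)
    cd8 <- immunogradient_indicators(iz)
  }

  structure(list(ki67 = ki67, cd8 = cd8, iz = iz, qc = qc, config = config),
            class = "slide_result")
}

#' @export
print.slide_result <- function(x, ...) {
  cat("slide_result\n")
  cat(sprintf("  tumor content: %.2f mm^2 (QC %s)\n", x$qc$tumor_area_mm2,
              if (x$qc$pass) "pass" else "fail"))
  if (!is.null(x$ki67))
    cat(sprintf("  Ki67: entropy %.3f over %d hexagons (global %.1f%%)\n",
                x$ki67$ki67_entropy, x$ki67$n_hexagons_included,
                x$ki67$ki67_pct_global))
  if (!is.null(x$cd8))
    cat(sprintf("  CD8: m_S %.0f, m_TE %.0f, m_T %.0f cells/mm^2, ID %.2f, CM %.2f\n",
                x$cd8$CD8_m_S, x$cd8$CD8_m_TE, x$cd8$CD8_m_T,
                x$cd8$CD8_ID, x$cd8$CD8_CM))
  invisible(x)
}

#' Cohort-level modeling: screen, multivariable Cox, CPBS
#'
#' Joins slide indicators to clinical data on `id`, screens the given
#' variables univariately by optimal-cutoff log-rank test, fits a
#' multivariable Cox model on the retained variables (continuous form), and
#' assigns combined prognostic scores when a CPBS specification is given.
#'
#' @param cohort data.frame with `id`, `time_months`, `event`, covariates
#'   and indicator columns (e.g. the output of [generate_cohort()], or a
#'   clinical table merged with [run_slide()] indicators).
#' @param variables character vector of variables to screen.
#' @param cpbs optional list `(model =, indicators =, directions =)`:
#'   `indicators` are column names (4 for ER+HER2-, 3 for TNBC) and
#'   `directions` is `+1`/`-1` per indicator (`+1` = values above the cutoff
#'   are poor prognosis). Cutoffs come from the screen results.
#' @param alpha univariate retention threshold.
#' @return list of class `cohort_result`: `screen`, `cox`, `cpbs`
#'   (per-patient data.frame or NULL), `n`, `n_events`.
#' @export
run_cohort <- function(cohort, variables, cpbs = NULL, alpha = 0.05) {
  if (anyDuplicated(cohort$id)) stop("duplicated patient ids")
  if (nrow(cohort) < 2) stop("cohort too small for modeling")
  scr <- univariate_screen(cohort, variables, alpha = alpha)
  cox <- if (length(scr$retained) >= 1 &&
             sum(cohort$event) >= length(scr$retained) + 5) {
    fit_multivariable_cox(cohort, scr$retained)
  } else NULL

  cpbs_out <- NULL
  if (!is.null(cpbs)) {
    sc <- sapply(seq_along(cpbs$indicators), function(k) {
      v <- cpbs$indicators[k]
      cut <- scr$results[[v]]$cutoff
      if (is.null(cut)) stop("no cutoff available for CPBS indicator ", v)
      high <- as.integer(cohort[[v]] > cut)
      if (cpbs$directions[k] > 0) high else 1L - high
    })
    cpbs_out <- cbind(id = cohort$id,
                      cpbs_score(matrix(sc, nrow = nrow(cohort)),
                                 model = cpbs$model))
  }
  structure(list(screen = scr, cox = cox, cpbs = cpbs_out,
                 n = nrow(cohort), n_events = sum(cohort$event)),
            class = "cohort_result")
}

#' Serialize a cohort result to a JSON report
#'
#' @param result a [run_cohort()] result.
#' @param path output path.
#' @param config optional [analysis_config()] echoed into the report.
#' @export
write_cohort_report <- function(result, path, config = NULL) {
  screen_tab <- lapply(result$screen$results, function(r)
    r[c("cutoff", "chisq", "p", "hr", "ci_lower", "ci_upper",
        "n_low", "n_high")])
  rep <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("hexiz")),
    config = if (!is.null(config)) unclass(config),
    n = result$n, n_events = result$n_events,
    univariate = screen_tab, retained = result$screen$retained,
    cox = if (!is.null(result$cox))
      list(table = result$cox$table, lr_stat = result$cox$lr_stat,
           lr_p = result$cox$lr_p, c_index = result$cox$c_index),
    cpbs = if (!is.null(result$cpbs))
      as.list(table(result$cpbs$risk_group)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
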