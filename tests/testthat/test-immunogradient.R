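# Shared fixture: CD8 grid aggregates of a half-plane slide (tumor right).
halfplane_agg <- local({
  slide <- make_halfplane_slide(kappa = 2, seed = 4)
  grid <- make_grid(ncol(slide$tissue), nrow(slide$tissue),
                    hex_config(130, seed = 5))
  frac <- tissue_fractions(slide$tissue, grid)
  counts <- assign_cells(slide$cells, grid)
  list(agg = hex_aggregate(frac, counts), grid = grid,
       boundary_x = ncol(slide$tissue) / 2, tissue = slide$tissue)
})

test_that("edge detection: half-plane band, degenerate maps, disk perimeter", {
  agg <- halfplane_agg$agg
  edge <- detect_tumor_edge(agg)
  expect_gt(sum(edge), 0)
  # the edge band lies within about one hexagon pitch of the true boundary
  pitch <- sqrt(3) * 130
  expect_true(all(abs(agg$center_x_px[edge] - halfplane_agg$boundary_x)
                  <= 1.5 * pitch))
  # and the band is laterally continuous: every interior y is represented
  ys <- sort(agg$center_y_px[edge])
  expect_lt(max(diff(ys)), 2 * 130 * 1.5)

  # uniform all-tumor map -> no interface
  tm_t <- generate_tissue_map(
    tissue_scenario(800, 800, list(type = "uniform", class = "tumor")))
  g <- make_grid(800, 800, hex_config(80, seed = 1))
  fr <- tissue_fractions(tm_t, g)
  fr$n_cd8 <- 0L
  expect_error(detect_tumor_edge(fr), "no interface")

  # tumor disk: edge hexagon count ~ perimeter / pitch (+-30%)
  R <- 800
  tm_d <- generate_tissue_map(
    tissue_scenario(2200, 2200, list(type = "disk", center_px = c(1100, 1100),
                                     radius_px = R)))
  gd <- make_grid(2200, 2200, hex_config(130, seed = 2))
  frd <- tissue_fractions(tm_d, gd)
  edge_d <- detect_tumor_edge(frd)
  expected <- 2 * pi * R / (sqrt(3) * 130)
  expect_gt(sum(edge_d), 0.7 * expected)
  expect_lt(sum(edge_d), 1.3 * expected)
})

test_that("tumor-background transitions are not classified as tumor edge", {
  # tumor disk surrounded by background only: no tumor-stroma interface
  tm <- generate_tissue_map(
    tissue_scenario(1200, 1200, list(type = "disk", center_px = c(600, 600),
                                     radius_px = 400)))
  tm[tm == 1L] <- 0L  # replace all stroma with background
  tm <- tissue_map(tm, 0.5)
  g <- make_grid(1200, 1200, hex_config(130, seed = 3))
  fr <- tissue_fractions(tm, g)
  expect_error(detect_tumor_edge(fr), "no interface")
})

test_that("signed ranks: edge zero, adjacency, BFS oracle, sign convention", {
  agg <- halfplane_agg$agg
  edge <- detect_tumor_edge(agg)
  rank <- assign_ranks(agg, edge)
  expect_true(all(rank[edge] == 0L))

  # |rank| equals BFS distance from the edge set over included hexagons
  include <- agg$frac_background <= 0.5
  d <- oracle_bfs_distance(agg$q, agg$r, which(edge), include)
  expect_identical(abs(rank), d)

  # sign follows the dominant tissue class
  tumor_dom <- !edge & include & agg$frac_tumor >= agg$frac_stroma
  stroma_dom <- !edge & include & agg$frac_tumor < agg$frac_stroma
  expect_true(all(rank[tumor_dom] > 0, na.rm = TRUE))
  expect_true(all(rank[stroma_dom] < 0, na.rm = TRUE))

  # a tumor-dominant hexagon adjacent to an edge hexagon gets rank +1
  nb_of_edge <- include & !edge & vapply(seq_len(nrow(agg)), function(i) {
    any(hex_distance(agg$q[i], agg$r[i], agg$q[edge], agg$r[edge]) == 1L)
  }, logical(1))
  expect_true(all(abs(rank[nb_of_edge]) == 1L, na.rm = TRUE))
  expect_true(any(rank[nb_of_edge & tumor_dom] == 1L))

  expect_error(assign_ranks(agg, rep(FALSE, nrow(agg))), "empty edge set")
})

test_that("interface zone extraction: nine classes, clipping, half-width", {
  agg <- halfplane_agg$agg
  edge <- detect_tumor_edge(agg)
  rank <- assign_ranks(agg, edge)
  iz <- extract_interface_zone(agg, rank)
  expect_setequal(unique(iz$rank), -4:4)      # nine rank classes
  expect_true(all(abs(iz$rank) <= 4))

  iz1 <- extract_interface_zone(agg, rank, edge_config(half_width = 1L))
  expect_setequal(unique(iz1$rank), -1:1)     # three classes

  # a zone missing some rank class warns but proceeds
  sub <- agg[rank %in% c(-1, 0, 1) | is.na(rank), ]
  expect_warning(
    extract_interface_zone(sub, rank[rank %in% c(-1, 0, 1) | is.na(rank)]),
    "absent")
})

test_that("cd8 density: closed-form hexagon area, zero counts, scaling", {
  area_65 <- 3 * sqrt(3) / 2 * 65^2 / 1e6
  expect_equal(11 / area_65, 1002, tolerance = 0.001)
  expect_equal(cd8_density(11, area_65), 11 / area_65)
  expect_equal(cd8_density(0, area_65), 0)
  expect_equal(cd8_density(7, area_65 / 2), 2 * cd8_density(7, area_65))
  expect_true(is.na(cd8_density(3, 0)))
})

test_that("aspect statistics: uniform and hand-computed profiles", {
  izu <- make_linear_iz(rep(250, 9))
  a <- aspect_statistics(izu)
  expect_equal(a$CD8_m_S, 250); expect_equal(a$CD8_sd_S, 0)
  expect_equal(a$CD8_m_TE, 250); expect_equal(a$CD8_sd_TE, 0)
  expect_equal(a$CD8_m_T, 250); expect_equal(a$CD8_sd_T, 0)

  # densities 1..9 over ranks -4..4: stroma mean 2.5, edge 5, tumor mean 7.5
  iz9 <- make_linear_iz(1:9)
  a9 <- aspect_statistics(iz9)
  expect_equal(a9$CD8_m_S, 2.5)
  expect_equal(a9$CD8_m_TE, 5)
  expect_equal(a9$CD8_m_T, 7.5)
  expect_equal(a9$CD8_sd_S, sd(1:4))
  expect_equal(a9$CD8_sd_TE, 0)
})

test_that("immunodrop: stated ratio, flat profile, degenerate flags", {
  # D(-1) = 400, D(+1) = 100 -> 4.0
  iz <- make_linear_iz(c(500, 450, 420, 400, 300, 100, 80, 60, 50))
  expect_equal(immunodrop(iz), 4)
  # flat profile -> 1
  expect_equal(immunodrop(make_linear_iz(rep(123, 9))), 1)
  # zero denominator, positive numerator -> capped with flag
  izc <- make_linear_iz(c(1, 1, 1, 200, 1, 0, 0, 0, 0))
  expect_equal(as.numeric(immunodrop(izc)), 100)
  expect_equal(attr(immunodrop(izc), "flag"), "capped")
  # both zero -> 1 with flag
  iz0 <- make_linear_iz(c(1, 1, 1, 0, 1, 0, 1, 1, 1))
  expect_equal(as.numeric(immunodrop(iz0)), 1)
  expect_equal(attr(immunodrop(iz0), "flag"), "both_zero")
})

test_that("center of mass: symmetry, point mass, weighted arithmetic", {
  expect_equal(center_of_mass(make_linear_iz(c(1, 2, 3, 4, 9, 4, 3, 2, 1))), 0)
  expect_equal(center_of_mass(make_linear_iz(c(7, 0, 0, 0, 0, 0, 0, 0, 0))), -4)
  # Dbar(-1) = 300, Dbar(+1) = 100 -> CM = (-300 + 100) / 400 = -0.5
  expect_equal(center_of_mass(make_linear_iz(c(0, 0, 0, 300, 0, 100, 0, 0, 0))),
               -0.5)
  expect_true(is.na(center_of_mass(make_linear_iz(rep(0, 9)))))
})

test_that("stroma-skewed gradients give ID > 1 and CM < 0 end-to-end", {
  grid <- halfplane_agg$grid
  agg <- halfplane_agg$agg
  edge <- detect_tumor_edge(agg)
  rank <- assign_ranks(agg, edge)
  iz <- extract_interface_zone(agg, rank)
  ind <- immunogradient_indicators(iz)
  expect_named(ind, c("CD8_m_S", "CD8_sd_S", "CD8_m_TE", "CD8_sd_TE",
                      "CD8_m_T", "CD8_sd_T", "CD8_CM", "CD8_ID"))
  expect_gt(ind$CD8_ID, 1)          # kappa = 2 gradient
  expect_lt(ind$CD8_CM, 0)
  expect_gt(ind$CD8_m_S, ind$CD8_m_T)

  # rank overlay raster mirrors the zone (labels 1..9 inside, 0 outside)
  ov <- rank_overlay(halfplane_agg$tissue, grid, iz)
  expect_identical(dim(ov), dim(halfplane_agg$tissue))
  expect_setequal(sort(unique(as.integer(ov))), 0:9)
})

test_that("interface zone CSV export round-trips", {
  iz <- make_linear_iz(1:9)
  path <- tempfile(fileext = ".csv")
  write_interface_zone(iz, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("q", "r", "rank", "cd8_count", "tissue_area_mm2", "density"))
  expect_equal(back$density, iz$density)
  unlink(path)
})
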