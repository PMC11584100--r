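test_that("hexagon physical area matches the closed form", {
  cfg <- hex_config(side_px = 130, resolution_um_px = 0.5)
  expect_equal(hex_side_um(cfg), 65)
  expect_equal(hex_area_mm2(cfg), 3 * sqrt(3) / 2 * 65^2 / 1e6,
               tolerance = 1e-12)
  # the 65-um hexagon is about 0.01098 mm^2
  expect_equal(hex_area_mm2(cfg), 0.010977, tolerance = 1e-4)
})

test_that("grid construction: count, determinism, input validation", {
  cfg <- hex_config(side_px = 40, seed = 11L)
  g <- make_grid(1000, 800, cfg)
  # analytic count: bound area / hexagon area, within a boundary ring
  hex_area_px <- 3 * sqrt(3) / 2 * 40^2
  expected <- 1000 * 800 / hex_area_px
  ring <- 2 * (1000 / (sqrt(3) * 40) + 800 / (1.5 * 40)) + 8
  expect_gt(nrow(g$hexes), expected - ring)
  expect_lt(nrow(g$hexes), expected + ring)

  g2 <- make_grid(1000, 800, cfg)
  expect_identical(g$hexes, g2$hexes)
  g3 <- make_grid(1000, 800, hex_config(side_px = 40, seed = 12L))
  expect_false(isTRUE(all.equal(g$origin, g3$origin)))

  expect_error(hex_config(side_px = 0), "positive")
  expect_error(make_grid(0, 100, cfg), "nonempty")
})

test_that("each point maps to exactly one hexagon; centers round-trip", {
  cfg <- hex_config(side_px = 37, seed = 3L)
  g <- make_grid(600, 600, cfg)
  ax <- locate_hex(g, g$hexes$center_x_px, g$hexes$center_y_px)
  expect_identical(ax$q, g$hexes$q)
  expect_identical(ax$r, g$hexes$r)

  set.seed(42)
  x <- runif(5000, 0, 600); y <- runif(5000, 0, 600)
  ax <- locate_hex(g, x, y)
  # every point lands on an enumerated hexagon
  expect_true(all(paste(ax$q, ax$r) %in% paste(g$hexes$q, g$hexes$r)))
  # points very near a center belong to that center's hexagon
  i <- sample(nrow(g$hexes), 100)
  ax2 <- locate_hex(g, g$hexes$center_x_px[i] + 0.01,
                    g$hexes$center_y_px[i] - 0.01)
  expect_identical(ax2$q, g$hexes$q[i])
})

test_that("hexagonal distance equals BFS shortest paths on the lattice", {
  expect_identical(hex_distance(2L, -1L, 2L, -1L), 0L)
  offs <- cbind(c(1, -1, 0, 0, 1, -1), c(0, 0, 1, -1, -1, 1))
  expect_true(all(hex_distance(offs[,1], offs[,2], 0L, 0L) == 1L))

  # random pairs on a 9x9 axial block vs BFS oracle
  lat <- expand.grid(q = -4:4, r = -4:4)
  set.seed(7)
  for (src in sample(nrow(lat), 5)) {
    d_bfs <- oracle_bfs_distance(lat$q, lat$r, sources = src)
    d_ax <- hex_distance(lat$q, lat$r, lat$q[src], lat$r[src])
    expect_identical(d_ax, d_bfs)
  }
})

test_that("cell assignment conserves totals and rejects out-of-bounds", {
  cfg <- hex_config(side_px = 50, seed = 5L)
  g <- make_grid(700, 700, cfg)
  set.seed(1)
  n <- 4000
  cells <- data.frame(
    x_px = runif(n, 0, 700), y_px = runif(n, 0, 700),
    marker = sample(c("tumor_ki67", "cd8"), n, replace = TRUE),
    positive = rbinom(n, 1, 0.4))
  counts <- assign_cells(cells, g)
  expect_equal(sum(counts$n_tumor), sum(cells$marker == "tumor_ki67"))
  expect_equal(sum(counts$n_cd8), sum(cells$marker == "cd8"))
  expect_equal(sum(counts$n_tumor_pos),
               sum(cells$marker == "tumor_ki67" & cells$positive == 1))

  # constructive placement: cells exactly at three interior hexagon centers
  interior <- which(g$hexes$center_x_px > 100 & g$hexes$center_x_px < 600 &
                      g$hexes$center_y_px > 100 & g$hexes$center_y_px < 600)
  i <- interior[c(1, 5, 9)]
  at_centers <- data.frame(x_px = g$hexes$center_x_px[i],
                           y_px = g$hexes$center_y_px[i],
                           marker = "cd8", positive = 1L)
  cc <- assign_cells(at_centers, g)
  m <- match(paste(g$hexes$q[i], g$hexes$r[i]), paste(cc$q, cc$r))
  expect_true(all(cc$n_cd8[m] == 1L))

  expect_equal(nrow(assign_cells(cells[0, ], g)), 0)
  bad <- data.frame(x_px = -5, y_px = 10, marker = "cd8", positive = 1L)
  expect_error(assign_cells(bad, g), "outside")
})

test_that("tissue fractions: normalization, pure regions, straddling", {
  # all-tumor map: interior hexagons have fractions (1, 0, 0)
  tm <- generate_tissue_map(
    tissue_scenario(800, 800, list(type = "uniform", class = "tumor")))
  g <- make_grid(800, 800, hex_config(side_px = 60, seed = 2L))
  fr <- tissue_fractions(tm, g)
  expect_true(all(abs(fr$frac_tumor + fr$frac_stroma +
                        fr$frac_background - 1) < 1e-9))
  interior <- fr$center_x_px > 120 & fr$center_x_px < 680 &
    fr$center_y_px > 120 & fr$center_y_px < 680
  expect_true(all(fr$frac_tumor[interior] == 1))
  # pixel-count conservation across hexagons
  expect_equal(sum(fr$n_px), 800 * 800)
  # full interior hexagon area consistent with the closed form
  cfg <- g$config
  full_px <- 3 * sqrt(3) / 2 * 60^2
  expect_equal(mean(fr$n_px[interior]), full_px, tolerance = 0.01)

  # half-plane: straddling hexagons match the analytic tumor fraction of a
  # pointy-top hexagon cut by a vertical line (numeric integral oracle);
  # a hexagon centered exactly on the boundary would give 0.5
  tm2 <- generate_tissue_map(
    tissue_scenario(800, 800, list(type = "half_plane", boundary_x_px = 400)))
  fr2 <- tissue_fractions(tm2, g)
  s <- 60
  halfw <- sqrt(3) / 2 * s
  analytic_frac <- function(delta) {
    # tumor occupies x > delta in hexagon-centered coordinates;
    # height profile h(x) = 2 (s - |x| / sqrt(3)) for |x| <= sqrt(3)/2 s
    f <- function(x) 2 * (s - abs(x) / sqrt(3))
    stats::integrate(f, delta, halfw)$value / (3 * sqrt(3) / 2 * s^2)
  }
  straddle <- which(abs(fr2$center_x_px - 400) < 0.8 * halfw &
                      fr2$center_y_px > 120 & fr2$center_y_px < 680)
  expect_gt(length(straddle), 0)
  for (i in straddle) {
    expected <- analytic_frac(400 - fr2$center_x_px[i])
    expect_equal(fr2$frac_tumor[i], expected, tolerance = 0.02)
  }

  expect_error(tissue_fractions(matrix(0L, 10, 10), g), "resolution")
})

test_that("analyzed-tissue area excludes background", {
  tm <- generate_tissue_map(
    tissue_scenario(600, 600, list(type = "uniform", class = "stroma"),
                    margin_px = 100))
  g <- make_grid(600, 600, hex_config(side_px = 50, seed = 9L))
  fr <- tissue_fractions(tm, g)
  px_mm2 <- 0.25 / 1e6
  expect_equal(fr$tissue_area_mm2,
               (1 - fr$frac_background) * fr$n_px * px_mm2,
               tolerance = 1e-12)
  expect_true(all(fr$tissue_area_mm2 <=
                    fr$n_px * px_mm2 + 1e-12))
})
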