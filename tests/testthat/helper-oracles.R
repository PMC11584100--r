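# Independent brute-force oracles used across test files. These deliberately
# re-derive results by the most literal method available (exhaustive double
# loops, BFS over explicit adjacency lists) rather than calling back into
# the package's optimized paths.

# Brute-force co-occurrence: double loop over ALL hexagon pairs, keep those
# within `distance` hexagonal steps, symmetrize, normalize.
oracle_cooccurrence <- function(field, n_levels = 10L, distance = 1L) {
  n <- nrow(field)
  P <- matrix(0, n_levels, n_levels)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- hex_distance(field$q[i], field$r[i], field$q[j], field$r[j])
      if (d >= 1 && d <= distance) {
        a <- field$rank[i]; b <- field$rank[j]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}

# BFS shortest-path distances from a source set over an explicit 6-neighbour
# adjacency list (queue-based, one node at a time).
oracle_bfs_distance <- function(q, r, sources, include = rep(TRUE, length(q))) {
  n <- length(q)
  key <- paste(q, r)
  adj <- lapply(seq_len(n), function(i) {
    offs <- cbind(c(1, -1, 0, 0, 1, -1), c(0, 0, 1, -1, -1, 1))
    nb <- match(paste(q[i] + offs[, 1], r[i] + offs[, 2]), key)
    nb[!is.na(nb)]
  })
  dist <- rep(NA_integer_, n)
  queue <- sources[include[sources]]
  dist[queue] <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (include[w] && is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Exhaustive optimal-cutoff scan, written independently: every midpoint of
# consecutive sorted distinct values, groups checked against the minimum
# fraction, log-rank p via survdiff for each.
oracle_cutoff <- function(values, times, events, min_group_fraction = 0.1) {
  sv <- sort(unique(values))
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  n <- length(values)
  best <- NULL
  for (cc in mids) {
    nl <- sum(values <= cc)
    if (nl < ceiling(min_group_fraction * n) ||
        (n - nl) < ceiling(min_group_fraction * n)) next
    sd1 <- survival::survdiff(survival::Surv(times, events) ~ (values > cc))
    p <- stats::pchisq(sd1$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p) best <- list(cutoff = cc, p = p)
  }
  best
}

# O(n^2) concordance enumeration with explicit pair logic.
oracle_harrell_c <- function(lp, times, events) {
  n <- length(lp)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # i must be the earlier subject with an event
      earlier <- (times[i] < times[j]) ||
        (times[i] == times[j] && events[i] == 1 && events[j] == 0)
      if (!(events[i] == 1 && earlier)) next
      comp <- comp + 1
      if (lp[i] > lp[j]) conc <- conc + 1
      else if (lp[i] == lp[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Small half-plane slide shared by immunogradient tests: 1.3 x 1.95 mm at
# 0.5 um/px with the tumor on the right half.
make_halfplane_slide <- function(kappa = 2, seed = 1L, lambda_s = 800,
                                 decay_um = 4000, width = 2600,
                                 height = 3900) {
  ts <- tissue_scenario(width, height,
                        list(type = "half_plane", boundary_x_px = width / 2))
  tm <- generate_tissue_map(ts)
  cs <- cell_scenario(tumor_cell_density_mm2 = 0,
                      cd8_lambda_s_mm2 = lambda_s, cd8_kappa = kappa,
                      cd8_decay_um = decay_um, seed = seed)
  list(tissue = tm, cells = generate_cells(tm, cs))
}

# Hand-built interface zone: one hexagon per rank -4..4 on a single axial
# row, with chosen densities (unit analyzed area so density == count).
make_linear_iz <- function(densities, half_width = 4L) {
  ranks <- -half_width:half_width
  stopifnot(length(densities) == length(ranks))
  hexes <- data.frame(q = ranks, r = 0L, n_cd8 = densities,
                      tissue_area_mm2 = 1)
  extract_interface_zone(hexes, ranks,
                         edge_config(half_width = half_width))
}
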