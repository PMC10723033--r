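# Independent brute-force oracles for the hexbin geometry. These recompute
# everything from the grid definition (center formula, trigonometric vertex
# positions) without reusing the package's neighbor tables or rounding code.

# All candidate axial cells whose center could be nearest to any input point.
oracle_candidate_cells <- function(x, y, grid) {
  s <- grid$size
  qf <- (sqrt(3) / 3 * (x - grid$x0) - (y - grid$y0) / 3) / s
  rf <- (2 / 3 * (y - grid$y0)) / s
  expand.grid(q = (floor(min(qf)) - 2):(ceiling(max(qf)) + 2),
              r = (floor(min(rf)) - 2):(ceiling(max(rf)) + 2))
}

# Nearest-center assignment by exhaustive search; ties (within the same
# squared-distance tolerance the package documents) break to the
# lexicographically smallest (q, r).
oracle_assign <- function(x, y, grid) {
  cand <- oracle_candidate_cells(x, y, grid)
  ctr <- hex_centers(grid, cand$q, cand$r)
  eps <- 1e-9 * grid$size^2
  q <- integer(length(x)); r <- integer(length(x))
  for (i in seq_along(x)) {
    d <- (x[i] - ctr$x)^2 + (y[i] - ctr$y)^2
    tied <- which(d <= min(d) + eps)
    pick <- tied[order(cand$q[tied], cand$r[tied])][1]
    q[i] <- cand$q[pick]; r[i] <- cand$r[pick]
  }
  data.frame(q = q, r = r)
}

# Group-by aggregation over a given assignment: count, arithmetic mean,
# tally, majority with lexicographic tie-break.
oracle_groupby <- function(values, labels, asg) {
  key <- paste(asg$q, asg$r)
  res <- list()
  for (k in unique(key)) {
    sel <- key == k
    lab <- labels[sel]
    lab <- lab[!is.na(lab)]
    tt <- sort(table(lab))
    tally <- as.integer(table(lab)[sort(names(table(lab)), method = "radix")])
    names(tally) <- sort(names(table(lab)), method = "radix")
    winners <- names(tally)[tally == max(tally)]
    res[[k]] <- list(
      count = sum(sel),
      mean = mean(values[sel], na.rm = TRUE),
      tally = tally,
      majority = sort(winners, method = "radix")[1]
    )
  }
  res
}

# Trigonometric vertex positions of cell (q, r): vertex k at angle
# 30 + 60k degrees from the center, snapped onto the half-step lattice.
oracle_vertices_lattice <- function(grid, q, r) {
  ctr <- hex_centers(grid, q, r)
  ang <- (30 + 60 * (0:5)) * pi / 180
  vx <- ctr$x + grid$size * cos(ang)
  vy <- ctr$y + grid$size * sin(ang)
  cbind(i = round((vx - grid$x0) / (grid$size * sqrt(3) / 2)),
        j = round((vy - grid$y0) / (grid$size / 2)))
}

seg_key <- function(i1, j1, i2, j2) {
  swap <- i1 > i2 | (i1 == i2 & j1 > j2)
  a1 <- ifelse(swap, i2, i1); b1 <- ifelse(swap, j2, j1)
  a2 <- ifelse(swap, i1, i2); b2 <- ifelse(swap, j1, j2)
  paste(a1, b1, a2, b2)
}

# Brute-force per-edge boundary classification. cells: data.frame(q, r,
# label). For each (cell, edge) pair, locate the occupied neighbor across
# the edge by matching the geometric neighbor center, and emit the edge into
# the cell's label set iff that neighbor is absent or differently labeled.
oracle_boundaries <- function(grid, cells) {
  ctr <- hex_centers(grid, cells$q, cells$r)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    v <- oracle_vertices_lattice(grid, cells$q[i], cells$r[i])
    for (k in 1:6) {
      mid_ang <- (60 + 60 * (k - 1)) * pi / 180
      nx <- ctr$x[i] + grid$size * sqrt(3) * cos(mid_ang)
      ny <- ctr$y[i] + grid$size * sqrt(3) * sin(mid_ang)
      d <- (ctr$x - nx)^2 + (ctr$y - ny)^2
      nb <- which(d < (0.1 * grid$size)^2)
      if (length(nb) == 1 && cells$label[nb] == cells$label[i]) next
      k2 <- if (k == 6) 1 else k + 1
      key <- seg_key(v[k, 1], v[k, 2], v[k2, 1], v[k2, 2])
      out[[cells$label[i]]] <- union(out[[cells$label[i]]], key)
    }
  }
  out
}

boundary_keys <- function(boundary) {
  lapply(boundary$segments, function(df) {
    if (nrow(df) == 0) character(0) else seg_key(df$i1, df$j1, df$i2, df$j2)
  })
}

# Build a hex_aggregate with a prescribed occupancy/label pattern by placing
# one point at each occupied cell's center.
aggregate_from_pattern <- function(grid, cells_df) {
  ctr <- hex_centers(grid, cells_df$q, cells_df$r)
  tab <- point_table(ids = sprintf("c%04d", seq_len(nrow(cells_df))),
                     x = ctr$x, y = ctr$y,
                     annotations = list(lab = annotation_column(
                       cells_df$label, "categorical", "lab")))
  hex_aggregate(tab, grid, categorical = "lab")
}
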