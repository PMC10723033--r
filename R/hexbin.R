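#' Hexagonal binning of 2D embeddings
#'
#' Dense 2D embeddings (UMAP, t-SNE, PCA) overplot badly: tens of thousands
#' of cells land on top of each other, and convex hulls drawn around clusters
#' overlap, making hexagon membership ambiguous. These functions partition
#' the plane into pointy-top hexagons, summarize each occupied hexagon (point
#' count, mean of continuous variables, majority vote of categorical labels),
#' and extract per-label region outlines made of hexagon edges, which replace
#' convex hulls and by construction never overlap.
#'
#' Hexagons are addressed by axial coordinates `(q, r)`; a cell's center is
#' `(x0 + size*sqrt(3)*(q + r/2), y0 + size*(3/2)*r)` where `size` is the
#' circumradius. Every hexagon vertex lies on the half-step lattice
#' `(x0 + size*sqrt(3)/2 * i, y0 + size/2 * j)` for integers `(i, j)`, so
#' boundary segments are computed and compared exactly, with no floating-point
#' vertex matching.
#'
#' @name hexbin-geometry
NULL

# Axial direction across edge k (edges indexed by the angle of their
# midpoint: edge k spans vertices at 30+60k and 90+60k degrees).
HEX_DIRS <- matrix(c(0L, 1L, -1L, 1L, -1L, 0L, 0L, -1L, 1L, -1L, 1L, 0L),
                   ncol = 2, byrow = TRUE, dimnames = list(NULL, c("q", "r")))

# Vertex k of cell (q,r) on the integer half-step lattice (i,j):
# center is (2q + r, 3r); offsets below are (di, dj) for k = 0..5.
HEX_VERTEX_OFFSETS <- matrix(c(1L, 1L, 0L, 2L, -1L, 1L, -1L, -1L, 0L, -2L, 1L, -1L),
                             ncol = 2, byrow = TRUE)

#' Build a hexagonal grid covering an extent
#'
#' `nbins` counts hexagon columns across the x-extent, so the circumradius is
#' `(x_max - x_min) / (nbins * sqrt(3))` (column pitch is `size * sqrt(3)`).
#' The origin sits at the extent's lower-left corner, which therefore lies in
#' cell `(0, 0)`.
#'
#' @param x_extent,y_extent numeric `c(min, max)` with `max > min`.
#' @param nbins number of hexagon columns spanning the x-extent (>= 1).
#' @return an object of class `hex_grid` with fields `size`, `x0`, `y0`,
#'   `nbins`.
#' @export
hex_grid <- function(x_extent, y_extent, nbins) {
  if (length(nbins) != 1 || !is.finite(nbins) || nbins < 1) {
    stop_param("nbins must be a positive integer")
  }
  if (length(x_extent) != 2 || length(y_extent) != 2 ||
      !all(is.finite(c(x_extent, y_extent)))) {
    stop_param("extents must be finite c(min, max) pairs")
  }
  if (x_extent[2] <= x_extent[1] || y_extent[2] <= y_extent[1]) {
    stop_param("degenerate extent: max must exceed min on both axes")
  }
  structure(
    list(size = (x_extent[2] - x_extent[1]) / (nbins * sqrt(3)),
         x0 = x_extent[1], y0 = y_extent[1], nbins = as.integer(nbins)),
    class = "hex_grid"
  )
}

#' Hexagon centers for axial coordinates
#' @param grid a `hex_grid`.
#' @param q,r integer axial coordinates (vectorized).
#' @return list with numeric `x`, `y`.
#' @export
hex_centers <- function(grid, q, r) {
  s <- grid$size
  list(x = grid$x0 + s * sqrt(3) * (q + r / 2),
       y = grid$y0 + s * 1.5 * r)
}

# Integer lattice coordinates of the 6 vertices of each cell; returns a list
# of 6 (i, j) matrices or, for scalar input, a 6 x 2 matrix.
hex_vertices_lattice <- function(q, r) {
  ci <- 2L * q + r
  cj <- 3L * r
  lapply(seq_len(6), function(k) {
    cbind(i = ci + HEX_VERTEX_OFFSETS[k, 1], j = cj + HEX_VERTEX_OFFSETS[k, 2])
  })
}

lattice_to_xy <- function(grid, i, j) {
  list(x = grid$x0 + grid$size * sqrt(3) / 2 * i,
       y = grid$y0 + grid$size / 2 * j)
}

#' Assign points to hexagon cells
#'
#' Each point maps to the cell whose center is nearest in Euclidean distance,
#' computed via fractional axial coordinates and cube rounding, then verified
#' against the rounded cell's six neighbors. Points equidistant from two or
#' more centers (edge midpoints, vertices) resolve to the lexicographically
#' smallest `(q, r)`, so assignment is invariant under permutation of input
#' rows.
#'
#' @param points a `point_table`, or a list/data.frame with numeric `x`, `y`.
#' @param grid a `hex_grid`.
#' @return data.frame with integer columns `q`, `r`, one row per point.
#' @export
assign_hex <- function(points, grid) {
  s <- grid$size
  x <- points$x
  y <- points$y
  dx <- (x - grid$x0) / s
  dy <- (y - grid$y0) / s
  qf <- sqrt(3) / 3 * dx - dy / 3
  rf <- 2 / 3 * dy

  # cube rounding of fractional axial coordinates
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  ddx <- abs(rx - xf); ddy <- abs(ry - yf); ddz <- abs(rz - zf)
  fix_x <- ddx > ddy & ddx > ddz
  fix_z <- !fix_x & ddz > ddy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  q0 <- as.integer(rx); r0 <- as.integer(rz)

  # verify against neighbors with an explicit tie rule
  best_q <- q0; best_r <- r0
  ctr <- hex_centers(grid, q0, r0)
  best_d <- (x - ctr$x)^2 + (y - ctr$y)^2
  eps <- 1e-9 * s^2
  for (k in seq_len(6)) {
    cq <- q0 + HEX_DIRS[k, 1]; cr <- r0 + HEX_DIRS[k, 2]
    cc <- hex_centers(grid, cq, cr)
    d <- (x - cc$x)^2 + (y - cc$y)^2
    better <- d < best_d - eps
    tie <- abs(d - best_d) <= eps &
      (cq < best_q | (cq == best_q & cr < best_r))
    take <- better | tie
    best_q[take] <- cq[take]; best_r[take] <- cr[take]; best_d[take] <- d[take]
  }
  data.frame(q = best_q, r = best_r)
}

#' Aggregate points per hexagon
#'
#' For every occupied cell: the point count, the arithmetic mean of each
#' requested continuous variable over its non-missing member points, and the
#' label tally plus majority label of each requested categorical variable.
#' Majority ties break to the lexicographically smallest tied label. Cells
#' with no points are absent, keeping the aggregate sparse.
#'
#' @param points a `point_table`.
#' @param grid a `hex_grid`.
#' @param continuous names of continuous annotations to average.
#' @param categorical names of categorical annotations to tally.
#' @return an object of class `hex_aggregate`: `cells` (data.frame `q`, `r`,
#'   `count`, ordered by `q` then `r`), `means` (named list of numeric
#'   vectors aligned to `cells`), `majority` (named list of character
#'   vectors), `tally` (named list; per variable, a list of named integer
#'   vectors), plus the `grid` and the source `coord_mode`.
#' @export
hex_aggregate <- function(points, grid, continuous = character(),
                          categorical = character()) {
  stopifnot(inherits(points, "point_table"))
  for (nm in c(continuous, categorical)) get_annotation(points, nm) # name errors
  for (nm in continuous) {
    if (get_annotation(points, nm)$kind != "continuous") {
      stop_kind(sprintf("'%s' is not continuous", nm))
    }
  }
  for (nm in categorical) {
    if (get_annotation(points, nm)$kind != "categorical") {
      stop_kind(sprintf("'%s' is not categorical", nm))
    }
  }
  asg <- assign_hex(points, grid)
  key <- paste(asg$q, asg$r)
  ukey <- unique(key)
  uq <- asg$q[match(ukey, key)]
  ur <- asg$r[match(ukey, key)]
  ord <- order(uq, ur)
  ukey <- ukey[ord]
  cells <- data.frame(q = uq[ord], r = ur[ord])
  idx <- match(key, ukey)
  cells$count <- as.integer(tabulate(idx, nbins = nrow(cells)))

  means <- list()
  for (nm in continuous) {
    ann <- get_annotation(points, nm)
    v <- ann$values
    v[ann$missing] <- NA_real_
    sums <- vapply(split(v, idx), function(z) sum(z, na.rm = TRUE), 0)
    ns <- vapply(split(v, idx), function(z) sum(!is.na(z)), 0L)
    m <- rep(NA_real_, nrow(cells))
    pos <- as.integer(names(sums))
    m[pos] <- ifelse(ns > 0, sums / ns, NA_real_)
    means[[nm]] <- m
  }

  majority <- list(); tally <- list()
  for (nm in categorical) {
    ann <- get_annotation(points, nm)
    v <- ann$values
    v[ann$missing] <- NA_character_
    tl <- vector("list", nrow(cells))
    mj <- rep(NA_character_, nrow(cells))
    sp <- split(v, idx)
    for (j in seq_along(sp)) {
      cell_i <- as.integer(names(sp)[j])
      lab <- sp[[j]][!is.na(sp[[j]])]
      if (length(lab) == 0) { tl[[cell_i]] <- integer(0); next }
      tt <- table(lab)
      counts <- as.integer(tt)
      names(counts) <- names(tt)
      counts <- counts[lex_order(names(counts))]
      tl[[cell_i]] <- counts
      winners <- names(counts)[counts == max(counts)]
      mj[cell_i] <- lex_sort(winners)[1]
    }
    majority[[nm]] <- mj
    tally[[nm]] <- tl
  }

  structure(
    list(cells = cells, means = means, majority = majority, tally = tally,
         grid = grid, coord_mode = points$coord_mode),
    class = "hex_aggregate"
  )
}

#' @export
print.hex_aggregate <- function(x, ...) {
  cat(sprintf("<hex_aggregate: %d occupied cells, %d points>\n",
              nrow(x$cells), sum(x$cells$count)))
  if (length(x$means) > 0) cat("  means:", paste(names(x$means), collapse = ", "), "\n")
  if (length(x$majority) > 0) cat("  majorities:", paste(names(x$majority), collapse = ", "), "\n")
  invisible(x)
}

#' Extract label-region boundaries from a hex aggregate
#'
#' For every occupied cell and each of its six edges, the edge is emitted
#' into the cell's majority-label segment set iff the neighboring cell across
#' that edge is unoccupied or carries a different majority label. Edges
#' between two occupied cells of the same majority are suppressed on both
#' sides, so each label's segments trace the outline of its hexagon region;
#' an edge between two occupied cells of *different* majorities appears once
#' in each label's set. Unlike convex hulls, the interiors of distinct label
#' regions never overlap.
#'
#' Segment endpoints live on the grid's exact integer vertex lattice;
#' endpoints within each segment are ordered lexicographically and segments
#' deduplicated per label.
#'
#' @param agg a `hex_aggregate`.
#' @param grid the `hex_grid` used to build it.
#' @param variable name of a categorical variable aggregated in `agg`.
#' @return an object of class `region_boundary`: `segments` is a named list
#'   (one element per label, labels in lexicographic order) of data.frames
#'   with integer lattice columns `i1`, `j1`, `i2`, `j2`; `grid` and
#'   `variable` are carried along. Use [boundary_coords()] for data-unit
#'   endpoints.
#' @export
extract_label_boundaries <- function(agg, grid = agg$grid, variable) {
  stopifnot(inherits(agg, "hex_aggregate"))
  if (!variable %in% names(agg$majority)) {
    stop_name(sprintf("variable '%s' was not aggregated as categorical (available: %s)",
                      variable, paste(names(agg$majority), collapse = ", ")))
  }
  cells <- agg$cells
  maj <- agg$majority[[variable]]
  occ_key <- paste(cells$q, cells$r)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    lab <- maj[i]
    if (is.na(lab)) next
    verts <- lapply(seq_len(6), function(k) {
      c(2L * cells$q[i] + cells$r[i] + HEX_VERTEX_OFFSETS[k, 1],
        3L * cells$r[i] + HEX_VERTEX_OFFSETS[k, 2])
    })
    for (k in seq_len(6)) {
      nb <- c(cells$q[i] + HEX_DIRS[k, 1], cells$r[i] + HEX_DIRS[k, 2])
      nb_i <- match(paste(nb[1], nb[2]), occ_key)
      if (!is.na(nb_i) && !is.na(maj[nb_i]) && maj[nb_i] == lab) next
      a <- verts[[k]]; b <- verts[[if (k == 6) 1 else k + 1]]
      if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { tmp <- a; a <- b; b <- tmp }
      out[[length(out) + 1L]] <- c(i1 = a[1], j1 = a[2], i2 = b[1], j2 = b[2],
                                   label = lab)
    }
  }
  labels <- lex_sort(unique(vapply(out, function(s) s[["label"]], "")))
  segs <- list()
  for (lab in labels) {
    rows <- Filter(function(s) s[["label"]] == lab, out)
    df <- as.data.frame(do.call(rbind, lapply(rows, function(s) {
      as.integer(s[c("i1", "j1", "i2", "j2")])
    })))
    names(df) <- c("i1", "j1", "i2", "j2")
    df <- unique(df)
    df <- df[order(df$i1, df$j1, df$i2, df$j2), , drop = FALSE]
    rownames(df) <- NULL
    segs[[lab]] <- df
  }
  structure(list(segments = segs, grid = grid, variable = variable),
            class = "region_boundary")
}

#' Boundary segments in data units
#'
#' @param boundary a `region_boundary`.
#' @return data.frame with columns `label`, `x1`, `y1`, `x2`, `y2`.
#' @export
boundary_coords <- function(boundary) {
  stopifnot(inherits(boundary, "region_boundary"))
  rows <- lapply(names(boundary$segments), function(lab) {
    df <- boundary$segments[[lab]]
    if (nrow(df) == 0) return(NULL)
    p1 <- lattice_to_xy(boundary$grid, df$i1, df$j1)
    p2 <- lattice_to_xy(boundary$grid, df$i2, df$j2)
    data.frame(label = lab, x1 = p1$x, y1 = p1$y, x2 = p2$x, y2 = p2$y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compose a hexbin figure
#'
#' Hexagon patches are filled by the per-cell mean of `fill_variable`
#' (continuous colormap over the occupied-cell means; cells whose member
#' values are all missing render neutral grey), and label-region boundary
#' segments are stroked above the fills in the label's discrete color,
#' later labels (sorted order) on top.
#'
#' @param agg a `hex_aggregate` with `fill_variable` among its means.
#' @param boundaries a `region_boundary` (or `NULL` for fills only).
#' @param fill_variable name of an aggregated continuous variable.
#' @param colormap continuous colormap name.
#' @param palette optional named `label -> color` overrides for boundaries.
#' @param width,height,background,title,legend as in [spot_plot()].
#' @param boundary_width boundary stroke width in pixels.
#' @return an object of class `hex_figure`; render with [render_figure()].
#' @export
hex_plot <- function(agg, boundaries = NULL, fill_variable,
                     colormap = "viridis", palette = NULL,
                     width = 900, height = 900, background = "#FFFFFF",
                     title = NULL, legend = TRUE, boundary_width = 2.5) {
  stopifnot(inherits(agg, "hex_aggregate"))
  if (!fill_variable %in% names(agg$means)) {
    stop_name(sprintf("variable '%s' was not aggregated as continuous (available: %s)",
                      fill_variable, paste(names(agg$means), collapse = ", ")))
  }
  if (!is.null(boundaries)) stopifnot(inherits(boundaries, "region_boundary"))
  structure(
    list(agg = agg, boundaries = boundaries, fill_variable = fill_variable,
         colormap = colormap, palette = palette,
         width = as.integer(width), height = as.integer(height),
         background = background, title = title, legend = isTRUE(legend),
         boundary_width = boundary_width),
    class = "hex_figure"
  )
}

#' @export
build_scene.hex_figure <- function(fig, ...) {
  agg <- fig$agg
  grid <- agg$grid
  cells <- agg$cells
  if (nrow(cells) == 0) stop_validation("empty aggregate: nothing to draw")
  legend_w <- if (fig$legend) 190 else 0
  verts <- hex_vertices_lattice(cells$q, cells$r) # 6 matrices, one per corner
  vx <- sapply(verts, function(m) lattice_to_xy(grid, m[, 1], m[, 2])$x)
  vy <- sapply(verts, function(m) lattice_to_xy(grid, m[, 1], m[, 2])$y)
  vx <- matrix(vx, nrow = nrow(cells)); vy <- matrix(vy, nrow = nrow(cells))
  scene <- new_scene(fig$width, fig$height, fig$background)
  tr <- make_transform(as.vector(vx), as.vector(vy), agg$coord_mode,
                       fig$width - legend_w, fig$height, 30, pad = 0)
  fills <- continuous_colors(agg$means[[fig$fill_variable]], fig$colormap)
  for (i in seq_len(nrow(cells))) {
    scene <- scene_add(scene, el_polygon(tr$x(vx[i, ]), tr$y(vy[i, ]),
                                         fills[i], "none", 0, "hexcell"))
  }
  pal <- NULL
  if (!is.null(fig$boundaries)) {
    labs <- names(fig$boundaries$segments)
    if (length(labs) > 0) {
      pal <- discrete_palette(labs, fig$palette)
      for (lab in lex_sort(labs)) {
        df <- fig$boundaries$segments[[lab]]
        if (nrow(df) == 0) next
        p1 <- lattice_to_xy(grid, df$i1, df$j1)
        p2 <- lattice_to_xy(grid, df$i2, df$j2)
        for (sgi in seq_len(nrow(df))) {
          scene <- scene_add(scene, el_line(
            tr$x(p1$x[sgi]), tr$y(p1$y[sgi]), tr$x(p2$x[sgi]), tr$y(p2$y[sgi]),
            pal[[lab]], fig$boundary_width, "boundary"))
        }
      }
    }
  }
  if (!is.null(fig$title)) {
    scene <- scene_add(scene, el_text(fig$width / 2, 22, fig$title, 16,
                                      "#000000", "title", anchor = "middle"))
  }
  if (fig$legend) {
    lx <- fig$width - legend_w + 10
    ly0 <- 40
    scene <- scene_add(scene, el_text(lx, ly0, paste("mean", fig$fill_variable),
                                      14, "#000000", "legend-title"))
    ramp <- grDevices::hcl.colors(64, fig$colormap)
    for (i in seq_along(ramp)) {
      scene <- scene_add(scene, el_rect(lx + (i - 1) * 2, ly0 + 8, 2.2, 14,
                                        toupper(ramp[i]), "none", "legend-ramp"))
    }
    mv <- agg$means[[fig$fill_variable]]
    mv <- mv[!is.na(mv)]
    if (length(mv) > 0) {
      scene <- scene_add(scene, el_text(lx, ly0 + 38, sprintf("%.3g", min(mv)),
                                        11, "#000000", "legend-ramp-label"))
      scene <- scene_add(scene, el_text(lx + 128, ly0 + 38, sprintf("%.3g", max(mv)),
                                        11, "#000000", "legend-ramp-label",
                                        anchor = "end"))
    }
    ly0 <- ly0 + 60
    if (!is.null(pal)) {
      blk <- add_legend_block(scene, lx, ly0, fig$boundaries$variable,
                              as.list(pal[lex_sort(names(pal))]), "fill")
      scene <- blk$scene
    }
  }
  scene
}

#' Write a hex aggregate as a TSV table
#'
#' One row per occupied cell: `q`, `r`, `count`, one `mean_<name>` column per
#' continuous variable, and `majority_<name>` plus `tally_<name>`
#' (`label:count` pairs joined by `;`) per categorical variable.
#'
#' @param agg a `hex_aggregate`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hex_table <- function(agg, path) {
  stopifnot(inherits(agg, "hex_aggregate"))
  df <- agg$cells
  for (nm in names(agg$means)) df[[paste0("mean_", nm)]] <- agg$means[[nm]]
  for (nm in names(agg$majority)) {
    df[[paste0("majority_", nm)]] <- agg$majority[[nm]]
    df[[paste0("tally_", nm)]] <- vapply(agg$tally[[nm]], function(tt) {
      if (length(tt) == 0) return("")
      paste(sprintf("%s:%d", names(tt), tt), collapse = ";")
    }, "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
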