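#' Layered figure-ground spot plots
#'
#' A spot plot displays up to three variables at once on one set of 2D
#' coordinates by exploiting figure-ground segmentation: the *figure* layer
#' fills each spot's disc with a color encoding one variable; the *ground*
#' layer encodes a second, categorical variable as a thin colored outline
#' around each disc (a thin colored boundary is perceived as a surface color,
#' the so-called watercolor effect, so the outline reads as a background
#' region even in tightly packed spot lattices); an optional *symbol* layer
#' draws a glyph (`+`, `*`, `x`, `o`, `triangle`) on selected spots to
#' highlight a third, categorical variable.
#'
#' Each spot is drawn as a single disc whose stroke carries the ground color
#' and whose fill carries the figure color; a role that is absent leaves its
#' aesthetic at `"none"`, so a ground-only plot draws unfilled outlines.
#'
#' `spot_plot()` creates an empty figure specification bound to a validated
#' [point_table()]; layers are added with [add_ground()], [add_fill()] and
#' [add_symbol()] and the result is written with [render_figure()].
#'
#' @param table a valid [point_table()].
#' @param spot_diameter disc diameter in data units (> 0). For 10x Visium
#'   full-resolution pixel coordinates this is the spot diameter in pixels.
#' @param width,height output dimensions in pixels.
#' @param background background color.
#' @param title optional title string.
#' @param legend draw legends for the layers present?
#' @return An object of class `spot_figure` with an empty layer list.
#' @examples
#' pts <- point_table(ids = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 1, 0),
#'                    annotations = list(layer = c("L1", "L1", "WM"),
#'                                       expr = c(0.5, 2.0, 1.1)))
#' fig <- spot_plot(pts, spot_diameter = 0.8)
#' fig <- add_ground(fig, "layer")
#' fig <- add_fill(fig, "expr")
#' \donttest{
#' render_figure(fig, file.path(tempdir(), "spots.svg"))
#' }
#' @export
spot_plot <- function(table, spot_diameter, width = 900, height = 900,
                      background = "#FFFFFF", title = NULL, legend = TRUE) {
  table <- validate_point_table(table)
  if (!is.numeric(spot_diameter) || length(spot_diameter) != 1 ||
      !is.finite(spot_diameter) || spot_diameter <= 0) {
    stop_param("spot_diameter must be a positive number")
  }
  structure(
    list(table = table, spot_diameter = spot_diameter, layers = list(),
         width = as.integer(width), height = as.integer(height),
         background = background, title = title, legend = isTRUE(legend)),
    class = "spot_figure"
  )
}

layer_roles <- c(ground = 1L, figure = 2L, symbol = 3L)

check_new_layer <- function(fig, role) {
  stopifnot(inherits(fig, "spot_figure"))
  if (role %in% names(fig$layers)) {
    stop_duplicate(sprintf("figure already has a %s layer", role))
  }
}

#' Add a ground (outline) layer
#'
#' Encodes a categorical variable as the spot outline color. The disc
#' interior is left to the figure layer (transparent if none), realizing the
#' background role through thin colored outlines.
#'
#' @param fig a `spot_figure`.
#' @param variable name of a categorical annotation.
#' @param palette optional named `level -> color` overrides (see
#'   [discrete_palette()]).
#' @param stroke_width outline width in data units; defaults to 15% of the
#'   spot diameter so the fill stays visually dominant.
#' @return the updated `spot_figure`.
#' @export
add_ground <- function(fig, variable, palette = NULL, stroke_width = NULL) {
  check_new_layer(fig, "ground")
  ann <- get_annotation(fig$table, variable)
  if (ann$kind != "categorical") {
    stop_kind(sprintf("ground layer requires a categorical variable; '%s' is %s",
                      variable, ann$kind))
  }
  if (is.null(stroke_width)) stroke_width <- 0.15 * fig$spot_diameter
  if (!is.finite(stroke_width) || stroke_width <= 0) {
    stop_param("stroke_width must be positive")
  }
  fig$layers$ground <- list(role = "ground", variable = variable,
                            palette = palette, stroke_width = stroke_width,
                            z_rank = layer_roles[["ground"]])
  fig
}

#' Add a fill (figure) layer
#'
#' Paints each spot's interior. A continuous variable maps onto a colormap
#' over the `[min, max]` of its non-missing values (a constant column maps to
#' the colormap midpoint); a categorical variable uses a discrete palette.
#' Missing values render neutral grey.
#'
#' @param fig a `spot_figure`.
#' @param variable name of an annotation (either kind).
#' @param palette optional named `level -> color` overrides (categorical only).
#' @param colormap continuous colormap name (see [grDevices::hcl.colors()]).
#' @return the updated `spot_figure`.
#' @export
add_fill <- function(fig, variable, palette = NULL, colormap = "viridis") {
  check_new_layer(fig, "figure")
  ann <- get_annotation(fig$table, variable) # name error if absent
  fig$layers$figure <- list(role = "figure", variable = variable,
                            palette = palette, colormap = colormap,
                            z_rank = layer_roles[["figure"]])
  fig
}

GLYPH_SET <- c("+", "*", "x", "o", "triangle")

#' Add a symbol (highlight) layer
#'
#' Draws a glyph centered on each spot whose level is named in `glyph_map`,
#' above the fill. Levels absent from the map draw nothing, so a sparse map
#' highlights a subset (e.g. only significant spots).
#'
#' @param fig a `spot_figure`.
#' @param variable name of a categorical annotation.
#' @param glyph_map named character vector `level -> glyph`; glyphs must be
#'   drawn from `+ * x o triangle`. May cover any subset of levels, including
#'   none.
#' @param color glyph color.
#' @return the updated `spot_figure`.
#' @export
add_symbol <- function(fig, variable, glyph_map, color = "#000000") {
  check_new_layer(fig, "symbol")
  ann <- get_annotation(fig$table, variable)
  if (ann$kind != "categorical") {
    stop_kind(sprintf("symbol layer requires a categorical variable; '%s' is %s",
                      variable, ann$kind))
  }
  glyph_map <- unlist(glyph_map)
  if (length(glyph_map) > 0) {
    if (is.null(names(glyph_map)) || any(names(glyph_map) == "")) {
      stop_param("glyph_map must be a named level -> glyph mapping")
    }
    bad <- setdiff(unname(glyph_map), GLYPH_SET)
    if (length(bad) > 0) {
      stop_param(sprintf("unknown glyph '%s' (allowed: %s)", bad[1],
                         paste(GLYPH_SET, collapse = " ")))
    }
  }
  fig$layers$symbol <- list(role = "symbol", variable = variable,
                            glyph_map = glyph_map, color = color,
                            z_rank = layer_roles[["symbol"]])
  fig
}

# Map data coordinates into the canvas. Image-mode tables already have y
# increasing downward (the canvas convention); cartesian tables are flipped
# at render time only.
make_transform <- function(xs, ys, coord_mode, width, height, margin, pad) {
  xr <- range(xs) + c(-pad, pad)
  yr <- range(ys) + c(-pad, pad)
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  s <- min((width - 2 * margin) / diff(xr), (height - 2 * margin) / diff(yr))
  ox <- margin + (width - 2 * margin - diff(xr) * s) / 2
  oy <- margin + (height - 2 * margin - diff(yr) * s) / 2
  flip <- !identical(coord_mode, "image")
  list(
    x = function(x) ox + (x - xr[1]) * s,
    y = if (flip) function(y) oy + (yr[2] - y) * s
        else      function(y) oy + (y - yr[1]) * s,
    scale = s
  )
}

glyph_elements <- function(glyph, px, py, g, color, lw) {
  h <- g / 2
  switch(glyph,
    "+" = list(el_line(px - h, py, px + h, py, color, lw, "glyph"),
               el_line(px, py - h, px, py + h, color, lw, "glyph")),
    "x" = {
      d <- h * sqrt(0.5)
      list(el_line(px - d, py - d, px + d, py + d, color, lw, "glyph"),
           el_line(px - d, py + d, px + d, py - d, color, lw, "glyph"))
    },
    "*" = {
      d <- h * sqrt(0.5)
      list(el_line(px - h, py, px + h, py, color, lw, "glyph"),
           el_line(px, py - h, px, py + h, color, lw, "glyph"),
           el_line(px - d, py - d, px + d, py + d, color, lw, "glyph"),
           el_line(px - d, py + d, px + d, py - d, color, lw, "glyph"))
    },
    "o" = list(el_circle(px, py, h * 0.8, "none", color, lw, "glyph")),
    "triangle" = list(el_polygon(
      c(px, px - h * 0.9, px + h * 0.9),
      c(py - h, py + h * 0.75, py + h * 0.75),
      "none", color, lw, "glyph"))
  )
}

add_legend_block <- function(scene, x, y, title, entries, swatch_kind) {
  scene <- scene_add(scene, el_text(x, y, title, 14, "#000000", "legend-title"))
  y <- y + 10
  for (i in seq_along(entries)) {
    y <- y + 20
    col <- entries[[i]]
    if (swatch_kind == "stroke") {
      scene <- scene_add(scene, el_circle(x + 7, y - 4, 6, "none", col, 2, "legend-swatch"))
    } else {
      scene <- scene_add(scene, el_rect(x, y - 11, 14, 14, col, "none", "legend-swatch"))
    }
    scene <- scene_add(scene, el_text(x + 22, y, names(entries)[i], 12,
                                      "#000000", "legend-label"))
  }
  list(scene = scene, y = y + 24)
}

build_spot_scene <- function(fig, config = list()) {
  if (length(fig$layers) == 0) {
    stop_validation("figure has no layers; add at least one of ground/fill/symbol")
  }
  tab <- fig$table
  n <- length(tab$ids)
  legend_w <- if (fig$legend) 190 else 0
  margin <- 30
  scene <- new_scene(fig$width, fig$height, fig$background)
  tr <- make_transform(tab$x, tab$y, tab$coord_mode,
                       fig$width - legend_w, fig$height, margin,
                       pad = fig$spot_diameter / 2)
  ord <- lex_order(tab$ids) # deterministic overplotting order
  px <- tr$x(tab$x)[ord]
  py <- tr$y(tab$y)[ord]
  r_px <- fig$spot_diameter / 2 * tr$scale

  fill_cols <- rep("none", n)
  fill_legend <- NULL
  if ("figure" %in% names(fig$layers)) {
    ly <- fig$layers$figure
    ann <- get_annotation(tab, ly$variable)
    if (ann$kind == "continuous") {
      fill_cols <- continuous_colors(ann$values, ly$colormap)
      fill_legend <- list(kind = "continuous", values = ann$values,
                          colormap = ly$colormap, variable = ly$variable)
    } else {
      pal <- discrete_palette(ann$levels, ly$palette)
      fill_cols <- ifelse(ann$missing, MISSING_GREY, pal[ann$values])
      present <- lex_sort(unique(ann$values[!ann$missing]))
      fill_legend <- list(kind = "categorical", pal = pal[present],
                          variable = ly$variable)
    }
    fill_cols <- fill_cols[ord]
  }

  stroke_cols <- rep("none", n)
  stroke_w <- 0
  ground_legend <- NULL
  if ("ground" %in% names(fig$layers)) {
    ly <- fig$layers$ground
    ann <- get_annotation(tab, ly$variable)
    pal <- discrete_palette(ann$levels, ly$palette)
    stroke_cols <- ifelse(ann$missing, MISSING_GREY, pal[ann$values])[ord]
    stroke_w <- ly$stroke_width * tr$scale
    present <- lex_sort(unique(ann$values[!ann$missing]))
    ground_legend <- list(pal = pal[present], variable = ly$variable)
  }

  for (i in seq_len(n)) {
    scene <- scene_add(scene, el_circle(px[i], py[i], r_px,
                                        fill_cols[i], stroke_cols[i],
                                        stroke_w, "spot"))
  }

  symbol_legend <- NULL
  if ("symbol" %in% names(fig$layers)) {
    ly <- fig$layers$symbol
    ann <- get_annotation(tab, ly$variable)
    vals <- ann$values[ord]
    miss <- ann$missing[ord]
    g <- max(2 * r_px * 0.6, 3)
    lw <- max(r_px * 0.18, 1)
    for (i in seq_len(n)) {
      if (miss[i]) next
      gl <- unname(ly$glyph_map[vals[i]])
      if (length(gl) != 1 || is.na(gl)) next
      for (el in glyph_elements(gl, px[i], py[i], g, ly$color, lw)) {
        scene <- scene_add(scene, el)
      }
    }
    covered <- intersect(names(ly$glyph_map), unique(vals[!miss]))
    if (length(covered) > 0) {
      symbol_legend <- list(map = ly$glyph_map[lex_sort(covered)],
                            variable = ly$variable, color = ly$color)
    }
  }

  if (!is.null(fig$title)) {
    scene <- scene_add(scene, el_text(fig$width / 2, 22, fig$title, 16,
                                      "#000000", "title", anchor = "middle"))
  }

  if (fig$legend) {
    lx <- fig$width - legend_w + 10
    ly0 <- 40
    if (!is.null(ground_legend)) {
      blk <- add_legend_block(scene, lx, ly0, ground_legend$variable,
                              as.list(ground_legend$pal), "stroke")
      scene <- blk$scene; ly0 <- blk$y
    }
    if (!is.null(fill_legend)) {
      if (fill_legend$kind == "categorical") {
        blk <- add_legend_block(scene, lx, ly0, fill_legend$variable,
                                as.list(fill_legend$pal), "fill")
        scene <- blk$scene; ly0 <- blk$y
      } else {
        scene <- scene_add(scene, el_text(lx, ly0, fill_legend$variable, 14,
                                          "#000000", "legend-title"))
        ramp <- grDevices::hcl.colors(64, fill_legend$colormap)
        for (i in seq_along(ramp)) {
          scene <- scene_add(scene, el_rect(lx + (i - 1) * 2, ly0 + 8, 2.2, 14,
                                            toupper(ramp[i]), "none", "legend-ramp"))
        }
        okv <- fill_legend$values[!is.na(fill_legend$values)]
        if (length(okv) > 0) {
          scene <- scene_add(scene, el_text(lx, ly0 + 38,
                                            sprintf("%.3g", min(okv)), 11,
                                            "#000000", "legend-ramp-label"))
          scene <- scene_add(scene, el_text(lx + 128, ly0 + 38,
                                            sprintf("%.3g", max(okv)), 11,
                                            "#000000", "legend-ramp-label", anchor = "end"))
        }
        ly0 <- ly0 + 60
      }
    }
    if (!is.null(symbol_legend)) {
      scene <- scene_add(scene, el_text(lx, ly0, symbol_legend$variable, 14,
                                        "#000000", "legend-title"))
      yy <- ly0 + 10
      for (i in seq_along(symbol_legend$map)) {
        yy <- yy + 20
        for (el in glyph_elements(symbol_legend$map[[i]], lx + 7, yy - 4, 10,
                                  symbol_legend$color, 1.5)) {
          el$class <- "legend-swatch"
          scene <- scene_add(scene, el)
        }
        scene <- scene_add(scene, el_text(lx + 22, yy, names(symbol_legend$map)[i],
                                          12, "#000000", "legend-label"))
      }
    }
  }
  scene
}

#' Render a spot figure to a file
#'
#' SVG output is fully deterministic and structured for inspection: every
#' spot is one `<circle class="spot">` whose `stroke` carries the ground
#' color (or `"none"`), whose `fill` carries the figure color (or `"none"`),
#' and symbol glyphs appear strictly after all spot discs in document order.
#'
#' @param fig a `spot_figure` with at least one layer.
#' @param path output file path.
#' @param format `"svg"`, `"png"` or `"pdf"`; default inferred from the file
#'   extension, falling back to svg.
#' @return the path, invisibly.
#' @export
render_figure <- function(fig, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("svg", "png", "pdf")) ext else "svg"
  }
  scene <- build_scene(fig)
  write_scene(scene, path, format)
  invisible(path)
}

# Internal dispatch shared by spot and hex figures.
build_scene <- function(fig, ...) UseMethod("build_scene")

#' @export
build_scene.spot_figure <- function(fig, ...) build_spot_scene(fig, ...)
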