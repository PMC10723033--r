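# A "scene" is an ordered list of drawing primitives in canvas (pixel)
# coordinates, y increasing downward as in SVG. Renderers write it to SVG
# textually (circles, polygons, lines and text keep their semantic class
# attributes, so z-order and styling are machine-checkable) or replay it on a
# grDevices raster/vector device for PNG and PDF.

new_scene <- function(width, height, background = "#FFFFFF") {
  list(width = width, height = height, background = background, elements = list())
}

scene_add <- function(scene, el) {
  scene$elements[[length(scene$elements) + 1L]] <- el
  scene
}

el_circle <- function(cx, cy, r, fill, stroke, stroke_width, class) {
  list(type = "circle", cx = cx, cy = cy, r = r, fill = fill,
       stroke = stroke, stroke_width = stroke_width, class = class)
}

el_polygon <- function(xs, ys, fill, stroke, stroke_width, class) {
  list(type = "polygon", xs = xs, ys = ys, fill = fill,
       stroke = stroke, stroke_width = stroke_width, class = class)
}

el_line <- function(x1, y1, x2, y2, stroke, stroke_width, class) {
  list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       stroke = stroke, stroke_width = stroke_width, class = class)
}

el_rect <- function(x, y, w, h, fill, stroke, class) {
  list(type = "rect", x = x, y = y, w = w, h = h,
       fill = fill, stroke = stroke, class = class)
}

el_text <- function(x, y, label, size, fill, class, anchor = "start") {
  list(type = "text", x = x, y = y, label = label, size = size,
       fill = fill, class = class, anchor = anchor)
}

svg_attr <- function(name, value) sprintf(' %s="%s"', name, value)

element_to_svg <- function(el) {
  switch(el$type,
    circle = sprintf(
      '<circle class="%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      el$class, fmt_px(el$cx), fmt_px(el$cy), fmt_px(el$r),
      el$fill, el$stroke, fmt_px(el$stroke_width)),
    polygon = sprintf(
      '<polygon class="%s" points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      el$class,
      paste(sprintf("%s,%s", fmt_px(el$xs), fmt_px(el$ys)), collapse = " "),
      el$fill, el$stroke, fmt_px(el$stroke_width)),
    line = sprintf(
      '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      el$class, fmt_px(el$x1), fmt_px(el$y1), fmt_px(el$x2), fmt_px(el$y2),
      el$stroke, fmt_px(el$stroke_width)),
    rect = sprintf(
      '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
      el$class, fmt_px(el$x), fmt_px(el$y), fmt_px(el$w), fmt_px(el$h),
      el$fill, el$stroke),
    text = sprintf(
      '<text class="%s" x="%s" y="%s" font-size="%s" fill="%s" text-anchor="%s" font-family="sans-serif">%s</text>',
      el$class, fmt_px(el$x), fmt_px(el$y), fmt_px(el$size), el$fill,
      el$anchor, xml_escape(el$label)),
    stop_validation(sprintf("unknown scene element type '%s'", el$type))
  )
}

write_scene_svg <- function(scene, path) {
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            scene$width, scene$height, scene$width, scene$height),
    sprintf('<rect class="background" x="0" y="0" width="%d" height="%d" fill="%s" stroke="none"/>',
            scene$width, scene$height, scene$background),
    vapply(scene$elements, element_to_svg, character(1)),
    "</svg>"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Replay the scene on a grDevices device (canvas y-down handled by a flipped
# plot window).
draw_scene_device <- function(scene) {
  col_or_na <- function(x) if (identical(x, "none")) NA else x
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, scene$width), ylim = c(scene$height, 0), asp = 1)
  graphics::rect(0, scene$height, scene$width, 0, col = scene$background, border = NA)
  for (el in scene$elements) {
    switch(el$type,
      circle = graphics::symbols(el$cx, el$cy, circles = el$r, inches = FALSE,
                                 add = TRUE, bg = col_or_na(el$fill),
                                 fg = if (identical(el$stroke, "none")) NA else el$stroke,
                                 lwd = max(el$stroke_width, 0.1)),
      polygon = graphics::polygon(el$xs, el$ys, col = col_or_na(el$fill),
                                  border = col_or_na(el$stroke),
                                  lwd = max(el$stroke_width, 0.1)),
      line = graphics::segments(el$x1, el$y1, el$x2, el$y2,
                                col = el$stroke, lwd = max(el$stroke_width, 0.1)),
      rect = graphics::rect(el$x, el$y + el$h, el$x + el$w, el$y,
                            col = col_or_na(el$fill), border = col_or_na(el$stroke)),
      text = graphics::text(el$x, el$y, labels = el$label,
                            adj = c(if (el$anchor == "middle") 0.5 else 0, 0),
                            cex = el$size / 12, col = el$fill)
    )
  }
  invisible(NULL)
}

write_scene <- function(scene, path, format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("output directory does not exist: '%s'", dir))
  if (format == "svg") return(write_scene_svg(scene, path))
  if (format == "png") {
    grDevices::png(path, width = scene$width, height = scene$height, type = "cairo")
  } else {
    grDevices::pdf(path, width = scene$width / 96, height = scene$height / 96)
  }
  on.exit(grDevices::dev.off())
  draw_scene_device(scene)
  invisible(path)
}
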