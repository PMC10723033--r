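test_that("figure construction enforces its contracts", {
  tab <- tiny_table()
  fig <- spot_plot(tab, 1.0)
  expect_s3_class(fig, "spot_figure")
  expect_length(fig$layers, 0)
  expect_error(spot_plot(tab, 0), class = "spotlayer_param_error")
  expect_error(spot_plot(tab, -2), class = "spotlayer_param_error")
  bad <- tab; bad$ids <- c("a", "a", "b")
  expect_error(spot_plot(bad, 1), class = "spotlayer_duplicate_error")
})

test_that("layer roles enforce variable kinds and single occupancy", {
  fig <- spot_plot(tiny_table(), 1.0)
  expect_error(add_ground(fig, "expr"), class = "spotlayer_kind_error")
  expect_error(add_symbol(fig, "expr", c(hit = "+")),
               class = "spotlayer_kind_error")
  expect_error(add_fill(fig, "nope"), class = "spotlayer_name_error")
  g <- add_ground(fig, "domain")
  expect_error(add_ground(g, "status"), class = "spotlayer_duplicate_error")
  f <- add_fill(fig, "expr")
  expect_error(add_fill(f, "domain"), class = "spotlayer_duplicate_error")
  expect_error(add_symbol(fig, "status", c(hit = "donut")),
               class = "spotlayer_param_error")
})

test_that("svg discs carry ground stroke and figure fill; glyphs come last", {
  fig <- spot_plot(tiny_table(), 1.0, legend = FALSE)
  fig <- add_ground(fig, "domain")
  fig <- add_fill(fig, "status")
  fig <- add_symbol(fig, "status", c(hit = "+"))
  els <- svg_elements(render_tmp_svg(fig))
  spots <- els[els$class == "spot", ]
  expect_identical(nrow(spots), 3L)
  expect_true(all(spots$fill != "none" & spots$stroke != "none"))
  glyphs <- which(els$class == "glyph")
  expect_length(glyphs, 4L) # two "+" glyphs, two strokes each
  expect_true(min(glyphs) > max(which(els$class == "spot")))
})

test_that("ground-only plots draw unfilled discs (transparent interior)", {
  fig <- add_ground(spot_plot(tiny_table(), 1.0, legend = FALSE), "domain")
  els <- svg_elements(render_tmp_svg(fig))
  spots <- els[els$class == "spot", ]
  expect_true(all(spots$fill == "none"))
  expect_true(all(spots$stroke != "none"))
})

test_that("stroke colors are exactly the palette colors of levels present", {
  tab <- point_table(
    ids = sprintf("s%02d", 1:8), x = 1:8, y = rep(1:2, 4),
    annotations = list(domain = rep(c("L1", "L2", "L3", "WM"), 2)))
  fig <- add_ground(spot_plot(tab, 0.8, legend = FALSE), "domain")
  els <- svg_elements(render_tmp_svg(fig))
  pal <- discrete_palette(c("L1", "L2", "L3", "WM"))
  expect_setequal(unique(els$stroke[els$class == "spot"]), unname(pal))
})

test_that("categorical fill uses one color per level; 7 levels get 7 outline colors", {
  lv <- c(paste0("L", 1:6), "WM")
  tab <- point_table(ids = sprintf("s%02d", 1:14), x = 1:14, y = rep(1:2, 7),
                     annotations = list(domain = rep(lv, 2)))
  fig <- add_ground(spot_plot(tab, 0.8, legend = FALSE), "domain")
  els <- svg_elements(render_tmp_svg(fig))
  expect_length(unique(els$stroke[els$class == "spot"]), 7L)
})

test_that("constant continuous fill maps every spot to the colormap midpoint", {
  tab <- point_table(ids = c("a", "b"), x = c(0, 1), y = c(0, 0),
                     annotations = list(v = c(3.3, 3.3)))
  fig <- add_fill(spot_plot(tab, 0.5, legend = FALSE), "v")
  els <- svg_elements(render_tmp_svg(fig))
  mid <- toupper(grDevices::hcl.colors(256, "viridis")[128])
  expect_identical(unique(els$fill[els$class == "spot"]), mid)
})

test_that("missing annotation values render neutral grey", {
  tab <- point_table(ids = c("a", "b"), x = c(0, 1), y = c(0, 0),
                     annotations = list(v = c(1.0, NA)))
  fig <- add_fill(spot_plot(tab, 0.5, legend = FALSE), "v")
  els <- svg_elements(render_tmp_svg(fig))
  expect_identical(els$fill[els$class == "spot"][2], "#BDBDBD")
})

test_that("empty glyph map draws no glyphs; uncovered levels draw nothing", {
  fig0 <- add_symbol(spot_plot(tiny_table(), 1.0, legend = FALSE), "status",
                     character(0))
  els0 <- svg_elements(render_tmp_svg(fig0))
  expect_false(any(els0$class == "glyph"))
  fig1 <- add_symbol(spot_plot(tiny_table(), 1.0, legend = FALSE), "status",
                     c(hit = "o")) # "none" level uncovered
  els1 <- svg_elements(render_tmp_svg(fig1))
  expect_identical(sum(els1$class == "glyph"), 2L) # the two "hit" points
})

test_that("rebuilding without a layer is byte-identical to never adding it", {
  base <- add_fill(add_ground(spot_plot(tiny_table(), 1.0), "domain"), "expr")
  p1 <- render_tmp_svg(base)
  with_symbol <- add_symbol(base, "status", c(hit = "*"))
  render_tmp_svg(with_symbol) # add ...
  rebuilt <- add_fill(add_ground(spot_plot(tiny_table(), 1.0), "domain"), "expr")
  p2 <- render_tmp_svg(rebuilt) # ... and rebuild without
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("every level present appears exactly once in its layer's legend", {
  tab <- point_table(
    ids = sprintf("s%02d", 1:6), x = 1:6, y = rep(1, 6),
    annotations = list(
      domain = c("L1", "L2", "L3", "L1", "L2", "L3"),
      status = c("both", "none", "geneA", "none", "none", "geneA")))
  fig <- add_fill(add_ground(spot_plot(tab, 0.8), "domain"), "status")
  els <- svg_elements(render_tmp_svg(fig))
  labels <- els$text[els$class == "legend-label"]
  for (lv in c("L1", "L2", "L3", "both", "none", "geneA")) {
    expect_identical(sum(labels == lv), 1L)
  }
  # a level absent from the data is absent from the legend
  expect_false("geneB" %in% labels)
})

test_that("rendering an empty figure or to a bad path fails loudly", {
  fig <- spot_plot(tiny_table(), 1.0)
  expect_error(render_figure(fig, tempfile(fileext = ".svg")),
               class = "spotlayer_validation_error")
  full <- add_fill(fig, "expr")
  expect_error(render_figure(full, "/nonexistent/dir/x.svg"),
               class = "spotlayer_io_error")
})

test_that("image-mode tables render with the y axis flipped, data untouched", {
  tab_img <- point_table(c("a", "b"), x = c(0, 0), y = c(0, 10),
                         coord_mode = "image",
                         annotations = list(v = c(1, 2)))
  tab_car <- point_table(c("a", "b"), x = c(0, 0), y = c(0, 10),
                         coord_mode = "cartesian",
                         annotations = list(v = c(1, 2)))
  get_cys <- function(tab) {
    fig <- add_fill(spot_plot(tab, 1, legend = FALSE), "v")
    doc <- xml2::read_xml(render_tmp_svg(fig))
    nodes <- xml2::xml_find_all(doc, "//*[local-name()='circle']")
    as.numeric(vapply(nodes, function(n) xml2::xml_attr(n, "cy"), ""))
  }
  cy_img <- get_cys(tab_img)
  cy_car <- get_cys(tab_car)
  # point "a" (y=0) is at the top in image mode, at the bottom in cartesian
  expect_lt(cy_img[1], cy_img[2])
  expect_gt(cy_car[1], cy_car[2])
  expect_identical(tab_img$y, c(0, 10)) # stored coordinates never mutated
})

test_that("png and pdf renderings are written", {
  fig <- add_fill(spot_plot(tiny_table(), 1.0), "expr")
  for (ext in c("png", "pdf")) {
    path <- tempfile(fileext = paste0(".", ext))
    render_figure(fig, path)
    expect_gt(file.size(path), 0)
  }
})
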