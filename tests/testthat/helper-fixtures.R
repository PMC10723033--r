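# Small in-code fixtures shared across test files.

tiny_table <- function() {
  point_table(
    ids = c("a", "b", "c"),
    x = c(0, 1, 2), y = c(0, 1, 0),
    annotations = list(
      domain = annotation_column(c("L1", "L1", "WM"), "categorical", "domain"),
      expr = annotation_column(c(0.5, 2.0, 1.1), "continuous", "expr"),
      status = annotation_column(c("hit", "none", "hit"), "categorical", "status")
    )
  )
}

# Parse an SVG and return a data.frame of drawable elements in document
# order with their class/fill/stroke attributes.
svg_elements <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[self::*[local-name()='circle'] or
    self::*[local-name()='polygon'] or self::*[local-name()='line'] or
    self::*[local-name()='rect'] or self::*[local-name()='text']]")
  data.frame(
    tag = xml2::xml_name(nodes),
    class = vapply(nodes, function(n) xml2::xml_attr(n, "class"), ""),
    fill = vapply(nodes, function(n) xml2::xml_attr(n, "fill"), ""),
    stroke = vapply(nodes, function(n) xml2::xml_attr(n, "stroke"), ""),
    text = vapply(nodes, function(n) xml2::xml_text(n), ""),
    stringsAsFactors = FALSE
  )
}

render_tmp_svg <- function(fig) {
  path <- tempfile(fileext = ".svg")
  render_figure(fig, path)
  path
}
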