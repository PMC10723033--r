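# Byte-order (C locale) sorting so level -> color assignment and drawing
# order never depend on the session locale.
lex_sort <- function(x) {
  if (length(x) == 0) return(x)
  x[order(x, method = "radix")]
}

lex_order <- function(x) order(x, method = "radix")

# Fixed-precision coordinate formatting for SVG output: deterministic bytes.
fmt_px <- function(v) sprintf("%.3f", v)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}
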