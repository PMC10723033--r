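#' Read a flat style configuration file
#'
#' A minimal flat TOML dialect: one `key = value` per line, `#` comments,
#' values either quoted strings, bare numbers, or `true`/`false`. Recognized
#' keys (all optional): `width`, `height` (pixels), `background`,
#' `missing_color`, `glyph_color` (colors), `colormap` (continuous palette
#' name), `stroke_frac` (ground outline width as a fraction of spot
#' diameter), `boundary_width` (pixels), `legend` (boolean), and
#' `palette.<level> = "<color>"` entries overriding discrete level colors.
#'
#' @param path config file path, or `NULL` for defaults.
#' @return named list of style settings.
#' @export
read_style_config <- function(path = NULL) {
  cfg <- list(width = 900, height = 900, background = "#FFFFFF",
              missing_color = MISSING_GREY, glyph_color = "#000000",
              colormap = "viridis", stroke_frac = 0.15,
              boundary_width = 2.5, legend = TRUE, palette = NULL)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_io(sprintf("config file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  pal <- character()
  strip_comment <- function(s) {
    # '#' starts a comment only outside quoted strings (colors contain '#')
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    inq <- FALSE
    for (i in seq_along(chars)) {
      if (chars[i] %in% c('"', "'")) inq <- !inq
      else if (chars[i] == "#" && !inq) return(substr(s, 1, i - 1))
    }
    s
  }
  for (ln in seq_along(lines)) {
    raw <- trimws(strip_comment(lines[ln]))
    if (raw == "") next
    m <- regmatches(raw, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", raw))[[1]]
    if (length(m) != 3) {
      stop_format(sprintf("config line %d is not 'key = value': '%s'", ln, lines[ln]))
    }
    key <- m[2]; val <- trimws(m[3])
    parsed <- if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      substr(val, 2, nchar(val) - 1)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop_format(
        sprintf("config line %d: unquoted value '%s' is not a number or boolean", ln, val))
      num
    }
    if (startsWith(key, "palette.")) {
      pal[sub("^palette\\.", "", key)] <- as.character(parsed)
    } else {
      cfg[[key]] <- parsed
    }
  }
  if (length(pal) > 0) cfg$palette <- pal
  cfg
}
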