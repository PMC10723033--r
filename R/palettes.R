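# Color assignment. Discrete levels get a colorblind-safe Okabe-Ito cycle,
# assigned deterministically by sorted level order so the same data always
# renders the same way. Continuous values map onto a perceptually uniform
# colormap over [min, max] of the non-missing values.

MISSING_GREY <- "#BDBDBD"

#' Deterministic discrete palette
#'
#' Maps sorted levels onto a colorblind-safe cycle (Okabe-Ito, recycled past
#' eight levels). A named palette vector overrides the default per level.
#'
#' @param levels character vector of levels (order irrelevant; assignment is
#'   by sorted order).
#' @param palette optional named character vector `level -> color`; levels it
#'   does not name fall back to the default cycle.
#' @return named character vector `level -> hex color`.
#' @export
discrete_palette <- function(levels, palette = NULL) {
  levels <- lex_sort(unique(levels))
  base <- grDevices::palette.colors(9, palette = "Okabe-Ito")[-1] # drop black
  cols <- rep(base, length.out = length(levels))
  names(cols) <- levels
  cols[] <- toupper(substr(cols, 1, 7))
  if (!is.null(palette)) {
    hit <- intersect(names(palette), levels)
    cols[hit] <- toupper(as.character(palette[hit]))
  }
  cols
}

#' Continuous colormap lookup
#'
#' Linearly maps values over `[min, max]` of the non-missing entries onto a
#' 256-step colormap. A constant column (zero range) maps to the colormap
#' midpoint; missing values map to neutral grey.
#'
#' @param values numeric vector, may contain `NA`.
#' @param colormap a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param missing_color color used for `NA` values.
#' @return character vector of hex colors, same length as `values`.
#' @export
continuous_colors <- function(values, colormap = "viridis",
                              missing_color = MISSING_GREY) {
  ramp <- grDevices::hcl.colors(256, palette = colormap)
  out <- rep(missing_color, length(values))
  ok <- !is.na(values) & is.finite(values)
  if (!any(ok)) return(out)
  rng <- range(values[ok])
  if (rng[1] == rng[2]) {
    out[ok] <- ramp[128]
  } else {
    idx <- 1L + as.integer(round((values[ok] - rng[1]) / (rng[2] - rng[1]) * 255))
    out[ok] <- ramp[pmin(pmax(idx, 1L), 256L)]
  }
  toupper(out)
}
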