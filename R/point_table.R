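#' Annotation column
#'
#' A single per-point variable attached to a [point_table()]. Continuous
#' columns hold real values (e.g. gene expression); categorical columns hold
#' labels drawn from a finite level set (e.g. cortical layer, cluster id,
#' colocalization status). Missing values are carried as `NA` plus an explicit
#' missing mask, and are rendered in a neutral grey.
#'
#' @param values numeric vector (continuous) or character/factor/logical
#'   vector (categorical). `NA` entries are treated as missing.
#' @param kind `"continuous"`, `"categorical"`, or `NULL` to infer with
#'   [infer_kind()]. An explicit kind always wins over inference, so integer
#'   cluster ids can be forced categorical.
#' @param name column name (short string).
#' @return An object of class `annotation_column` with fields `name`, `kind`,
#'   `values`, `missing` (logical mask) and, for categorical columns,
#'   `levels` (sorted unique non-missing labels).
#' @export
annotation_column <- function(values, kind = NULL, name = "value") {
  if (length(values) == 0L) stop_validation("annotation values must be non-empty")
  if (is.null(kind)) kind <- infer_kind(values)
  kind <- match.arg(kind, c("continuous", "categorical"))
  if (kind == "continuous") {
    if (!is.numeric(values) && !all(is.na(values))) {
      stop_kind(sprintf("column '%s': continuous values must be numeric", name))
    }
    values <- as.double(values)
    missing <- is.na(values) | !is.finite(values)
    values[missing] <- NA_real_
    levels <- NULL
  } else {
    if (is.factor(values)) values <- as.character(values)
    if (is.logical(values)) values <- as.character(values)
    values <- as.character(values)
    missing <- is.na(values)
    levels <- lex_sort(unique(values[!missing]))
    if (all(missing)) stop_validation(
      sprintf("column '%s': categorical column has no non-missing level", name))
  }
  structure(
    list(name = name, kind = kind, values = values,
         missing = missing, levels = levels),
    class = "annotation_column"
  )
}

#' Infer whether raw values are continuous or categorical
#'
#' Numeric input (including integers, which cover expression counts) maps to
#' continuous; character, factor and logical input map to categorical. Mixed
#' numeric/character content in a character vector is rejected rather than
#' guessed: pass an explicit `kind` to [annotation_column()] instead.
#'
#' @param values a non-empty vector.
#' @return `"continuous"` or `"categorical"`.
#' @export
infer_kind <- function(values) {
  if (length(values) == 0L) stop_validation("cannot infer kind of empty input")
  if (is.numeric(values)) return("continuous")
  if (is.logical(values) || is.factor(values)) return("categorical")
  if (is.character(values)) {
    nonmiss <- values[!is.na(values)]
    if (length(nonmiss) == 0L) return("categorical")
    numlike <- suppressWarnings(!is.na(as.numeric(nonmiss)))
    if (all(numlike)) return("continuous")
    if (any(numlike)) stop_kind(
      "mixed numeric and non-numeric values; pass an explicit kind override")
    return("categorical")
  }
  if (is.list(values)) {
    num <- vapply(values, is.numeric, logical(1))
    chr <- vapply(values, function(v) is.character(v) || is.logical(v), logical(1))
    if (all(num)) return("continuous")
    if (all(chr)) return("categorical")
    stop_kind("mixed numeric and non-numeric values; pass an explicit kind override")
  }
  stop_kind("cannot infer kind for this input type")
}

#' Points in a 2D coordinate system with named annotations
#'
#' The shared data model for all plotting and binning operations: point ids,
#' x/y coordinates (micrometres, full-resolution pixels, or embedding units)
#' and any number of aligned annotation columns. `coord_mode = "image"` marks
#' tables whose y axis increases downward (microscopy pixel convention, the
#' default for Visium-derived tables); rendering flips the axis, stored
#' coordinates are never mutated. Embeddings use `"cartesian"`.
#'
#' @param ids unique point identifiers (coerced to character).
#' @param x,y finite numeric coordinates.
#' @param coord_mode `"cartesian"` or `"image"`.
#' @param annotations named list: each element is an [annotation_column()] or
#'   a raw vector (kind inferred).
#' @return A validated object of class `point_table`.
#' @seealso [validate_point_table()], [attach_annotation()]
#' @export
point_table <- function(ids, x, y, coord_mode = c("cartesian", "image"),
                        annotations = list()) {
  coord_mode <- match.arg(coord_mode)
  ids <- as.character(ids)
  ann <- list()
  nm <- names(annotations)
  if (length(annotations) > 0 && (is.null(nm) || any(nm == ""))) {
    stop_validation("all annotation columns must be named")
  }
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    if (!inherits(a, "annotation_column")) a <- annotation_column(a, name = nm[i])
    a$name <- nm[i]
    ann[[nm[i]]] <- a
  }
  tab <- structure(
    list(ids = ids, x = as.double(x), y = as.double(y),
         coord_mode = coord_mode, annotations = ann),
    class = "point_table"
  )
  validate_point_table(tab)
}

#' Validate a point table
#'
#' Checks all invariants: unique ids, finite aligned coordinates, and every
#' annotation column aligned to the point count with legal values. Returns
#' the table unchanged when valid, so validation is idempotent.
#'
#' @param table a `point_table`.
#' @return `table`, unchanged.
#' @export
validate_point_table <- function(table) {
  if (!inherits(table, "point_table")) stop_validation("not a point_table")
  n <- length(table$ids)
  dup <- table$ids[duplicated(table$ids)]
  if (length(dup) > 0) {
    stop_duplicate(sprintf("duplicate point id: '%s'", dup[1]))
  }
  if (length(table$x) != n || length(table$y) != n) {
    stop_validation("coordinate vectors not aligned to point ids")
  }
  badx <- which(!is.finite(table$x))
  if (length(badx) > 0) stop_validation(
    sprintf("non-finite x coordinate at point id '%s'", table$ids[badx[1]]))
  bady <- which(!is.finite(table$y))
  if (length(bady) > 0) stop_validation(
    sprintf("non-finite y coordinate at point id '%s'", table$ids[bady[1]]))
  for (a in table$annotations) {
    if (length(a$values) != n || length(a$missing) != n) {
      stop_validation(sprintf("annotation column '%s' not aligned to point count", a$name))
    }
    if (a$kind == "continuous") {
      if (any(!is.finite(a$values) & !a$missing)) stop_validation(
        sprintf("column '%s': non-finite value outside the missing mask", a$name))
    } else {
      if (length(a$levels) == 0) stop_validation(
        sprintf("column '%s': empty level set", a$name))
      off <- !a$missing & !(a$values %in% a$levels)
      if (any(off)) stop_validation(
        sprintf("column '%s': value outside level set", a$name))
    }
  }
  table
}

#' Number of points in a table
#' @param x a `point_table`.
#' @param ... unused.
#' @return integer point count.
#' @export
length.point_table <- function(x) length(x$ids)

#' Look up an annotation column by name
#'
#' Lookup is total over declared names and fails loudly otherwise.
#'
#' @param table a `point_table`.
#' @param name annotation name.
#' @return the `annotation_column`.
#' @export
get_annotation <- function(table, name) {
  stopifnot(inherits(table, "point_table"))
  if (!name %in% names(table$annotations)) {
    stop_name(sprintf("no annotation named '%s' (available: %s)", name,
                      paste(names(table$annotations), collapse = ", ")))
  }
  table$annotations[[name]]
}

#' @export
print.point_table <- function(x, ...) {
  cat(sprintf("<point_table: %d points, coord_mode=%s>\n", length(x$ids), x$coord_mode))
  for (a in x$annotations) {
    extra <- if (a$kind == "categorical") sprintf(" (%d levels)", length(a$levels)) else ""
    cat(sprintf("  %s: %s%s, %d missing\n", a$name, a$kind, extra, sum(a$missing)))
  }
  invisible(x)
}

#' Convert a point table to a data.frame
#'
#' One row per point: `id`, `x`, `y`, then one column per annotation
#' (missing entries become `NA`).
#'
#' @param x a `point_table`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.point_table <- function(x, ...) {
  df <- data.frame(id = x$ids, x = x$x, y = x$y, stringsAsFactors = FALSE)
  for (a in x$annotations) {
    v <- a$values
    v[a$missing] <- NA
    df[[a$name]] <- v
  }
  df
}
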