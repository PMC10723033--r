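#' Read a delimited point table
#'
#' Reads a CSV/TSV with a header row into a [point_table()]. Every column
#' other than the id and coordinate columns is ingested as an annotation via
#' [infer_kind()] (empty cells become missing), unless overridden.
#'
#' @param path file path.
#' @param x_col,y_col,id_col column names for coordinates and point ids.
#' @param kind_overrides named character vector `column -> kind` forcing
#'   `"continuous"` or `"categorical"` (e.g. integer cluster ids).
#' @param coord_mode `"cartesian"` (embeddings) or `"image"` (pixel
#'   coordinates, y growing downward).
#' @param sep field separator; `","` by default, `"\t"` for TSV.
#' @return a validated `point_table`.
#' @export
read_points_csv <- function(path, x_col = "x", y_col = "y", id_col = "id",
                            kind_overrides = NULL,
                            coord_mode = c("cartesian", "image"), sep = ",") {
  coord_mode <- match.arg(coord_mode)
  if (!file.exists(path)) stop_io(sprintf("input file not found: '%s'", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = "", comment.char = "",
                          stringsAsFactors = FALSE)
  for (col in c(id_col, x_col, y_col)) {
    if (!col %in% names(df)) {
      stop_name(sprintf("column '%s' not found (available: %s)", col,
                        paste(names(df), collapse = ", ")))
    }
  }
  parse_coord <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop_format(sprintf("unparsable %s coordinate at data row %d: '%s'",
                          col, bad[1], raw[bad[1]]))
    }
    v
  }
  x <- parse_coord(x_col)
  y <- parse_coord(y_col)
  ann <- list()
  for (col in setdiff(names(df), c(id_col, x_col, y_col))) {
    raw <- df[[col]]
    kind <- if (!is.null(kind_overrides) && col %in% names(kind_overrides)) {
      kind_overrides[[col]]
    } else {
      infer_kind(raw)
    }
    vals <- if (kind == "continuous") suppressWarnings(as.numeric(raw)) else raw
    ann[[col]] <- annotation_column(vals, kind = kind, name = col)
  }
  point_table(ids = df[[id_col]], x = x, y = y, coord_mode = coord_mode,
              annotations = ann)
}

#' Write a point table as CSV
#'
#' Inverse of [read_points_csv()]: ids and labels round-trip exactly, real
#' coordinates and continuous values to within 1e-12 relative (15 significant
#' digits are written). Missing annotation values are written as empty cells.
#'
#' @param table a `point_table`.
#' @param path output path.
#' @param id_col,x_col,y_col header names to use.
#' @return the path, invisibly.
#' @export
write_points_csv <- function(table, path, id_col = "id",
                             x_col = "x", y_col = "y") {
  stopifnot(inherits(table, "point_table"))
  fmt_real <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "" else format(z, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")
    out
  }
  df <- data.frame(a = table$ids, b = fmt_real(table$x), c = fmt_real(table$y),
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, x_col, y_col)
  for (a in table$annotations) {
    v <- if (a$kind == "continuous") fmt_real(a$values) else a$values
    v[a$missing] <- ""
    df[[a$name]] <- v
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

VISIUM_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row_in_fullres", "pxl_col_in_fullres")

#' Read a 10x Visium tissue-positions file
#'
#' Accepts both Space Ranger dialects: the headerless
#' `tissue_positions_list.csv` and the headered `tissue_positions.csv`
#' (columns `barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,
#' pxl_col_in_fullres`); header presence does not change the result. The
#' full-resolution pixel coordinates become `x = pxl_col_in_fullres`,
#' `y = pxl_row_in_fullres` with `coord_mode = "image"`; `in_tissue` is kept
#' as a categorical annotation and `array_row`/`array_col` verbatim as
#' continuous annotations.
#'
#' @param path CSV path.
#' @param drop_out_of_tissue drop spots with `in_tissue == 0`?
#' @return a `point_table` keyed by barcode.
#' @export
read_visium_positions <- function(path, drop_out_of_tissue = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("input file not found: '%s'", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  df <- utils::read.table(path, header = has_header, sep = ",",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 6) {
    stop_format(sprintf("expected 6 columns in a tissue-positions file, found %d",
                        ncol(df)))
  }
  names(df) <- VISIUM_COLS
  if (!all(df$in_tissue %in% c("0", "1"))) {
    stop_format("in_tissue must be 0 or 1")
  }
  if (drop_out_of_tissue) df <- df[df$in_tissue == "1", , drop = FALSE]
  point_table(
    ids = df$barcode,
    x = as.numeric(df$pxl_col_in_fullres),
    y = as.numeric(df$pxl_row_in_fullres),
    coord_mode = "image",
    annotations = list(
      in_tissue = annotation_column(df$in_tissue, "categorical", "in_tissue"),
      array_row = annotation_column(as.numeric(df$array_row), "continuous", "array_row"),
      array_col = annotation_column(as.numeric(df$array_col), "continuous", "array_col")
    )
  )
}

#' Read one feature's expression from a Matrix Market triplet
#'
#' Loads a sparse genes-by-barcodes matrix (MTX coordinate format, as written
#' by Space Ranger / Cell Ranger) plus its `barcodes.tsv` and `features.tsv`
#' sidecars, and returns the expression of one feature keyed by barcode.
#' Entries absent from the sparse matrix are 0, the standard sparse-count
#' convention, not missing. `feature_name` is matched against the feature id
#' (first column) and, when present, the gene-symbol second column.
#'
#' @param matrix_path MTX file path.
#' @param barcodes_path one barcode per line.
#' @param features_path one feature per line (1-3 tab-separated columns).
#' @param feature_name feature id or symbol to extract.
#' @return named numeric vector `barcode -> value`.
#' @export
read_mtx_expression <- function(matrix_path, barcodes_path, features_path,
                                feature_name) {
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop_io(sprintf("input file not found: '%s'", p))
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop_format(
                  sprintf("cannot parse Matrix Market file '%s': %s",
                          matrix_path, conditionMessage(e))))
  barcodes <- readLines(barcodes_path)
  feat_lines <- readLines(features_path)
  if (nrow(m) != length(feat_lines)) {
    stop_format(sprintf("matrix has %d rows but features file has %d lines",
                        nrow(m), length(feat_lines)))
  }
  if (ncol(m) != length(barcodes)) {
    stop_format(sprintf("matrix has %d columns but barcodes file has %d lines",
                        ncol(m), length(barcodes)))
  }
  fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1)
  symbols <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else f[[1]], "")
  row <- which(ids == feature_name | symbols == feature_name)
  if (length(row) == 0) {
    stop_name(sprintf("feature '%s' not found among %d features",
                      feature_name, length(feat_lines)))
  }
  v <- as.numeric(m[row[1], ])
  names(v) <- barcodes
  v
}

#' Attach a keyed annotation to a point table
#'
#' Joins `mapping` onto the table by point id; ids absent from the mapping
#' become missing values.
#'
#' @param table a `point_table`.
#' @param mapping named vector `id -> value`.
#' @param name new annotation name (must not already exist).
#' @param kind `"continuous"`, `"categorical"`, or `NULL` to infer.
#' @return the updated `point_table`.
#' @export
attach_annotation <- function(table, mapping, name, kind = NULL) {
  stopifnot(inherits(table, "point_table"))
  if (name %in% names(table$annotations)) {
    stop_duplicate(sprintf("annotation '%s' already exists", name))
  }
  if (is.null(names(mapping))) stop_param("mapping must be named by point id")
  idx <- match(table$ids, names(mapping))
  if (is.null(kind)) kind <- infer_kind(unname(mapping))
  vals <- if (kind == "continuous") {
    v <- rep(NA_real_, length(table$ids))
    v[!is.na(idx)] <- as.numeric(mapping[idx[!is.na(idx)]])
    v
  } else {
    v <- rep(NA_character_, length(table$ids))
    v[!is.na(idx)] <- as.character(mapping[idx[!is.na(idx)]])
    v
  }
  table$annotations[[name]] <- annotation_column(vals, kind = kind, name = name)
  validate_point_table(table)
}
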