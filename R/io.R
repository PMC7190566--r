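#' Read and write rating-panel CSV files
#'
#' The panel CSV has a first column `object_id` followed by one column per
#' rater; cell values are exactly `TB`, `PDC` or `NEITHER` (empty cells are
#' allowed only for incomplete designs and read as `NA`). Parsing is
#' strict: unknown category tokens (including stray whitespace), duplicate
#' object ids and ragged rows are errors reported with their line numbers.
#'
#' @param path File path.
#' @param allow_incomplete Accept empty/NA cells.
#' @return `read_panel()`: a [rating_panel()] (zero-object when the file has
#'   a header only).
#' @export
read_panel <- function(path, allow_incomplete = FALSE) {
  fields <- count.fields(path, sep = ",", quote = "\"")
  if (length(fields) == 0L) stop("empty panel file: ", path)
  ragged <- which(fields != fields[1])
  if (length(ragged) > 0L) {
    stop("ragged row(s) in ", path, " at line(s) ",
         paste(ragged, collapse = ", "))
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df)[1], "object_id")) {
    stop("first column must be 'object_id'")
  }
  if (ncol(df) < 2L) stop("panel file has no rater columns")
  if (anyDuplicated(df$object_id)) {
    dup <- which(duplicated(df$object_id))
    stop("duplicate object id(s) at line(s) ",
         paste(dup + 1L, collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  bad <- which(!(m %in% RATING_CLASSES) & !is.na(m))
  if (length(bad) > 0L) {
    lines <- unique((bad - 1L) %% nrow(m) + 2L) # +1 header, +1 1-based
    stop("invalid rating token(s) ",
         paste(sQuote(unique(m[bad])), collapse = ", "),
         " at line(s) ", paste(sort(lines), collapse = ", "))
  }
  rownames(m) <- df$object_id
  rating_panel(m, allow_incomplete = allow_incomplete)
}

#' @rdname read_panel
#' @param panel A [rating_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  df <- data.frame(object_id = panel$object_ids,
                   panel$ratings, check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write candidate-object tables
#'
#' Candidate CSV columns: `object_id`, `tile_id`, `centroid_x_um`,
#' `centroid_y_um`, `area_um2`, `pixel_count`, `stratum`, `group`.
#' Numeric columns are written at full precision so a write/read round
#' trip is lossless.
#'
#' @param path File path.
#' @return `read_candidates()`: candidate data.frame.
#' @export
read_candidates <- function(path) {
  df <- read.csv(path, colClasses = c(
    object_id = "integer", tile_id = "character",
    centroid_x_um = "character", centroid_y_um = "character",
    area_um2 = "character", pixel_count = "integer",
    stratum = "character", group = "integer"))
  if (anyDuplicated(paste(df$tile_id, df$object_id))) {
    stop("duplicate object id(s) within a tile in ", path)
  }
  for (col in c("centroid_x_um", "centroid_y_um", "area_um2")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' @rdname read_candidates
#' @param objects Candidate data.frame.
#' @export
write_candidates <- function(objects, path) {
  cols <- c("object_id", "tile_id", "centroid_x_um", "centroid_y_um",
            "area_um2", "pixel_count", "stratum", "group")
  missing_cols <- setdiff(cols, names(objects))
  if (length(missing_cols) > 0L) {
    stop("candidate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- objects[, cols]
  for (col in c("centroid_x_um", "centroid_y_um", "area_um2")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write and read RGB tiles and label masks
#'
#' Tiles are written as 8-bit RGB PNG or TIFF (chosen by file extension);
#' intensities are quantized from the `[0, 255]` working scale. Label masks
#' are written as 16-bit single-channel TIFF.
#'
#' @param tile Numeric `h x w x 3` array on the 0-255 scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_tile <- function(tile, path) {
  # quantize to 8 bits here: the writers' own conversion may truncate
  q <- round(pmin(pmax(tile, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = 8L)
  } else {
    stop("unsupported tile format: .", ext)
  }
  invisible(path)
}

#' @rdname write_tile
#' @return `read_tile()`: numeric `h x w x 3` array on the 0-255 scale.
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
      stop("unsupported tile format: .", ext)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE] # drop alpha
  }
  img * 255
}

#' @rdname write_tile
#' @param label_mask Integer matrix (0 = background, k = object id; max
#'   65535).
#' @export
write_label_mask <- function(label_mask, path) {
  stopifnot(max(label_mask) <= 65535L)
  tiff::writeTIFF(label_mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tile
#' @return `read_label_mask()`: integer matrix of object ids.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Plain-text key/value configuration files
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Values parse to numeric vectors when every comma-separated
#' element is numeric, otherwise to character.
#'
#' @param path File path.
#' @return `read_config()`: named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (no '='): ", sQuote(ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) > 0 && !anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalars/vectors.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
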