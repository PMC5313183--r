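#' Read an Esri ASCII grid
#'
#' Parses the 6-line `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by a whitespace-separated body. The first body row is the
#' northernmost row, matching the matrix convention used throughout the
#' package (row 1 = north).
#'
#' @param path Path to a `.asc` file.
#' @return A matrix with attributes `cell_size`, `xllcorner`, `yllcorner`.
#'   `NODATA_value` cells are returned as `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  hdr <- numeric(6)
  for (i in seq_len(6)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L || tolower(parts[1]) != keys[i] ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed Esri ASCII header at line ", i, ": '", lines[i], "'")
    hdr[i] <- as.numeric(parts[2])
  }
  nc <- as.integer(hdr[1]); nr <- as.integer(hdr[2])
  if (nc < 1L || nr < 1L) stop("malformed Esri ASCII header: non-positive grid shape")
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != nc * nr)
    stop("body has ", length(body), " values; header promises ", nc * nr)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr[6]] <- NA_real_
  structure(m, cell_size = hdr[5], xllcorner = hdr[3], yllcorner = hdr[4])
}

#' Write an Esri ASCII grid
#'
#' @param x Numeric matrix, row 1 = northernmost row. `NA` written as the
#'   nodata value.
#' @param path Output path.
#' @param cell_size Cell size in metres.
#' @param xllcorner,yllcorner Lower-left corner coordinates.
#' @param nodata Value standing in for `NA`.
#' @param digits Significant digits written; the default 17 round-trips
#'   doubles exactly.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cell_size = 200, xllcorner = 0,
                             yllcorner = 0, nodata = -9999, digits = 17) {
  stopifnot(is.matrix(x))
  hdr <- c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", format(xllcorner, digits = digits)),
    paste("yllcorner", format(yllcorner, digits = digits)),
    paste("cellsize", format(cell_size, digits = digits)),
    paste("NODATA_value", nodata))
  x[is.na(x)] <- nodata
  rows <- apply(x, 1L, function(r)
    paste(sprintf("%.*g", digits, r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
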