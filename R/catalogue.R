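# Fire-catalogue CSV IO with invariant validation.

#' Write a fire catalogue to CSV
#'
#' @param catalogue A `fire_catalogue` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fire_catalogue <- function(catalogue, path) {
  utils::write.csv(catalogue, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a fire catalogue
#'
#' Requires columns `date`, `row`, `col`, `cause`, `size_ha` (`x`, `y` are
#' reconstructed from `row`/`col` if absent). Rows violating the event
#' invariants — non-positive or sub-minimum size, cell outside the grid,
#' unparseable or out-of-span date, unknown cause — are dropped with a
#' message reporting the counts; a clean file loses no rows.
#'
#' @param path CSV path.
#' @param n_rows,n_cols Grid shape for the cell-inside-grid check
#'   (optional).
#' @param date_range Length-2 character vector of ISO dates bounding the
#'   archive span (optional).
#' @param min_size Smallest valid fire size in ha.
#' @param cell_size Cell size in metres used to reconstruct `x`/`y`.
#' @return A validated `fire_catalogue`.
#' @export
read_fire_catalogue <- function(path, n_rows = NULL, n_cols = NULL,
                                date_range = NULL, min_size = 0.3,
                                cell_size = 200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "row", "col", "cause", "size_ha")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalogue missing column(s): ",
                         paste(miss, collapse = ", "))
  n0 <- nrow(df)
  drop <- rep(FALSE, n0); why <- character(0)
  bad <- is.na(df$size_ha) | df$size_ha < min_size
  if (any(bad)) why <- c(why, sprintf("%d with size below %g ha", sum(bad & !drop), min_size))
  drop <- drop | bad
  d <- as.Date(df$date)
  bad <- is.na(d)
  if (any(bad & !drop)) why <- c(why, sprintf("%d with unparseable date", sum(bad & !drop)))
  drop <- drop | bad
  if (!is.null(date_range)) {
    span <- as.Date(date_range)
    bad <- !is.na(d) & (d < span[1] | d > span[2])
    if (any(bad & !drop)) why <- c(why, sprintf("%d outside the archive span", sum(bad & !drop)))
    drop <- drop | bad
  }
  if (!is.null(n_rows)) {
    bad <- df$row < 1 | df$row > n_rows | df$col < 1 | df$col > n_cols
    if (any(bad & !drop)) why <- c(why, sprintf("%d outside the grid", sum(bad & !drop)))
    drop <- drop | bad
  }
  bad <- !df$cause %in% c("human", "lightning", "unknown")
  if (any(bad & !drop)) why <- c(why, sprintf("%d with unknown cause code", sum(bad & !drop)))
  drop <- drop | bad
  if (any(drop))
    message("dropped ", sum(drop), " of ", n0, " catalogue rows (",
            paste(why, collapse = "; "), ")")
  df <- df[!drop, , drop = FALSE]
  if (is.null(df$x) || is.null(df$y)) {
    if (is.null(n_rows))
      n_rows <- max(df$row)
    df$x <- (df$col - 0.5) * cell_size
    df$y <- (n_rows - df$row + 0.5) * cell_size
  }
  rownames(df) <- NULL
  class(df) <- c("fire_catalogue", "data.frame")
  df
}
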