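# Minimal ESRI ASCII grid raster container and I/O.

#' Construct a raster grid
#'
#' Row-major from the top row (row 1 = northernmost), as in ESRI ASCII
#' grids.
#'
#' @param values numeric matrix (nrows x ncols), `NA` for nodata.
#' @param xllcorner,yllcorner lower-left corner (degrees).
#' @param cellsize cell size (degrees).
#' @param nodata nodata value used on disk.
#' @return an `hg_raster`.
#' @export
new_raster <- function(values, xllcorner, yllcorner, cellsize,
                       nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) > 0, ncol(values) > 0,
            cellsize > 0)
  structure(list(ncols = ncol(values), nrows = nrow(values),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata, values = values),
            class = "hg_raster")
}

#' @export
print.hg_raster <- function(x, ...) {
  cat(sprintf("raster: %d x %d cells, cellsize %g, origin (%g, %g), %d valid\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner,
              sum(!is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Standard 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by whitespace-separated values, top row first.
#'
#' @param path file path.
#' @return an `hg_raster` with nodata cells as `NA`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) hg_stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    hg_stop("malformed ASCII grid header in ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr)
    hg_stop("expected ", nc * nr, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  new_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param r an `hg_raster`.
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", r$ncols),
               paste("nrows", r$nrows),
               paste("xllcorner", format(r$xllcorner, scientific = FALSE)),
               paste("yllcorner", format(r$yllcorner, scientific = FALSE)),
               paste("cellsize", format(r$cellsize, scientific = FALSE)),
               paste("NODATA_value", r$nodata)), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  for (i in seq_len(r$nrows))
    writeLines(paste(signif(m[i, ], digits), collapse = " "), con)
  invisible(path)
}

# centers of all cells: list of x (by col) and y (by row, top first)
raster_axes <- function(r) {
  list(x = r$xllcorner + (seq_len(r$ncols) - 0.5) * r$cellsize,
       y = r$yllcorner + (r$nrows - seq_len(r$nrows) + 0.5) * r$cellsize)
}

# (row, col) of lon/lat points; NA outside the extent
raster_cell <- function(r, lon, lat) {
  col <- floor((lon - r$xllcorner) / r$cellsize) + 1
  row <- r$nrows - floor((lat - r$yllcorner) / r$cellsize)
  bad <- col < 1 | col > r$ncols | row < 1 | row > r$nrows
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

# raster values at lon/lat points
raster_extract <- function(r, lon, lat) {
  rc <- raster_cell(r, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[rc[ok, , drop = FALSE]]
  out
}

same_grid <- function(a, b) {
  a$ncols == b$ncols && a$nrows == b$nrows &&
    isTRUE(all.equal(a$xllcorner, b$xllcorner)) &&
    isTRUE(all.equal(a$yllcorner, b$yllcorner)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize))
}
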