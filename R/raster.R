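#' Raster grid objects
#'
#' A `raster_grid` is the carrier for every map in the package: a numeric
#' matrix of cell values on a regular projected grid, together with the cell
#' size in metres. Nodata cells (land, outside a species' depth range, ...)
#' are stored as `NA`. Row 1 is the northern edge; distances between cell
#' centres are Euclidean in projected metres.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param cell_size Cell edge length in metres (single positive number).
#' @return An object of class `raster_grid`: a list with elements `values`
#'   and `cell_size`.
#' @examples
#' g <- raster_grid(matrix(runif(16), 4, 4), cell_size = 250)
#' dim(g)
#' @export
raster_grid <- function(values, cell_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  structure(list(values = values, cell_size = as.numeric(cell_size)),
            class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g m\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  nodata cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  value range: [%g, %g]\n", min(fin), max(fin)))
  invisible(x)
}

#' @rdname raster_grid
#' @param x Object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

# Abort unless two grids share shape and cell size.
check_congruent <- function(a, b, what = c("a", "b")) {
  if (!is_raster_grid(a) || !is_raster_grid(b))
    stop("both inputs must be raster_grid objects", call. = FALSE)
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("grids `%s` (%dx%d) and `%s` (%dx%d) differ in shape",
                 what[1], nrow(a$values), ncol(a$values),
                 what[2], nrow(b$values), ncol(b$values)), call. = FALSE)
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)))
    stop(sprintf("grids `%s` and `%s` differ in cell size (%g vs %g m)",
                 what[1], what[2], a$cell_size, b$cell_size), call. = FALSE)
  invisible(TRUE)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Grids are serialized in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by one whitespace-separated row of cell values
#' per raster row, north row first. The format is plain text and readable by
#' standard GIS software. Values round-trip exactly: cells are written with
#' `format(..., digits = 17)` so `read_raster(write_raster(g))` reproduces
#' `g` bit for bit, and nodata cells survive as nodata.
#'
#' @param path File path of the `.asc` file.
#' @param grid A [raster_grid()].
#' @param nodata Sentinel value written for `NA` cells (default -9999).
#' @return `read_raster` returns a [raster_grid()]; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete in ", path, call. = FALSE)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d", length(body),
                 nr * nc), call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, cell_size = hdr$cellsize)
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  if (!is_raster_grid(grid)) stop("`grid` must be a raster_grid", call. = FALSE)
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel value ", nodata, call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format(grid$cell_size, digits = 17)),
    sprintf("NODATA_value %s", format(nodata, digits = 17))
  )
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
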