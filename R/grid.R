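#' Define a regular analysis grid
#'
#' All rasters in the package are plain numeric matrices indexed `[row, col]`
#' with row 1 at the top (north) edge, on a shared 30 m grid described by a
#' `grid_spec`. Cell centers sit at `origin + (index - 0.5) * cell_size_m`,
#' with x increasing eastward along columns and y increasing northward, so the
#' center of cell `[r, c]` is at
#' `(origin_x + (c - 0.5) * cell, origin_y + (n_rows - r + 0.5) * cell)`.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size_m Cell edge length in meters; 30 m matches the analysis
#'   resolution throughout.
#' @param origin_x,origin_y Projected coordinates (m) of the lower-left grid
#'   corner.
#' @return An object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `cell_size_m`, `origin_x`, `origin_y` and `cell_area_m2` (= cell size
#'   squared, 900 m2 at the default resolution).
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_m = 30,
                      origin_x = 0, origin_y = 0) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (!is.finite(cell_size_m) || cell_size_m <= 0) {
    stop("cell_size_m must be positive", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size_m = cell_size_m,
         origin_x = origin_x, origin_y = origin_y,
         cell_area_m2 = cell_size_m^2),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m (%g m2/cell)\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$cell_area_m2))
  invisible(x)
}

#' Projected coordinates of every cell center
#'
#' @param spec A [grid_spec()].
#' @return A list with matrices `x` and `y` (same shape as the grid).
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  cs <- spec$cell_size_m
  x <- matrix(spec$origin_x + (seq_len(spec$n_cols) - 0.5) * cs,
              spec$n_rows, spec$n_cols, byrow = TRUE)
  y <- matrix(spec$origin_y + (spec$n_rows - seq_len(spec$n_rows) + 0.5) * cs,
              spec$n_rows, spec$n_cols)
  list(x = x, y = y)
}

check_layer <- function(layer, spec) {
  if (!is.matrix(layer) || nrow(layer) != spec$n_rows ||
      ncol(layer) != spec$n_cols) {
    stop("layer does not match the grid spec", call. = FALSE)
  }
  invisible(layer)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange. NA cells are written as the
#' nodata value.
#'
#' @param layer Numeric matrix.
#' @param spec [grid_spec()] describing the layer.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Value used to encode NA.
#' @export
write_ascii_grid <- function(layer, spec, path, nodata = -9999) {
  check_layer(layer, spec)
  header <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y),
    sprintf("cellsize %.10g", spec$cell_size_m),
    sprintf("NODATA_value %.10g", nodata)
  )
  vals <- layer
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1L, function(row) paste(format(row, digits = 10, trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming .asc).
#' @return A list with `layer` (matrix, nodata as NA) and `spec`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  layer <- do.call(rbind, vals)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) layer[layer == nodata] <- NA_real_
  spec <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                    hdr$xllcorner, hdr$yllcorner)
  list(layer = layer, spec = spec)
}

#' Write a named list of raster layers
#'
#' One ASCII grid per layer; the layer name becomes the file stem.
#'
#' @param stack Named list of matrices on a common grid.
#' @param spec [grid_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_stack <- function(stack, spec, dir) {
  stopifnot(length(names(stack)) == length(stack))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack), function(nm) {
    write_ascii_grid(stack[[nm]], spec, file.path(dir, paste0(nm, ".asc")))
  }, character(1))
  invisible(paths)
}

# Shrinking odd-window bounds helper shared by the moving-window routines.
window_bounds <- function(center, half, n) {
  lo <- max(1L, center - half)
  hi <- min(n, center + half)
  c(lo, hi)
}
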