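# Minimal lon/lat raster container. All grids are WGS84 geographic,
# square cells, row-major from the northwest corner (row 1 = northernmost).
# Missing cells are held as NA internally; the nodata sentinel only appears
# on disk.

#' Construct a raster grid
#'
#' A `raster_grid` is a numeric matrix of cell values plus its georeference:
#' the longitude of the west edge, the latitude of the north edge, and a
#' square cell size in decimal degrees. Row 1 is the northernmost row
#' (the usual image/GeoTIFF convention). Cells carrying the nodata sentinel
#' are stored as `NA`.
#'
#' @param values numeric matrix, `n_rows x n_cols`, row 1 = north.
#' @param west longitude of the western grid edge (degrees).
#' @param north latitude of the northern grid edge (degrees).
#' @param cell_size cell edge length in degrees (cells are square).
#' @param nodata sentinel written to disk for missing cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, west, north, cell_size, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(west), is.numeric(north), cell_size > 0)
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(is.infinite(values))) {
    stop("raster values must be finite or nodata")
  }
  structure(
    list(values = values, west = as.numeric(west), north = as.numeric(north),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d rows x %d cols, cell %.6g deg\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              x$west, x$west + ncol(x$values) * x$cell_size,
              x$north - nrow(x$values) * x$cell_size, x$north))
  cat(sprintf("  values: min %.4g, max %.4g, NA cells %d\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

grid_nrow <- function(grid) nrow(grid$values)
grid_ncol <- function(grid) ncol(grid$values)
grid_south <- function(grid) grid$north - grid_nrow(grid) * grid$cell_size
grid_east <- function(grid) grid$west + grid_ncol(grid) * grid$cell_size

#' Cell-center coordinates of a grid
#'
#' @param grid a `raster_grid`.
#' @return list with `lon` (length `n_cols`) and `lat` (length `n_rows`,
#'   north to south) of cell centers.
#' @export
cell_centers <- function(grid) {
  cs <- grid$cell_size
  list(
    lon = grid$west + (seq_len(grid_ncol(grid)) - 0.5) * cs,
    lat = grid$north - (seq_len(grid_nrow(grid)) - 0.5) * cs
  )
}

same_geometry <- function(a, b, tol = 1e-9) {
  grid_nrow(a) == grid_nrow(b) && grid_ncol(a) == grid_ncol(b) &&
    abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Bundle co-registered raster layers into a stack
#'
#' All layers must share geometry (rows, cols, origin, cell size) and carry
#' unique names. The canonical bioclim role names used throughout the
#' pipeline are BIO2, BIO4, BIO5, BIO6, BIO12, BIO15, BIO18 and BIO19.
#'
#' @param layers named list of `raster_grid` objects.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("raster_stack layers must carry unique names")
  }
  for (l in layers) {
    if (!inherits(l, "raster_grid")) stop("every layer must be a raster_grid")
    if (!same_geometry(l, layers[[1]])) {
      stop("all layers in a stack must share identical geometry")
    }
  }
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack with %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$layers[[1]])
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' Read a raster grid from disk
#'
#' Only the ESRI ASCII grid format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by row-major values from the
#' northwest corner) is supported; the whole pipeline works in this plain
#' text format.
#'
#' @param path file to read.
#' @param format raster format; only `"ascii_grid"` is supported.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF input is not supported; convert to ESRI ASCII grid")
  }
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("malformed ESRI ASCII header record: ", lines[i])
    hdr[[key]] <- val
    i <- i + 1
  }
  req <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss)) {
    stop("ESRI ASCII header missing required field(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(hdr$dy) || (!is.null(hdr$dx) && is.null(hdr$cellsize))) {
    stop("non-square cells are not supported")
  }
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    west <- hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    west <- hdr$xllcenter - cs / 2
  } else stop("ESRI ASCII header missing xllcorner/xllcenter")
  if (!is.null(hdr$yllcorner)) {
    south <- hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    south <- hdr$yllcenter - cs / 2
  } else stop("ESRI ASCII header missing yllcorner/yllcenter")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- suppressWarnings(as.numeric(scan(
    text = paste(lines[seq(i, length(lines))], collapse = "\n"),
    what = double(), quiet = TRUE
  )))
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("ESRI ASCII body has %d values, expected %d (nrows*ncols)",
                 length(vals), n_rows * n_cols))
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  raster_grid(m, west = west, north = south + n_rows * cs,
              cell_size = cs, nodata = nodata)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  hdr <- c(
    sprintf("ncols %d", grid_ncol(grid)),
    sprintf("nrows %d", grid_nrow(grid)),
    sprintf("xllcorner %.10g", grid$west),
    sprintf("yllcorner %.10g", grid_south(grid)),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  body <- apply(vals, 1, function(r) paste(format(r, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a raster stack from a directory of ESRI ASCII grids
#'
#' Expects files named `<layer>.asc`.
#'
#' @param dir directory containing the layer files.
#' @param layers layer names to read; defaults to every `.asc` file found.
#' @return a `raster_stack`.
#' @export
read_stack <- function(dir, layers = NULL) {
  if (is.null(layers)) {
    layers <- sub("\\.asc$", "", sort(list.files(dir, pattern = "\\.asc$")))
  }
  if (!length(layers)) stop("no .asc layers found in ", dir)
  lst <- lapply(layers, function(nm) read_raster(file.path(dir, paste0(nm, ".asc"))))
  names(lst) <- layers
  raster_stack(lst)
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' @param stack a `raster_stack`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    write_raster(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
    file.path(dir, paste0(nm, ".asc"))
  }, character(1))
  invisible(paths)
}

# Point -> (row, col) under the half-open cell convention
# [west, west + cs) x (south, south + cs]; equivalently nearest cell with
# the northern/western edges resolved consistently. Returns NA for points
# outside the extent.
point_cell <- function(grid, lon, lat) {
  cs <- grid$cell_size
  col <- floor((lon - grid$west) / cs) + 1
  row <- floor((grid$north - lat) / cs) + 1
  bad <- col < 1 | col > grid_ncol(grid) | row < 1 | row > grid_nrow(grid)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract climate values at occurrence points
#'
#' Each point takes the value of the grid cell containing it (no
#' interpolation). Points falling outside the extent, or on a nodata cell
#' in any layer, are dropped and counted.
#'
#' @param stack a `raster_stack`.
#' @param points an occurrence `data.frame` with columns `lon`, `lat`,
#'   `label` (see [read_occurrences()]).
#' @return object of class `climate_matrix`: list with `values` (retained
#'   points x layers), `labels`, `lon`, `lat` and `dropped_count`.
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "raster_stack"))
  stopifnot(all(c("lon", "lat", "label") %in% names(points)))
  g1 <- stack$layers[[1]]
  rc <- point_cell(g1, points$lon, points$lat)
  n <- nrow(points)
  vals <- matrix(NA_real_, nrow = n, ncol = length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  inside <- !is.na(rc$row)
  if (any(inside)) {
    idx <- cbind(rc$row[inside], rc$col[inside])
    for (j in seq_along(stack$layers)) {
      vals[inside, j] <- stack$layers[[j]]$values[idx]
    }
  }
  keep <- inside & !apply(vals, 1, anyNA)
  if (!any(keep)) stop("all points were dropped (out of extent or nodata)")
  structure(
    list(values = vals[keep, , drop = FALSE],
         labels = as.character(points$label)[keep],
         lon = points$lon[keep], lat = points$lat[keep],
         dropped_count = sum(!keep)),
    class = "climate_matrix"
  )
}

#' Geodesic area of the cells in one grid row
#'
#' Uses the spherical-quadrilateral area R^2 * d_lambda *
#' (sin(phi_top) - sin(phi_bottom)) with R = 6,371,000 m; at 35 degrees
#' of latitude this is about 18% smaller than the equatorial cell, a
#' difference the nominal "~1 km^2 per 30-arc-second cell" figure hides.
#'
#' @param grid a `raster_grid`.
#' @param row_index row number(s), 1 = northernmost.
#' @param flat_area if non-`NULL`, a constant per-cell area in hectares that
#'   overrides the geodesic computation (useful to mimic a flat-area
#'   convention exactly).
#' @return area in hectares of a single cell in each requested row.
#' @export
cell_area_ha <- function(grid, row_index, flat_area = NULL) {
  stopifnot(all(row_index >= 1), all(row_index <= grid_nrow(grid)))
  if (!is.null(flat_area)) return(rep(as.numeric(flat_area), length(row_index)))
  R <- 6371000
  cs <- grid$cell_size * pi / 180
  phi_top <- (grid$north - (row_index - 1) * grid$cell_size) * pi / 180
  phi_bot <- phi_top - cs
  area_m2 <- R^2 * cs * (sin(phi_top) - sin(phi_bot))
  area_m2 / 1e4
}

# Per-cell area matrix matching grid geometry (ha).
cell_area_matrix <- function(grid, flat_area = NULL) {
  row_areas <- cell_area_ha(grid, seq_len(grid_nrow(grid)), flat_area = flat_area)
  matrix(row_areas, nrow = grid_nrow(grid), ncol = grid_ncol(grid))
}

#' Crop a stack to a lon/lat rectangle
#'
#' Keeps exactly the cells whose centers lie inside the bounding box.
#'
#' @param stack a `raster_stack`.
#' @param bbox numeric `c(west, east, south, north)` in degrees.
#' @return the cropped `raster_stack`.
#' @export
crop <- function(stack, bbox) {
  stopifnot(inherits(stack, "raster_stack"), length(bbox) == 4)
  g <- stack$layers[[1]]
  ctr <- cell_centers(g)
  keep_col <- which(ctr$lon >= bbox[1] & ctr$lon <= bbox[2])
  keep_row <- which(ctr$lat >= bbox[3] & ctr$lat <= bbox[4])
  if (!length(keep_col) || !length(keep_row)) {
    stop("crop bbox does not intersect the stack extent")
  }
  cs <- g$cell_size
  new_west <- g$west + (min(keep_col) - 1) * cs
  new_north <- g$north - (min(keep_row) - 1) * cs
  raster_stack(lapply(stack$layers, function(l) {
    raster_grid(l$values[keep_row, keep_col, drop = FALSE],
                west = new_west, north = new_north, cell_size = cs,
                nodata = l$nodata)
  }))
}

#' Read occurrence points from CSV
#'
#' Expects a header `lon,lat,label` with labels `presence` or `background`.
#'
#' @param path CSV file.
#' @return `data.frame` with columns `lon`, `lat`, `label`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "label")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have header lon,lat,label")
  }
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)) {
    stop("occurrence coordinates outside valid lon/lat ranges")
  }
  if (!all(df$label %in% c("presence", "background"))) {
    stop("occurrence labels must be 'presence' or 'background'")
  }
  df[need]
}

#' Write occurrence points to CSV
#'
#' @param points occurrence `data.frame` (`lon`, `lat`, `label`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(points, path) {
  utils::write.csv(points[c("lon", "lat", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
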