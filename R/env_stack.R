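#' Environmental raster stack
#'
#' An `env_stack` holds a set of co-registered gridded environmental layers
#' over a shared geographic extent, together with a validity mask and a
#' per-layer kind (continuous or categorical).  Grids are stored as plain
#' matrices with row 1 at the northern edge (row-major from the NW corner),
#' on a regular lon/lat grid in decimal degrees (WGS84).
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions.  Categorical layers must hold integer codes.
#' @param extent numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees.
#' @param res cell size in degrees (one value, square cells).  Default
#'   1/120 degree (30 arc-seconds).
#' @param kind character vector, one of `"continuous"` or `"categorical"`
#'   per layer; recycled if length 1.
#' @param mask optional logical matrix of valid cells; defaults to cells
#'   that are non-`NA` in every layer.
#' @param cartesian logical; if `TRUE` cell areas are taken as 1 (unit
#'   cells, no geodesy).  Used for synthetic landscapes where exact
#'   pixel-count arithmetic is wanted.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, extent, res = 1 / 120, kind = "continuous",
                      mask = NULL, cartesian = FALSE) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L)
    stop("alignment error: layers have differing dimensions")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("extent must be c(lon_min, lon_max, lat_min, lat_max) with min < max")
  if (abs((extent[2] - extent[1]) / res - nc) > 1e-6 ||
      abs((extent[4] - extent[3]) / res - nr) > 1e-6)
    stop("alignment error: extent and resolution inconsistent with grid shape")
  kind <- rep_len(match.arg(kind, c("continuous", "categorical"),
                            several.ok = TRUE), length(layers))
  names(kind) <- names(layers)
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  }
  stopifnot(is.logical(mask), all(dim(mask) == c(nr, nc)))
  for (i in seq_along(layers)) {
    v <- layers[[i]][mask]
    if (kind[i] == "categorical") {
      if (any(is.finite(v) & v != round(v)))
        stop("categorical layer '", names(layers)[i], "' has non-integer codes")
    } else if (any(!is.finite(v))) {
      stop("continuous layer '", names(layers)[i],
           "' has non-finite values on masked-in cells")
    }
  }
  structure(list(layers = layers, extent = extent, res = res, kind = kind,
                 mask = mask, crs = "WGS84 geographic",
                 cartesian = isTRUE(cartesian)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat("env_stack: ", length(x$layers), " layer(s), ", d[1], " x ", d[2],
      " cells\n", sep = "")
  cat("  extent: lon [", x$extent[1], ", ", x$extent[2], "], lat [",
      x$extent[3], ", ", x$extent[4], "], res ", signif(x$res, 6),
      if (x$cartesian) " (cartesian areas)" else "", "\n", sep = "")
  cat("  layers:", paste0(names(x$layers), " (", substr(x$kind, 1, 4), ")",
                          collapse = ", "), "\n")
  cat("  mask:", sum(x$mask), "of", length(x$mask), "cells valid\n")
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]])

n_layers <- function(stack) length(stack$layers)

#' Cell indices of lon/lat points
#'
#' Maps points to grid cells with the row-major-from-NW convention: column
#' `floor((lon - lon_min)/res) + 1`, row `floor((lat_max - lat)/res) + 1`,
#' half-open intervals `[edge, edge + res)`; points exactly on the max edge
#' belong to the last cell.
#'
#' @param stack an `env_stack` (or list with `extent` and `res`).
#' @param lon,lat numeric vectors of coordinates.
#' @return integer matrix with columns `row`, `col`; `NA` for points
#'   outside the extent.
#' @export
cell_index <- function(stack, lon, lat) {
  ex <- stack$extent; res <- stack$res
  d <- dim(stack$layers[[1]])
  col <- floor((lon - ex[1]) / res) + 1L
  row <- floor((ex[4] - lat) / res) + 1L
  # points on the max edge belong to the last cell
  col[lon == ex[2]] <- d[2]
  row[lat == ex[3]] <- d[1]
  out <- lon < ex[1] | lon > ex[2] | lat < ex[3] | lat > ex[4]
  col[out] <- NA_integer_; row[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Latitudes of cell centres per grid row
#' @keywords internal
row_lats <- function(stack) {
  nr <- dim(stack$layers[[1]])[1]
  stack$extent[4] - (seq_len(nr) - 0.5) * stack$res
}

#' Spherical cell area
#'
#' Area in km^2 of a grid cell of width `resolution` degrees centred at
#' latitude `lat`, on a sphere of radius 6371 km:
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`.
#'
#' @param lat cell-centre latitude(s), degrees; `|lat| <= 90`.
#' @param resolution cell size in degrees (default 1/120, 30 arc-seconds).
#' @return numeric vector of areas in km^2.
#' @export
pixel_area <- function(lat, resolution = 1 / 120) {
  stopifnot(all(abs(lat) <= 90))
  R <- 6371
  top <- pmin(lat + resolution / 2, 90) * pi / 180
  bot <- pmax(lat - resolution / 2, -90) * pi / 180
  R^2 * (resolution * pi / 180) * (sin(top) - sin(bot))
}

#' Per-cell areas of a stack
#'
#' Returns a matrix of cell areas (km^2, spherical formula at the cell-centre
#' latitude of each grid row), or unit areas when the stack is Cartesian.
#'
#' @param stack an `env_stack`.
#' @return numeric matrix of the grid shape.
#' @export
cell_areas <- function(stack) {
  d <- dim(stack$layers[[1]])
  if (stack$cartesian) return(matrix(1, d[1], d[2]))
  matrix(pixel_area(row_lats(stack), stack$res), d[1], d[2])
}

#' Crop a stack to an extent
#'
#' The requested bounds are snapped outward to cell edges of the source grid,
#' so the returned stack covers (at least) the intersection of the two
#' extents.
#'
#' @param stack an `env_stack`.
#' @param extent numeric `c(lon_min, lon_max, lat_min, lat_max)` or an
#'   [extent_config()].
#' @return a cropped `env_stack`.
#' @export
crop_extent <- function(stack, extent) {
  if (inherits(extent, "extent_config"))
    extent <- c(extent$lon_min, extent$lon_max, extent$lat_min, extent$lat_max)
  ex <- stack$extent; res <- stack$res
  d <- dim(stack$layers[[1]])
  lo_lon <- max(extent[1], ex[1]); hi_lon <- min(extent[2], ex[2])
  lo_lat <- max(extent[3], ex[3]); hi_lat <- min(extent[4], ex[4])
  if (lo_lon >= hi_lon || lo_lat >= hi_lat)
    stop("extent error: empty intersection with stack extent")
  eps <- 1e-9
  c0 <- floor((lo_lon - ex[1]) / res + eps) + 1L
  c1 <- ceiling((hi_lon - ex[1]) / res - eps)
  r0 <- floor((ex[4] - hi_lat) / res + eps) + 1L
  r1 <- ceiling((ex[4] - lo_lat) / res - eps)
  c0 <- max(c0, 1L); c1 <- min(c1, d[2]); r0 <- max(r0, 1L); r1 <- min(r1, d[1])
  new_ext <- c(ex[1] + (c0 - 1L) * res, ex[1] + c1 * res,
               ex[4] - r1 * res, ex[4] - (r0 - 1L) * res)
  layers <- lapply(stack$layers, function(m) m[r0:r1, c0:c1, drop = FALSE])
  env_stack(layers, new_ext, res = res, kind = stack$kind,
            mask = stack$mask[r0:r1, c0:c1, drop = FALSE],
            cartesian = stack$cartesian)
}

#' Study extent configuration
#'
#' Default bounds cover the New Zealand landmass (latitudes -49 to -32,
#' longitudes 165 to 180).
#'
#' @param lat_min,lat_max,lon_min,lon_max extent bounds in decimal degrees.
#' @return an object of class `extent_config`.
#' @export
extent_config <- function(lat_min = -49, lat_max = -32,
                          lon_min = 165, lon_max = 180) {
  if (!(lat_min < lat_max && lon_min < lon_max))
    stop("extent bounds must satisfy lat_min < lat_max and lon_min < lon_max")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "extent_config")
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return list with `data` (matrix, row 1 = north, `NA` for nodata),
#'   `extent`, `res`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  res <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    x0 <- hdr$xllcorner; y0 <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    x0 <- hdr$xllcenter - res / 2; y0 <- hdr$yllcenter - res / 2
  } else stop("ESRI ASCII header lacks corner coordinates in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII data size mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(data = m, extent = c(x0, x0 + nc * res, y0, y0 + nr * res), res = res)
}

#' Write an ESRI ASCII grid
#'
#' @param m matrix (row 1 = north); `NA` written as the nodata value.
#' @param path output path.
#' @param extent,res grid georeference.
#' @param nodata nodata sentinel (default -9999).
#' @export
write_ascii_grid <- function(m, path, extent, res, nodata = -9999) {
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(extent[1], digits = 12)),
           paste("yllcorner", format(extent[3], digits = 12)),
           paste("cellsize", format(res, digits = 12)),
           paste("NODATA_value", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a stack of ESRI ASCII rasters
#'
#' All files must be coextensive (same extent, resolution, and shape); the
#' union of per-layer nodata cells becomes the stack mask.
#'
#' @param paths character vector of raster files; layer names are taken
#'   from `names(paths)` or file basenames.
#' @param kinds per-layer kind, `"continuous"` or `"categorical"`
#'   (recycled).
#' @param cartesian see [env_stack()].
#' @return an `env_stack`.
#' @export
read_env_stack <- function(paths, kinds = "continuous", cartesian = FALSE) {
  stopifnot(length(paths) >= 1)
  grids <- lapply(paths, read_ascii_grid)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (any(abs(g$extent - ref$extent) > 1e-6) || abs(g$res - ref$res) > 1e-9 ||
        any(dim(g$data) != dim(ref$data)))
      stop("alignment error: rasters are not coextensive")
  }
  nms <- names(paths)
  if (is.null(nms) || any(nms == ""))
    nms <- sub("\\.[^.]*$", "", basename(paths))
  layers <- stats::setNames(lapply(grids, `[[`, "data"), nms)
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  kinds <- rep_len(kinds, length(layers))
  # categorical codes survive the nodata round-trip as integers
  env_stack(layers, ref$extent, res = ref$res, kind = kinds, mask = mask,
            cartesian = cartesian)
}

#' Write every layer of a stack as ESRI ASCII grids
#' @param stack an `env_stack`.
#' @param dir output directory (created if missing).
#' @return invisible character vector of file paths.
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    m <- stack$layers[[nm]]
    m[!stack$mask] <- NA
    write_ascii_grid(m, file.path(dir, paste0(nm, ".asc")),
                     stack$extent, stack$res)
  }, character(1))
  invisible(paths)
}
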