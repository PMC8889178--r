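#' Read an occurrence table
#'
#' Expects a CSV with header `species,lon,lat,presence,source` (source is
#' optional), coordinates in WGS84 decimal degrees, presence coded 0/1.
#'
#' @param path CSV file path.
#' @return a data.frame with columns species, lon, lat, presence, source.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "presence")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns ", paste(need, collapse = ", "))
  if (is.null(df$source)) df$source <- ""
  if (!all(df$presence %in% c(0, 1))) stop("presence must be coded 0/1")
  df[c("species", "lon", "lat", "presence", "source")]
}

# round half away from zero, stable across platforms
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Filter an occurrence compilation
#'
#' Reduces coordinates to two decimal places (half away from zero), drops
#' within-species duplicate (lon, lat, presence) rows so that each species
#' keeps at most one record per ~1 km^2, resolves presence/absence conflicts
#' at the same rounded location in favour of presence, and removes records
#' outside the configured extent.
#'
#' @param raw occurrence data.frame (see [read_occurrences()]).
#' @param extent optional [extent_config()] or `c(lon_min, lon_max,
#'   lat_min, lat_max)`; rows outside it are removed and counted.
#' @param digits decimal places kept (default 2).
#' @return the filtered data.frame, with a `"filter_report"` attribute
#'   listing counts of rows in, duplicates removed, conflicts resolved,
#'   out-of-extent removals, and rows out.
#' @export
filter_occurrences <- function(raw, extent = NULL, digits = 2) {
  stopifnot(all(c("species", "lon", "lat", "presence") %in% names(raw)))
  n_in <- nrow(raw)
  df <- raw
  df$lon <- round_away(df$lon, digits)
  df$lat <- round_away(df$lat, digits)
  n_outside <- 0L
  if (!is.null(extent)) {
    if (inherits(extent, "extent_config"))
      extent <- c(extent$lon_min, extent$lon_max, extent$lat_min, extent$lat_max)
    keep <- df$lon >= extent[1] & df$lon <= extent[2] &
      df$lat >= extent[3] & df$lat <= extent[4]
    n_outside <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  key <- paste(df$species, df$lon, df$lat, df$presence, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  # presence wins over absence at the same rounded location
  loc <- paste(df$species, df$lon, df$lat, sep = "\r")
  pres_loc <- unique(loc[df$presence == 1])
  conflict <- df$presence == 0 & loc %in% pres_loc
  n_conflict <- sum(conflict)
  df <- df[!conflict, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "filter_report") <- list(
    n_in = n_in, n_duplicates = n_dup, n_conflicts = n_conflict,
    n_outside_extent = n_outside, n_out = nrow(df))
  df
}

#' Derive absences for a target species from a multi-species compilation
#'
#' Locations where other species in the compilation were recorded (together
#' with any explicit absences of the target) act as surveyed sites; each
#' grid cell among them that contains no target presence contributes one
#' absence, placed at the cell centre.  Returns target presences plus these
#' derived absences.
#'
#' @param records filtered occurrence table (see [filter_occurrences()]).
#' @param target species label to model.
#' @param stack `env_stack` whose grid defines the cells.
#' @return occurrence data.frame of target presences (original coordinates)
#'   and derived absences (cell-centre coordinates, source
#'   `"derived absence"`).
#' @export
derive_absences <- function(records, target, stack) {
  if (!target %in% records$species)
    stop("unknown species: ", target)
  pres <- records[records$species == target & records$presence == 1, ,
                  drop = FALSE]
  donors <- records[(records$species != target & records$presence == 1) |
                    (records$species == target & records$presence == 0), ,
                    drop = FALSE]
  pc <- cell_index(stack, pres$lon, pres$lat)
  dc <- cell_index(stack, donors$lon, donors$lat)
  pres_cells <- unique(stats::na.omit(pc[, "row"] * 1e7 + pc[, "col"]))
  don_key <- dc[, "row"] * 1e7 + dc[, "col"]
  keep <- !is.na(don_key) & !(don_key %in% pres_cells) & !duplicated(don_key)
  dc <- dc[keep, , drop = FALSE]
  abs_lon <- stack$extent[1] + (dc[, "col"] - 0.5) * stack$res
  abs_lat <- stack$extent[4] - (dc[, "row"] - 0.5) * stack$res
  out <- rbind(
    data.frame(species = target, lon = pres$lon, lat = pres$lat,
               presence = 1, source = pres$source,
               stringsAsFactors = FALSE),
    if (nrow(dc) > 0)
      data.frame(species = target, lon = abs_lon, lat = abs_lat,
                 presence = 0, source = "derived absence",
                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Extract covariates at occurrence points
#'
#' Looks up each record's containing grid cell and returns the per-layer
#' values there as a design data.frame (categorical layers as factors),
#' together with the response.  Records falling on masked-out cells are
#' dropped with a warning.
#'
#' @param stack an `env_stack`.
#' @param table occurrence data.frame with lon, lat, presence.
#' @return list with `X` (data.frame), `y` (integer 0/1), `cells` (row/col
#'   matrix), `dropped` (count of masked-out records).
#' @export
extract_covariates <- function(stack, table) {
  idx <- cell_index(stack, table$lon, table$lat)
  inside <- !is.na(idx[, "row"])
  ok <- inside
  lin <- idx[, "row"] + (idx[, "col"] - 1L) * dim(stack$layers[[1]])[1]
  ok[inside] <- stack$mask[lin[inside]]
  n_drop <- sum(!ok)
  if (all(!ok)) stop("empty-design error: all points are masked out or outside")
  if (n_drop > 0)
    warning(n_drop, " record(s) on masked-out or outside cells dropped")
  lin <- lin[ok]
  X <- as.data.frame(lapply(stack$layers, function(m) m[lin]))
  for (nm in names(stack$layers)) {
    if (stack$kind[nm] == "categorical") X[[nm]] <- factor(X[[nm]])
  }
  list(X = X, y = as.integer(table$presence[ok]),
       cells = idx[ok, , drop = FALSE], dropped = n_drop)
}
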