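#' Label habitat patches in a binary map
#'
#' Connected-component labelling of habitat (value 1) pixels.  Labels are
#' assigned in deterministic order: patch 1 contains the first habitat
#' pixel in row-major order from the NW corner, and so on.
#'
#' @param binary 0/1 matrix (`NA` = off-mask, treated as background).
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return a `patch_set`: list with `labels` (integer matrix, 0 background,
#'   `NA` off-mask), `sizes` (pixels per patch), `connectivity`.
#' @export
label_patches <- function(binary, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(binary); nc <- ncol(binary)
  hab <- !is.na(binary) & binary == 1
  labels <- matrix(0L, nr, nc)
  labels[is.na(binary)] <- NA_integer_
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  visited <- !hab
  next_label <- 0L
  sizes <- integer(0)
  # row-major scan from the NW corner fixes the label order
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (visited[r, co]) next
    next_label <- next_label + 1L
    queue <- matrix(c(r, co), 1)
    visited[r, co] <- TRUE
    n_px <- 0L
    while (nrow(queue) > 0) {
      labels[queue] <- next_label
      n_px <- n_px + nrow(queue)
      nbr_r <- rep(queue[, 1], each = length(dr)) + dr
      nbr_c <- rep(queue[, 2], each = length(dc)) + dc
      ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
      nbr <- cbind(nbr_r[ok], nbr_c[ok])
      nbr <- nbr[!visited[nbr], , drop = FALSE]
      if (nrow(nbr) > 0) {
        nbr <- nbr[!duplicated(nbr[, 1] + (nbr[, 2] - 1) * nr), ,
                   drop = FALSE]
        visited[nbr] <- TRUE
      }
      queue <- nbr
    }
    sizes <- c(sizes, n_px)
  }
  structure(list(labels = labels, sizes = sizes,
                 connectivity = connectivity),
            class = "patch_set")
}

#' Per-patch areas
#'
#' @param patches a `patch_set`.
#' @param stack optional `env_stack` supplying geodesic cell areas; when
#'   omitted (or the stack is Cartesian) each pixel counts 1 km^2.
#' @return numeric vector of patch areas (km^2), in label order.
#' @export
patch_areas <- function(patches, stack = NULL) {
  lab <- patches$labels
  n <- length(patches$sizes)
  if (n == 0) return(numeric(0))
  if (is.null(stack) || stack$cartesian) return(as.numeric(patches$sizes))
  area <- cell_areas(stack)
  sel <- !is.na(lab) & lab > 0
  as.numeric(tapply(area[sel], lab[sel], sum))
}

#' Remove patches below a minimum area
#'
#' Small patches are dropped from the patch set entirely (and hence from
#' all downstream metric denominators); their pixels become background.
#'
#' @param patches a `patch_set`.
#' @param areas per-patch areas (km^2), as from [patch_areas()].
#' @param min_area minimum retained patch area in km^2 (default 0.1).
#' @return list with the filtered `patch_set` and its `areas`.
#' @export
filter_small_patches <- function(patches, areas, min_area = 0.1) {
  keep <- which(areas >= min_area)
  lab <- patches$labels
  relab <- integer(length(patches$sizes))
  relab[keep] <- seq_along(keep)
  sel <- !is.na(lab) & lab > 0
  lab[sel] <- relab[lab[sel]]
  ps <- structure(list(labels = lab, sizes = patches$sizes[keep],
                       connectivity = patches$connectivity),
                  class = "patch_set")
  list(patches = ps, areas = areas[keep])
}

#' Splitting index
#'
#' `SPLIT = A^2 / sum(a_i^2)` with `A` the total landscape area and `a_i`
#' the patch areas.  Equals 1 when a single patch fills the landscape and
#' grows with fragmentation.
#'
#' @param areas per-patch areas.
#' @param landscape_area total (masked-in) landscape area, same units.
#' @return the splitting index, or `NA` for empty habitat.
#' @export
splitting_index <- function(areas, landscape_area) {
  if (length(areas) == 0 || sum(areas) == 0) return(NA_real_)
  landscape_area^2 / sum(areas^2)
}

#' Aggregation index
#'
#' `AI = 100 * g / g_max`, where `g` counts like (habitat-habitat) rook
#' adjacencies once, and `g_max` is the largest adjacency count achievable
#' by `A` habitat pixels: with `n = floor(sqrt(A))` and `m = A - n^2`,
#' `g_max = 2n(n-1)` if `m = 0`, `2n(n-1) + 2m - 1` if `m <= n`, and
#' `2n(n-1) + 2m - 2` otherwise.  A single habitat pixel has `g_max = 0`
#' and AI is defined as 0.
#'
#' @param binary 0/1 matrix (`NA` treated as background).
#' @return the aggregation index in \[0, 100\], or `NA` for empty habitat.
#' @export
aggregation_index <- function(binary) {
  hab <- !is.na(binary) & binary == 1
  A <- sum(hab)
  if (A == 0) return(NA_real_)
  nr <- nrow(hab); nc <- ncol(hab)
  g <- 0L
  if (nc > 1) g <- g + sum(hab[, -nc] & hab[, -1])
  if (nr > 1) g <- g + sum(hab[-nr, ] & hab[-1, ])
  n <- floor(sqrt(A)); m <- A - n^2
  g_max <- if (m == 0) 2 * n * (n - 1)
           else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
           else 2 * n * (n - 1) + 2 * m - 2
  if (g_max == 0) return(0)
  100 * g / g_max
}

#' Landscape fragmentation report
#'
#' Labels habitat patches, applies the minimum-patch-area filter, and
#' reports patch count, total and mean patch area, splitting index and
#' aggregation index.  Patch labelling uses the requested connectivity
#' (default 8) while AI adjacencies are rook-only, following the standard
#' landscape-metric definitions.
#'
#' @param binary 0/1 matrix (`NA` = off-mask).
#' @param stack optional `env_stack` for geodesic areas (else unit areas).
#' @param connectivity patch connectivity, 8 (default) or 4.
#' @param min_area minimum patch area retained, km^2 (default 0.1).
#' @return a `frag_report` list: `n_patches`, `total_area`,
#'   `mean_patch_area`, `splitting_index`, `aggregation_index`,
#'   `landscape_area`, `min_patch_filter`, plus the filtered `patch_set`.
#' @export
frag_report <- function(binary, stack = NULL, connectivity = 8,
                        min_area = 0.1) {
  ps <- label_patches(binary, connectivity)
  ar <- patch_areas(ps, stack)
  fl <- filter_small_patches(ps, ar, min_area)
  land <- if (is.null(stack) || stack$cartesian) sum(!is.na(binary))
          else sum(cell_areas(stack)[!is.na(binary)])
  n <- length(fl$areas)
  kept_binary <- binary
  kept_binary[] <- as.integer(!is.na(fl$patches$labels) &
                              fl$patches$labels > 0)
  kept_binary[is.na(binary)] <- NA_integer_
  structure(list(
    n_patches = n,
    total_area = if (n > 0) sum(fl$areas) else 0,
    mean_patch_area = if (n > 0) sum(fl$areas) / n else NA_real_,
    splitting_index = splitting_index(fl$areas, land),
    aggregation_index = if (n > 0) aggregation_index(kept_binary)
                        else NA_real_,
    landscape_area = land, min_patch_filter = min_area,
    connectivity = connectivity, patches = fl$patches,
    areas = fl$areas), class = "frag_report")
}

#' @export
print.frag_report <- function(x, ...) {
  cat("Fragmentation report (connectivity ", x$connectivity,
      ", min patch ", x$min_patch_filter, " km^2)\n", sep = "")
  cat(sprintf("  patches: %d, total area %.3f, mean patch %.3f\n",
              x$n_patches, x$total_area,
              ifelse(is.na(x$mean_patch_area), NaN, x$mean_patch_area)))
  cat(sprintf("  SPLIT %.3f, AI %.2f\n",
              x$splitting_index, x$aggregation_index))
  invisible(x)
}
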