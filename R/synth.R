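#' Generate a synthetic environmental landscape
#'
#' Builds a seeded `env_stack` emulating the structure of a gridded climate
#' dataset over a two-island landmass: one smooth north-south gradient
#' layer (a temperature analogue, strictly monotone along its axis), one or
#' more Gaussian-random-field layers (precipitation analogues, spatially
#' autocorrelated via Gaussian-kernel smoothing of white noise), and
#' optionally one categorical soil-analogue layer.  Continuous layers are
#' standardized to mean 0, sd 1 over masked-in cells.  The two-island
#' geometry is a vertical sea channel splitting the grid into a western and
#' an eastern landmass.
#'
#' @param nrow,ncol grid shape (>= 20 each, default 100 x 100).
#' @param n_grf number of random-field layers (default 2).
#' @param n_categories levels of the categorical layer; 0 omits it
#'   (default 4).
#' @param islands logical; carve the sea channel (default `TRUE`).
#' @param channel_width channel width in cells (default 3).
#' @param length_scale smoothing length scale of the random fields, in
#'   cells (default 8).
#' @param extent,res georeference; defaults place the grid in the
#'   southwest Pacific at a resolution of `0.15` degrees.
#' @param cartesian unit cell areas (default `TRUE` for exact pixel
#'   arithmetic in tests; set `FALSE` for geodesic areas).
#' @param seed integer seed; the stack is reproducible given it.
#' @return an `env_stack` with layers `temp`, `precip1..k`, and `soil`.
#' @export
generate_world <- function(nrow = 100, ncol = 100, n_grf = 2,
                           n_categories = 4, islands = TRUE,
                           channel_width = 3, length_scale = 8,
                           extent = NULL, res = 0.15, cartesian = TRUE,
                           seed = 1) {
  if (nrow < 20 || ncol < 20) stop("degenerate shape: need at least 20 x 20")
  if (is.null(extent))
    extent <- c(165, 165 + ncol * res, -32 - nrow * res, -32)
  mask <- matrix(TRUE, nrow, ncol)
  if (islands) {
    mid <- floor(ncol / 2)
    cols <- mid + seq_len(channel_width) - ceiling(channel_width / 2)
    mask[, cols[cols >= 1 & cols <= ncol]] <- FALSE
  }
  std <- function(m) {
    v <- m[mask]
    (m - mean(v)) / stats::sd(v)
  }
  layers <- list()
  # temperature analogue: latitudinal gradient, strictly monotone by row
  layers$temp <- std(matrix(rev(seq_len(nrow)), nrow, ncol))
  with_seed(seed, {
    for (k in seq_len(n_grf))
      layers[[paste0("precip", k)]] <- std(gaussian_field(nrow, ncol,
                                                          length_scale))
    if (n_categories > 0) {
      f <- gaussian_field(nrow, ncol, length_scale)
      q <- stats::quantile(f[mask], probs = seq(0, 1,
                                                length.out = n_categories + 1))
      q[1] <- -Inf; q[length(q)] <- Inf
      layers$soil <- matrix(as.integer(cut(f, q)), nrow, ncol)
    }
  })
  for (nm in names(layers)) layers[[nm]][!mask] <- NA
  kinds <- ifelse(names(layers) == "soil", "categorical", "continuous")
  env_stack(layers, extent, res = res, kind = kinds, mask = mask,
            cartesian = cartesian)
}

# Gaussian random field: separable Gaussian-kernel smoothing of white noise
gaussian_field <- function(nr, nc, length_scale) {
  half <- max(1L, ceiling(3 * length_scale))
  k <- stats::dnorm(seq(-half, half), sd = length_scale)
  pad <- length(k) %/% 2
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
}

#' True niche definition
#'
#' A logistic habitat-suitability model over the landscape layers:
#' `suitability(x) = plogis(beta0 + sum(beta * x))`, with optional additive
#' per-level effects for the categorical layer.
#'
#' @param beta0 intercept.
#' @param beta named coefficients over continuous layers.
#' @param cat_effects optional named list: per categorical layer, a vector
#'   of per-level additive effects.
#' @return an object of class `true_niche`.
#' @export
true_niche <- function(beta0, beta, cat_effects = NULL) {
  stopifnot(!is.null(names(beta)))
  structure(list(beta0 = beta0, beta = beta, cat_effects = cat_effects),
            class = "true_niche")
}

#' Closed-form suitability of a niche over a landscape
#'
#' @param world an `env_stack`.
#' @param niche a [true_niche()].
#' @return numeric matrix of suitabilities in (0, 1), `NA` off-mask.
#' @export
true_suitability <- function(world, niche) {
  eta <- matrix(niche$beta0, nrow(world$mask), ncol(world$mask))
  for (nm in names(niche$beta)) {
    if (!nm %in% names(world$layers))
      stop("niche references unknown layer: ", nm)
    eta <- eta + niche$beta[[nm]] * world$layers[[nm]]
  }
  for (nm in names(niche$cat_effects)) {
    lev <- world$layers[[nm]]
    eta <- eta + niche$cat_effects[[nm]][lev]
  }
  s <- stats::plogis(eta)
  s[!world$mask] <- NA
  s
}

#' Apply a climate scenario to a landscape
#'
#' Shifts continuous layers by additive deltas (e.g. a warming offset on
#' the temperature analogue) and/or multiplicative factors (on
#' precipitation analogues).  Categorical layers are static and never
#' change.
#'
#' @param world an `env_stack`.
#' @param deltas named additive offsets on continuous layers (e.g.
#'   `c(temp = 1.0)` for a +1.0 warming analogue, `c(temp = 3.7)` for
#'   +3.7).
#' @param mult named multiplicative factors on continuous layers.
#' @return the shifted `env_stack`.
#' @export
apply_scenario <- function(world, deltas = NULL, mult = NULL) {
  for (nm in names(deltas)) {
    if (!nm %in% names(world$layers)) stop("unknown layer: ", nm)
    if (world$kind[nm] == "categorical")
      stop("categorical layers are static; cannot shift '", nm, "'")
    world$layers[[nm]] <- world$layers[[nm]] + deltas[[nm]]
  }
  for (nm in names(mult)) {
    if (!nm %in% names(world$layers)) stop("unknown layer: ", nm)
    if (world$kind[nm] == "categorical")
      stop("categorical layers are static; cannot scale '", nm, "'")
    world$layers[[nm]] <- world$layers[[nm]] * mult[[nm]]
  }
  world
}

#' Standard warming scenarios for a landscape
#'
#' Convenience presets: the current conditions plus two warming analogues
#' shifting the temperature layer by +1.0 and +3.7 in layer units (the low-
#' and high-emission scenario analogues).
#'
#' @param world an `env_stack` with a `temp` layer.
#' @param deltas named numeric, shift per scenario (defaults
#'   `c(warm_low = 1.0, warm_high = 3.7)`).
#' @return named list of `env_stack`s including `current`.
#' @export
default_scenarios <- function(world,
                              deltas = c(warm_low = 1.0, warm_high = 3.7)) {
  out <- list(current = world)
  for (nm in names(deltas))
    out[[nm]] <- apply_scenario(world, deltas = c(temp = deltas[[nm]]))
  out
}

#' Sample a multi-species occurrence compilation
#'
#' Draws survey sites without replacement from the masked-in cells, then
#' records each species present at a site with probability equal to its
#' true suitability there.  Every species is recorded (0/1) at every site,
#' so absences for any one species can be derived from the compilation
#' exactly as for a field dataset.
#'
#' @param world an `env_stack`.
#' @param niches named list of [true_niche()] objects (one per species).
#' @param n_sites number of survey sites (<= masked-in cells).
#' @param seed integer seed.
#' @return occurrence data.frame (species, lon, lat, presence, source)
#'   with site coordinates at cell centres.
#' @export
sample_occurrences <- function(world, niches, n_sites, seed = 1) {
  cells <- which(world$mask)
  if (n_sites > length(cells))
    stop("n_sites exceeds the number of masked-in cells")
  nr <- nrow(world$mask)
  out <- with_seed(seed, {
    sites <- sample(cells, n_sites)
    r <- ((sites - 1L) %% nr) + 1L
    co <- ((sites - 1L) %/% nr) + 1L
    lon <- world$extent[1] + (co - 0.5) * world$res
    lat <- world$extent[4] - (r - 0.5) * world$res
    do.call(rbind, lapply(names(niches), function(sp) {
      s <- true_suitability(world, niches[[sp]])[sites]
      data.frame(species = sp, lon = lon, lat = lat,
                 presence = as.integer(stats::runif(n_sites) < s),
                 source = "synthetic", stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}

#' Truth maps for a niche
#'
#' @param world an `env_stack`.
#' @param niche a [true_niche()].
#' @param cutoff binary threshold (default 0.5, strict).
#' @return list with `suitability` (matrix) and `binary` (0/1 matrix,
#'   `NA` off-mask).
#' @export
truth_maps <- function(world, niche, cutoff = 0.5) {
  s <- true_suitability(world, niche)
  list(suitability = s, binary = binary_from_truth(s, cutoff))
}
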