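# Fixture builders and independent oracles shared across test files.

# small Cartesian-mode stack with given layer matrices (row 1 = north)
tiny_stack <- function(..., res = 1, lon_min = 0, lat_max = 0,
                       kind = "continuous", cartesian = TRUE) {
  layers <- list(...)
  if (is.null(names(layers)))
    names(layers) <- paste0("l", seq_along(layers))
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  env_stack(layers,
            extent = c(lon_min, lon_min + nc * res, lat_max - nr * res,
                       lat_max),
            res = res, kind = kind, cartesian = cartesian)
}

# brute-force pairwise AUC: P(presence outranks absence), ties half credit
auc_bruteforce <- function(pred, y) {
  p1 <- pred[y == 1]; p0 <- pred[y == 0]
  s <- 0
  for (a in p1) for (b in p0) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(p1) * length(p0))
}

# exhaustive TSS: max of sens+spec-1 over every distinct value as cutoff
# (strict >), plus a cutoff below the minimum
tss_bruteforce <- function(pred, y) {
  cuts <- c(min(pred) - 1, sort(unique(pred)))
  best <- -Inf
  for (ct in cuts) {
    sens <- mean(pred[y == 1] > ct)
    spec <- mean(pred[y == 0] <= ct)
    best <- max(best, sens + spec - 1)
  }
  best
}

# independent connected-component labelling: depth-first flood fill with an
# explicit stack, one pixel at a time
label_bruteforce <- function(binary, connectivity = 8) {
  nr <- nrow(binary); nc <- ncol(binary)
  hab <- !is.na(binary) & binary == 1
  lab <- matrix(0L, nr, nc)
  lab[is.na(binary)] <- NA_integer_
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (co in seq_len(nc)) for (r in seq_len(nr)) {
    if (!hab[r, co] || lab[r, co] > 0) next
    cur <- cur + 1L
    stack <- list(c(r, co))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (!hab[p[1], p[2]] || (!is.na(lab[p[1], p[2]]) && lab[p[1], p[2]] > 0))
        next
      lab[p[1], p[2]] <- cur
      for (i in seq_len(nrow(nb))) {
        rr <- p[1] + nb$dr[i]; cc <- p[2] + nb$dc[i]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && hab[rr, cc] &&
            lab[rr, cc] == 0)
          stack[[length(stack) + 1]] <- c(rr, cc)
      }
    }
  }
  lab
}

# patch partitions must agree up to label renaming
same_partition <- function(a, b) {
  ok <- !is.na(a) & a > 0
  if (!identical(which(ok), which(!is.na(b) & b > 0))) return(FALSE)
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# standard-conditions synthetic species fit, shared by recovery tests
fit_synthetic_species <- function(seed, beta = c(temp = 3), beta0 = 0,
                                  n_sites = 400, occ_seed = seed + 100,
                                  ...) {
  w <- generate_world(seed = seed)
  niche <- true_niche(beta0, beta)
  occ <- sample_occurrences(w, list(sp = niche), n_sites, seed = occ_seed)
  fit <- enm(occ, w, species = "sp", seed = seed, ...)
  list(world = w, niche = niche, occ = occ, fit = fit)
}
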