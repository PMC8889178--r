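test_that("patch labelling matches adjacency rules and the flood-fill oracle",
{
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_equal(length(label_patches(one)$sizes), 1)

  diagm <- matrix(0L, 3, 3); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_equal(length(label_patches(diagm, 8)$sizes), 1)
  expect_equal(length(label_patches(diagm, 4)$sizes), 2)

  # deterministic label order: first pixel in row-major order from NW
  two <- matrix(0L, 3, 4); two[1, 4] <- 1L; two[3, 1] <- 1L
  lp <- label_patches(two)
  expect_equal(lp$labels[1, 4], 1L)
  expect_equal(lp$labels[3, 1], 2L)

  set.seed(23)
  for (k in 1:8) {
    b <- matrix(rbinom(400, 1, 0.45), 20, 20)
    b[sample(400, 15)] <- NA
    for (conn in c(8, 4)) {
      got <- label_patches(b, conn)
      oracle <- label_bruteforce(b, conn)
      expect_true(same_partition(got$labels, oracle))
      expect_equal(sum(got$sizes), sum(b == 1, na.rm = TRUE))
    }
  }
  expect_equal(label_patches(matrix(0L, 4, 4))$sizes, integer(0))
})

test_that("small-patch filtering respects the area threshold", {
  b <- matrix(0L, 6, 6); b[1:2, 1:2] <- 1L; b[5, 5] <- 1L
  ps <- label_patches(b)
  # unit-area pixels: nothing below 0.1 km^2
  ar <- patch_areas(ps)
  expect_equal(sort(ar), c(1, 4))
  fl <- filter_small_patches(ps, ar, min_area = 0.1)
  expect_equal(length(fl$areas), 2)
  # with 0.05 km^2 pixels a single-pixel patch is removed
  fl2 <- filter_small_patches(ps, ar * 0.05, min_area = 0.1)
  expect_equal(length(fl2$areas), 1)
  expect_equal(fl2$areas, 4 * 0.05)
  expect_equal(max(fl2$patches$labels, na.rm = TRUE), 1L)
  # all patches removed -> empty report
  fr <- frag_report(b * 0L)
  expect_equal(fr$n_patches, 0)
  expect_equal(fr$total_area, 0)
  expect_true(is.na(fr$splitting_index))
})

test_that("splitting index matches its direct formula", {
  # habitat fills the whole 10x10 landscape
  expect_equal(splitting_index(100, 100), 1)
  # two equal patches covering the landscape
  expect_equal(splitting_index(c(50, 50), 100), 2)
  # one 25-cell patch in a 100-cell landscape
  expect_equal(splitting_index(25, 100), 16)
  expect_true(is.na(splitting_index(numeric(0), 100)))
  # merging two patches (same habitat) cannot increase SPLIT
  expect_lte(splitting_index(c(30), 100), splitting_index(c(20, 10), 100))
})

test_that("aggregation index counts rook adjacencies against the maximum", {
  solid2 <- matrix(1L, 2, 2)
  expect_equal(aggregation_index(solid2), 100)  # g = 4 = g_max
  iso <- matrix(0L, 3, 3); iso[1, 1] <- 1L; iso[3, 3] <- 1L
  expect_equal(aggregation_index(iso), 0)
  strip <- matrix(1L, 1, 4)
  expect_equal(aggregation_index(strip), 75)  # g = 3, g_max = 4
  single <- matrix(0L, 2, 2); single[1, 1] <- 1L
  expect_equal(aggregation_index(single), 0)
  expect_true(is.na(aggregation_index(matrix(0L, 3, 3))))
  # adding a like adjacency at constant habitat area cannot lower AI
  l_shape <- matrix(0L, 3, 3); l_shape[1, 1:2] <- 1L; l_shape[3, 3] <- 1L
  more <- matrix(0L, 3, 3); more[1, 1:3] <- 1L
  expect_gte(aggregation_index(more), aggregation_index(l_shape))
})

test_that("frag_report composes the metrics and matches brute force", {
  # solid square habitat in a larger landscape
  b <- matrix(0L, 10, 10); b[3:6, 3:6] <- 1L
  fr <- frag_report(b)
  expect_equal(fr$n_patches, 1)
  expect_equal(fr$total_area, 16)
  expect_equal(fr$mean_patch_area, 16)
  expect_equal(fr$aggregation_index, 100)
  expect_equal(fr$splitting_index, (100 / 16)^2)

  # random fixture: every metric equals a direct recomputation
  set.seed(5)
  rb <- matrix(rbinom(900, 1, 0.4), 30, 30)
  fr2 <- frag_report(rb)
  lab <- label_bruteforce(rb, 8)
  sizes <- as.numeric(table(lab[lab > 0]))
  expect_equal(fr2$n_patches, length(sizes))
  expect_equal(fr2$total_area, sum(sizes))
  expect_equal(fr2$mean_patch_area, mean(sizes))
  expect_equal(fr2$splitting_index, 900^2 / sum(sizes^2))
  hab <- rb == 1
  g <- sum(hab[, -30] & hab[, -1]) + sum(hab[-30, ] & hab[-1, ])
  A <- sum(hab); n <- floor(sqrt(A)); m <- A - n^2
  gmax <- 2 * n * (n - 1) + (if (m == 0) 0 else if (m <= n) 2 * m - 1
                             else 2 * m - 2)
  expect_equal(fr2$aggregation_index, 100 * g / gmax)
})

test_that("metrics are invariant to translation and rotation", {
  set.seed(9)
  core <- matrix(rbinom(100, 1, 0.5), 10, 10)
  pad <- function(m, up, left, nr = 25, nc = 25) {
    out <- matrix(0L, nr, nc)
    out[up + seq_len(nrow(m)) - 1, left + seq_len(ncol(m)) - 1] <- m
    out
  }
  rot90 <- function(m) t(m)[, nrow(m):1]
  a <- pad(core, 2, 2)
  b <- pad(core, 9, 12)                  # translated
  c_ <- pad(rot90(core), 5, 5)           # rotated 90 degrees
  fa <- frag_report(a); fb <- frag_report(b); fc <- frag_report(c_)
  for (f in list(fb, fc)) {
    expect_equal(f$n_patches, fa$n_patches)
    expect_equal(f$total_area, fa$total_area)
    expect_equal(f$splitting_index, fa$splitting_index)
    expect_equal(f$aggregation_index, fa$aggregation_index)
  }
})

test_that("geodesic patch areas use per-row cell areas", {
  b <- matrix(0L, 4, 4); b[1, 1] <- 1L; b[4, 4] <- 1L
  st <- tiny_stack(matrix(0, 4, 4), res = 1, lon_min = 0, lat_max = -40,
                   cartesian = FALSE)
  ps <- label_patches(b)
  ar <- patch_areas(ps, st)
  expect_equal(ar, pixel_area(c(-40.5, -43.5), 1))
  # higher-latitude (more poleward) pixels are smaller
  expect_gt(ar[1], ar[2])
})
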