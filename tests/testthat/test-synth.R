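test_that("generated worlds are reproducible, standardized and two-island",
{
  w1 <- generate_world(nrow = 40, ncol = 40, seed = 6)
  w2 <- generate_world(nrow = 40, ncol = 40, seed = 6)
  expect_equal(w1, w2)
  w3 <- generate_world(nrow = 40, ncol = 40, seed = 7)
  expect_false(identical(w1$layers$precip1, w3$layers$precip1))

  # 3 continuous + 1 categorical requested layers -> 4 layers
  expect_length(w1$layers, 4)
  expect_equal(unname(w1$kind),
               c("continuous", "continuous", "continuous", "categorical"))

  # gradient layer strictly monotone along its axis
  col_ok <- which(w1$mask[1, ])[1]
  expect_true(all(diff(w1$layers$temp[, col_ok]) < 0))
  # continuous layers standardized over masked-in cells
  for (nm in c("temp", "precip1", "precip2")) {
    expect_equal(mean(w1$layers[[nm]][w1$mask]), 0, tolerance = 1e-10)
    expect_equal(sd(w1$layers[[nm]][w1$mask]), 1, tolerance = 1e-10)
  }
  # vertical sea channel splits the landmass into two components
  land <- label_patches(ifelse(w1$mask, 1L, NA_integer_), 8)
  expect_equal(length(land$sizes), 2)
  expect_error(generate_world(nrow = 10, ncol = 10), "degenerate")
})

test_that("scenarios shift dynamic layers and keep categorical layers static",
{
  w <- generate_world(nrow = 30, ncol = 30, seed = 4)
  same <- apply_scenario(w)
  expect_equal(same, w)
  warm <- apply_scenario(w, deltas = c(temp = 1.0))
  expect_equal(warm$layers$temp[w$mask], w$layers$temp[w$mask] + 1.0)
  expect_equal(warm$layers$precip1, w$layers$precip1)
  expect_equal(warm$layers$soil, w$layers$soil)
  wetter <- apply_scenario(w, mult = c(precip1 = 1.2))
  expect_equal(wetter$layers$precip1[w$mask],
               w$layers$precip1[w$mask] * 1.2)
  expect_error(apply_scenario(w, deltas = c(soil = 1)), "static")
  expect_error(apply_scenario(w, deltas = c(nope = 1)), "unknown layer")

  sc <- default_scenarios(w)
  expect_named(sc, c("current", "warm_low", "warm_high"))
  expect_equal(sc$current, w)
  expect_equal(sc$warm_high$layers$temp[w$mask],
               w$layers$temp[w$mask] + 3.7)

  # a cold-adapted niche's most suitable cells move toward the cold end
  niche <- true_niche(0, c(temp = -3))
  s_cur <- true_suitability(w, niche)
  s_fut <- true_suitability(apply_scenario(w, deltas = c(temp = 2)), niche)
  # suitability drops everywhere under warming for this niche
  expect_true(all(s_fut[w$mask] < s_cur[w$mask]))
  r_best_cur <- which.max(apply(s_cur, 1, max, na.rm = TRUE))
  expect_equal(r_best_cur, which.max(apply(s_fut, 1, max, na.rm = TRUE)))
  expect_equal(r_best_cur, nrow(s_cur))  # coldest row is the gradient base
})

test_that("occurrence sampling follows the true suitability", {
  w <- generate_world(nrow = 30, ncol = 30, seed = 10)
  # suitability identically ~1: present at every site
  sure <- true_niche(30, c(temp = 0))
  occ <- sample_occurrences(w, list(a = sure), 100, seed = 3)
  expect_equal(mean(occ$presence), 1)
  expect_true(all(occ$species == "a"))

  # beta = 0 everywhere: presence probability 1/2, binomial 3-sigma bound
  coin <- true_niche(0, c(temp = 0))
  occ2 <- sample_occurrences(w, list(b = coin), 400, seed = 3)
  expect_lt(abs(mean(occ2$presence) - 0.5), 3 * sqrt(0.25 / 400))

  # reproducible; sites drawn without replacement from masked-in cells
  occ3 <- sample_occurrences(w, list(b = coin), 400, seed = 3)
  expect_equal(occ2, occ3)
  expect_equal(anyDuplicated(occ2[c("lon", "lat")]), 0)
  idx <- cell_index(w, occ2$lon, occ2$lat)
  expect_true(all(w$mask[cbind(idx[, 1], idx[, 2])]))
  expect_error(sample_occurrences(w, list(b = coin), 1e6, seed = 1),
               "exceeds")
})

test_that("truth maps threshold the closed-form suitability", {
  w <- generate_world(nrow = 30, ncol = 30, seed = 12)
  niche <- true_niche(0, c(temp = -3))
  tm <- truth_maps(w, niche, cutoff = 0.5)
  ok <- w$mask
  expect_equal(tm$binary[ok],
               as.integer(tm$suitability[ok] > 0.5))
  expect_true(all(is.na(tm$binary[!ok])))
  # the 0.5 contour sits at linear predictor zero
  expect_equal(tm$binary[ok], as.integer(-3 * w$layers$temp[ok] > 0))

  # warming shrinks a cold-ridge species' true range by an exact count
  gap <- diff(sort(unique(w$layers$temp[ok])))[1]
  warm <- apply_scenario(w, deltas = c(temp = 5 * gap))
  tm_w <- truth_maps(warm, niche, cutoff = 0.5)
  rows_occupied <- function(b) sum(rowSums(b == 1, na.rm = TRUE) > 0)
  expect_equal(rows_occupied(tm_w$binary), rows_occupied(tm$binary) - 5)
})
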