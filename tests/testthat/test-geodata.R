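test_that("ESRI ASCII grids round-trip with nodata honoured", {
  m <- matrix(runif(30), 5, 6)
  m[c(2, 9, 17)] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, extent = c(10, 16, -5, 0), res = 1)
  g <- read_ascii_grid(path)
  expect_equal(g$data, m, tolerance = 1e-6)
  expect_equal(g$extent, c(10, 16, -5, 0))
  expect_equal(g$res, 1)
})

test_that("read_env_stack aligns layers and masks the union of nodata", {
  dir <- withr::local_tempdir()
  a <- matrix(rnorm(100), 10, 10)
  b <- matrix(rnorm(100), 10, 10)
  b[c(3, 55, 91)] <- NA  # 3 nodata cells
  write_ascii_grid(a, file.path(dir, "a.asc"), c(0, 10, 0, 10), 1)
  write_ascii_grid(b, file.path(dir, "b.asc"), c(0, 10, 0, 10), 1)
  st <- read_env_stack(c(a = file.path(dir, "a.asc"),
                         b = file.path(dir, "b.asc")))
  expect_s3_class(st, "env_stack")
  expect_length(st$layers, 2)
  expect_equal(sum(st$mask), 97)

  write_ascii_grid(a, file.path(dir, "c.asc"), c(5, 15, 0, 10), 1)
  expect_error(read_env_stack(c(file.path(dir, "a.asc"),
                                file.path(dir, "c.asc"))),
               "alignment")
  expect_error(read_ascii_grid(file.path(dir, "missing.asc")), "cannot read")
})

test_that("crop_extent snaps to the source cell grid", {
  st <- tiny_stack(matrix(seq_len(400), 20, 20), res = 1, lon_min = 0,
                   lat_max = 20)
  expect_equal(crop_extent(st, c(0, 20, 0, 20))$layers[[1]],
               st$layers[[1]])
  ne <- crop_extent(st, c(10, 20, 10, 20))  # NE quadrant
  expect_equal(dim(ne), c(10L, 10L))
  expect_equal(ne$extent, c(10, 20, 10, 20))
  expect_equal(ne$layers[[1]], st$layers[[1]][1:10, 11:20])

  # misaligned bounds snap outward: index arithmetic oracle
  cr <- crop_extent(st, c(3.4, 7.6, 2.2, 9.9))
  c0 <- floor(3.4) + 1; c1 <- ceiling(7.6)      # columns 4..8
  r0 <- floor(20 - 9.9) + 1; r1 <- ceiling(20 - 2.2)  # rows 11..18
  expect_equal(dim(cr), c(r1 - r0 + 1L, c1 - c0 + 1L))
  expect_equal(cr$extent, c(c0 - 1, c1, 20 - r1, 20 - (r0 - 1)))
  expect_error(crop_extent(st, c(50, 60, 50, 60)), "empty intersection")

  # crop twice to the same extent equals a single crop
  expect_equal(crop_extent(cr, c(3.4, 7.6, 2.2, 9.9)), cr)
})

test_that("occurrence filtering rounds, deduplicates and is idempotent", {
  raw <- data.frame(
    species = "A",
    lon = c(170.123, 170.121), lat = c(-43.456, -43.459),
    presence = 1, source = "x")
  f <- filter_occurrences(raw)
  expect_equal(nrow(f), 1)
  expect_equal(f$lon, 170.12)
  expect_equal(f$lat, -43.46)

  # same rounded location, different species: both kept
  two <- data.frame(species = c("A", "B"), lon = 170.12, lat = -43.46,
                    presence = 1, source = "")
  expect_equal(nrow(filter_occurrences(two)), 2)

  # 12 raw rows with 3 within-species duplicates -> 9 rows
  fx <- data.frame(
    species = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "C", "C", "C"),
    lon = c(170.111, 170.113, 170.25, 171.00, 170.111, 170.50, 170.504,
            172.1, 172.1, 172.2, 172.3, 172.301),
    lat = c(-43.111, -43.112, -43.30, -44.00, -43.111, -43.60, -43.601,
            -45.0, -45.2, -45.3, -45.4, -45.396),
    presence = 1, source = "")
  f9 <- filter_occurrences(fx)
  expect_equal(nrow(f9), 9)
  expect_equal(attr(f9, "filter_report")$n_duplicates, 3)

  # idempotent
  expect_equal(nrow(filter_occurrences(f9)), nrow(f9))

  # presence beats absence at the same rounded cell
  pa <- data.frame(species = "A", lon = c(170.12, 170.121),
                   lat = c(-43.46, -43.458), presence = c(0, 1), source = "")
  expect_equal(filter_occurrences(pa)$presence, 1)

  # out-of-extent rows removed and counted
  oo <- data.frame(species = "A", lon = c(170, 10), lat = c(-43, -43),
                   presence = 1, source = "")
  fo <- filter_occurrences(oo, extent_config())
  expect_equal(nrow(fo), 1)
  expect_equal(attr(fo, "filter_report")$n_outside_extent, 1)
})

test_that("derive_absences uses other species' cells minus target cells", {
  st <- tiny_stack(matrix(0, 10, 10), res = 1, lon_min = 0, lat_max = 10)
  mk <- function(sp, lon, lat, presence = 1)
    data.frame(species = sp, lon = lon, lat = lat, presence = presence,
               source = "")
  # target present wherever others occur -> zero derived absences
  rec <- rbind(mk("T", c(1.5, 2.5), c(1.5, 2.5)),
               mk("O", c(1.5, 2.5), c(1.5, 2.5)))
  d <- derive_absences(rec, "T", st)
  expect_equal(sum(d$presence == 0), 0)

  # 1 target presence cell, 5 disjoint other-species cells -> 5 absences
  rec2 <- rbind(mk("T", 1.5, 1.5), mk("O", 2:6 + 0.5, rep(5.5, 5)))
  d2 <- derive_absences(rec2, "T", st)
  expect_equal(sum(d2$presence == 0), 5)
  expect_equal(sum(d2$presence == 1), 1)

  # shared cell excluded; counts follow cell-set arithmetic
  rec3 <- rbind(mk("T", c(1.5, 3.5), c(1.5, 3.5)),
                mk("O", c(3.5, 4.5, 4.7), c(3.5, 6.5, 6.6)),
                mk("T", 8.5, 8.5, presence = 0))  # explicit target absence
  d3 <- derive_absences(rec3, "T", st)
  # other cells: {(3.5,3.5) shared, (4,6) from two records, (8,8) explicit}
  expect_equal(sum(d3$presence == 0), 2)
  # presence and absence cells disjoint
  pc <- cell_index(st, d3$lon[d3$presence == 1], d3$lat[d3$presence == 1])
  ac <- cell_index(st, d3$lon[d3$presence == 0], d3$lat[d3$presence == 0])
  expect_length(intersect(paste(pc[, 1], pc[, 2]), paste(ac[, 1], ac[, 2])),
                0)
  expect_error(derive_absences(rec3, "nope", st), "unknown species")
})

test_that("covariate extraction matches per-point lookup and drops masked",
{
  set.seed(42)
  a <- matrix(rnorm(100), 10, 10); b <- matrix(rnorm(100), 10, 10)
  a[5, 5] <- NA
  st <- tiny_stack(a = a, b = b, res = 1, lon_min = 0, lat_max = 0)
  pts <- data.frame(species = "s",
                    lon = c(0.5, 3.2, 9.99, 4.5, 0, 10, 2.5, 6.1, 8.8, 1.1),
                    lat = -c(0.5, 3.2, 9.99, 4.5, 0, 10, 2.5, 6.1, 8.8, 1.1),
                    presence = rep(c(1, 0), 5), source = "")
  ex <- suppressWarnings(extract_covariates(st, pts))
  # oracle: per-point loop with the half-open cell rule
  for (i in seq_len(nrow(ex$X))) {
    r <- ex$cells[i, "row"]; co <- ex$cells[i, "col"]
    expect_identical(ex$X$a[i], a[r, co])
    expect_identical(ex$X$b[i], b[r, co])
  }
  # the masked cell (4.5, -4.5) -> row 5 col 5 is dropped
  expect_equal(ex$dropped, 1)
  expect_equal(nrow(ex$X), 9)

  # half-open rule: cell edges belong to the cell to the SE; max edges to
  # the last cell
  idx <- cell_index(st, c(3, 10, 0), c(-3, -10, 0))
  expect_equal(unname(idx[1, ]), c(4L, 4L))
  expect_equal(unname(idx[2, ]), c(10L, 10L))
  expect_equal(unname(idx[3, ]), c(1L, 1L))

  st_all_na <- tiny_stack(matrix(NA_real_, 10, 10) + 0, res = 1,
                          lon_min = 0, lat_max = 10)
  expect_error(extract_covariates(st_all_na, pts), "empty-design")
})

test_that("spherical pixel areas match the closed form and sum over bands",
{
  R <- 6371; res <- 1 / 120
  direct <- function(lat) {
    R^2 * (res * pi / 180) *
      (sin((lat + res / 2) * pi / 180) - sin((lat - res / 2) * pi / 180))
  }
  expect_equal(pixel_area(0), direct(0))
  expect_equal(pixel_area(0), 0.859, tolerance = 1e-3)
  expect_equal(pixel_area(-45), direct(-45))
  expect_equal(pixel_area(-45), 0.607, tolerance = 1e-3)
  expect_lt(pixel_area(90 - res / 2), 1e-4)

  # band sum equals the analytic band area to 1e-9 relative error
  lat0 <- -49; lat1 <- -32
  n <- round((lat1 - lat0) / res)
  centers <- lat0 + (seq_len(n) - 0.5) * res
  band <- R^2 * (res * pi / 180) *
    (sin(lat1 * pi / 180) - sin(lat0 * pi / 180))
  expect_equal(sum(pixel_area(centers)), band, tolerance = 1e-9)
})
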