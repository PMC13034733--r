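flat_dem <- function(z = 100, n = 40, cell = 30) {
  dem_grid(matrix(z, n, n), cell_size = cell)
}

test_that("flat terrain gives exactly planimetric distances", {
  dem <- flat_dem()
  a <- c(50, 60)
  b <- c(730, 410)
  expect_equal(profile_distance(dem, a, b), sqrt(sum((b - a)^2)))
  expect_equal(profile_distance(dem, a, a), 0)
})

test_that("a uniform 30 m rise over 40 m planimetric gives 50 m", {
  # planar ramp: z = 0.75 x, bilinear interpolation reproduces it exactly
  n <- 40
  cell <- 30
  xc <- (seq_len(n) - 0.5) * cell
  dem <- dem_grid(matrix(rep(0.75 * xc, each = n), n, n), cell_size = cell)
  a <- c(300, 500)
  b <- c(340, 500)
  expect_equal(profile_distance(dem, a, b, step = 40), 50)
  # and with subdivision: each 10 m step is a 10-7.5 right triangle
  expect_equal(profile_distance(dem, a, b, step = 10), 4 * sqrt(100 + 56.25))
})

test_that("profile distance is symmetric and bounded below by planimetric", {
  dem <- sim_dem(50, cell_size = 30, relief = 60, seed = 2)
  withr::with_seed(14, {
    for (rep in 1:10) {
      a <- runif(2, 100, 1300)
      b <- runif(2, 100, 1300)
      d_ab <- profile_distance(dem, a, b)
      expect_equal(d_ab, profile_distance(dem, b, a), tolerance = 1e-9)
      expect_gte(d_ab, sqrt(sum((b - a)^2)) - 1e-9)
    }
  })
})

test_that("coarse profiles stay within 1% of a 1 m refinement", {
  dem <- sim_dem(60, cell_size = 30, relief = 50, seed = 6)
  withr::with_seed(26, {
    for (rep in 1:5) {
      a <- runif(2, 150, 1600)
      b <- runif(2, 150, 1600)
      d30 <- profile_distance(dem, a, b, step = 30)
      d1 <- profile_distance(dem, a, b, step = 1)
      expect_lt(abs(d30 - d1) / d1, 0.01)
    }
  })
})

test_that("nodata under the path is reported by chainage", {
  m <- matrix(100, 20, 20)
  m[10, 10] <- NA
  dem <- dem_grid(m, cell_size = 30)
  expect_error(profile_distance(dem, c(30, 315), c(570, 315)),
               "nodata", class = "behavsyn_validation_error")
  expect_error(dem_elevation(dem, 1e6, 0),
               class = "behavsyn_validation_error")
})

test_that("ASCII grid IO round-trips the DEM", {
  dem <- sim_dem(15, cell_size = 30, relief = 40, seed = 9)
  dem$elevations[3, 4] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(dem, path)
  back <- read_ascii_grid(path)
  expect_equal(back$elevations, dem$elevations, tolerance = 1e-6)
  expect_equal(back$cell_size, 30)
  expect_equal(back$origin_x, dem$origin_x)
})

test_that("degree-sized cells are rejected as unprojected", {
  expect_error(dem_grid(matrix(1, 5, 5), cell_size = 0.0003),
               "reproject", class = "behavsyn_validation_error")
})

test_that("mask cells convert to centre points; empty masks error", {
  mask <- matrix(FALSE, 2, 2)
  mask[1, ] <- TRUE
  pts <- disturbance_points(mask, spacing = 30)
  expect_equal(nrow(pts), 2)
  expect_setequal(pts$x, c(15, 45))
  expect_equal(unique(pts$y), 45)  # top row is the northern one
  full <- disturbance_points(matrix(TRUE, 2, 2), spacing = 30)
  expect_equal(nrow(full), 4)
  expect_error(disturbance_points(matrix(FALSE, 2, 2)),
               class = "behavsyn_empty_data_error")
})

test_that("SSD takes the surface minimum, not the planimetric one", {
  # a steep ridge between the sample and the planimetrically nearer point
  n <- 60
  cell <- 30
  m <- matrix(0, n, n)
  ridge_col <- 30
  m[, ridge_col] <- 4000
  m[, ridge_col - 1] <- 2000
  m[, ridge_col + 1] <- 2000
  dem <- dem_grid(m, cell_size = cell)
  sample <- tibble::tibble(sample_id = "s", x = 800, y = 900)
  near_over_ridge <- c(1000, 900)   # 200 m away across the wall
  far_flat <- c(150, 900)           # 650 m away on the flat side
  dist_set <- tibble::tibble(x = c(near_over_ridge[1], far_flat[1]),
                             y = c(near_over_ridge[2], far_flat[2]))
  out <- ssd(dem, sample, dist_set)
  expect_equal(out$nearest_x, 150)
  brute <- min(profile_distance(dem, c(800, 900), near_over_ridge),
               profile_distance(dem, c(800, 900), far_flat))
  expect_equal(out$ssd_m, brute)
})

test_that("pruning changes the work done but never the minima", {
  dem <- sim_dem(50, cell_size = 30, relief = 80, seed = 31)
  withr::with_seed(37, {
    samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                              x = runif(4, 200, 1300),
                              y = runif(4, 200, 1300))
    cand <- tibble::tibble(x = runif(25, 100, 1400),
                           y = runif(25, 100, 1400))
    on <- ssd(dem, samples, cand, prune = TRUE)
    off <- ssd(dem, samples, cand, prune = FALSE)
    expect_equal(on$ssd_m, off$ssd_m, tolerance = 1e-12)
    expect_equal(on$nearest_x, off$nearest_x)
    expect_gt(sum(on$n_candidates_pruned), 0)
    expect_equal(sum(off$n_candidates_pruned), 0)
    # invariant: surface distance at least the planimetric distance
    for (i in 1:4) {
      plan_min <- min(sqrt((cand$x - samples$x[i])^2 +
                             (cand$y - samples$y[i])^2))
      expect_gte(on$ssd_m[i], plan_min - 1e-9)
    }
  })
})

test_that("single flat candidate returns its planimetric distance", {
  dem <- flat_dem(n = 60)
  out <- ssd(dem, tibble::tibble(sample_id = "s", x = 100, y = 900),
             tibble::tibble(x = 1100, y = 900))
  expect_equal(out$ssd_m, 1000)
  expect_equal(out$ssd_km, 1)
  expect_error(ssd(dem, tibble::tibble(sample_id = "s", x = 1, y = 1),
                   tibble::tibble(x = numeric(), y = numeric())),
               class = "behavsyn_empty_data_error")
})
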