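# A one-row toy grid: two land-adjacent cells then open ocean, 1/3 degree.
toy_path_grid <- function(v_by_cell, path_lat = 39.3, weeks = 1) {
  lons <- -74 + (seq_along(v_by_cell) - 1) / 3
  tidyr::expand_grid(time = as.Date("2000-01-05") + 7 * (seq_len(weeks) - 1),
                     lon = lons) |>
    dplyr::mutate(lat = 39 + 1 / 3, land = FALSE,
                  u_cm_s = 0,
                  v_cm_s = rep(v_by_cell, weeks))
}

test_that("the path discards 2 coastal cells and averages the remaining 4", {
  g <- toy_path_grid(c(9, 9, -4, -6, -2, -8))
  pv <- path_velocity(g)
  expect_equal(pv$v_cm_s, mean(c(-4, -6, -2, -8)))
  expect_equal(pv$v_cm_s, -5)
  expect_length(attr(pv, "cells"), 4L)
  # a uniform field passes through unchanged
  expect_equal(path_velocity(toy_path_grid(rep(-5, 8)))$v_cm_s, -5)
})

test_that("path velocity is linear in the field and errors on bad input", {
  g <- toy_path_grid(c(9, 9, -4, -6, -2, -8), weeks = 3)
  g2 <- dplyr::mutate(g, v_cm_s = 2 * v_cm_s)
  expect_equal(path_velocity(g2)$v_cm_s, 2 * path_velocity(g)$v_cm_s)
  gna <- g
  gna$v_cm_s[gna$lon == max(gna$lon)] <- NA
  expect_error(path_velocity(gna), "missing velocities")
  expect_error(path_velocity(g, path_lat = 50), "outside the grid")
  expect_error(path_velocity(toy_path_grid(rep(-5, 4))), "ocean cells")
})

test_that("bi-monthly aggregation averages by timestamp month", {
  x <- tibble::tibble(
    time = as.Date(c("2000-01-05", "2000-01-12", "2000-02-20", "2000-03-02")),
    v_cm_s = c(-3, -3, -3, 7))
  bi <- to_bimonthly(x)
  expect_equal(bi$v_cm_s[bi$bin == 1], -3)
  expect_equal(bi$v_cm_s[bi$bin == 2], 7)  # boundary week by its month
  expect_true(all(is.na(bi$v_cm_s[bi$bin > 2])))
  # generator truth: constant field aggregates to the constant
  truth <- synthetic_truth(seed = 2, velocity_years = c(1995L, 1996L),
                           sd_interannual = 0, sd_week = 0,
                           coupling_gsnwi_velocity = 0)
  g <- generate_velocity_grid(truth, lat_range = c(38.5, 40),
                              lon_range = c(-74.5, -71.5))
  bi2 <- to_bimonthly(path_velocity(g))
  expect_equal(bi2$v_cm_s, rep(truth$mean_alongshore, 12))
})

test_that("annual cumulative components split sign and sum to the total", {
  bi <- tibble::tibble(year = 2000L, bin = 1:2, v_cm_s = c(2, -3))
  ac <- annual_cumulative(bi)
  expect_equal(ac$north_sum, 2)
  expect_equal(ac$south_sum, -3)
  expect_true(ac$partial)  # only 2 of 6 bins present
  all_south <- tibble::tibble(year = 2001L, bin = 1:6, v_cm_s = -(1:6))
  expect_equal(annual_cumulative(all_south)$north_sum, 0)
  # identity over random series
  set.seed(5)
  rnd <- tidyr::expand_grid(year = 1995:1999, bin = 1:6) |>
    dplyr::mutate(v_cm_s = rnorm(30))
  ac2 <- annual_cumulative(rnd)
  expect_equal(ac2$north_sum + ac2$south_sum, ac2$total, tolerance = 1e-12)
  expect_true(all(ac2$north_sum >= 0) && all(ac2$south_sum <= 0))
})

test_that("degenerate PCA on identical series gives equal weights", {
  months <- seq(as.Date("1990-01-01"), by = "month", length.out = 36)
  base <- sin(seq_len(36) / 3) + seq_len(36) / 40
  nw <- tibble::tibble(date = months,
                       lat_79W = base, lat_75W = base, lat_72W = base,
                       lat_70W = base, lat_67W = base, lat_65W = base)
  gs <- gsnwi(nw)
  expect_equal(unname(attr(gs, "weights")), rep(1 / 6, 6), tolerance = 1e-10)
  expect_equal(gs$index, as.numeric(scale(base)), tolerance = 1e-10)
})

test_that("the index tracks the common signal better than any longitude", {
  truth <- synthetic_truth(seed = 17)
  nw <- generate_northwall(truth, noise_sd = 0.5)
  sig <- attr(nw, "gs_signal")$value
  gs <- gsnwi(nw)
  cor_idx <- cor(gs$index, sig)
  cor_each <- as.numeric(cor(as.matrix(nw[, -1]), sig))
  expect_true(all(cor_idx > cor_each))
  # every input series correlates positively with the index
  expect_true(all(cor(as.matrix(nw[, -1]), gs$index) > 0))
  expect_true(abs(sum(attr(gs, "weights")) - 1) < 1e-12)
})

test_that("the index is invariant to affine rescaling of an input series", {
  truth <- synthetic_truth(seed = 19)
  nw <- generate_northwall(truth)
  nw2 <- dplyr::mutate(nw, lat_72W = 2.5 * .data$lat_72W - 40)
  expect_equal(gsnwi(nw2)$index, gsnwi(nw)$index, tolerance = 1e-10)
})

test_that("GSNWI input contracts are enforced", {
  months <- seq(as.Date("1990-01-01"), by = "month", length.out = 36)
  nw <- tibble::tibble(date = months, a = rnorm(36), b = rnorm(36))
  expect_error(gsnwi(nw), "exactly 6")
  nw6 <- tibble::tibble(date = months[1:12], a = rnorm(12), b = rnorm(12),
                        c = rnorm(12), d = rnorm(12), e = rnorm(12),
                        f = rnorm(12))
  expect_error(gsnwi(nw6), "24")
  nw7 <- tibble::tibble(date = months, a = rnorm(36), b = rnorm(36),
                        c = rnorm(36), d = rnorm(36), e = rnorm(36),
                        f = 1)
  expect_error(gsnwi(nw7), "zero SD")
})
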