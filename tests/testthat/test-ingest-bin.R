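test_that("bi-monthly assignment follows the calendar", {
  expect_equal(assign_bimonthly(as.Date("1985-01-15")),
               tibble::tibble(year = 1985L, bin = 1L))
  expect_equal(assign_bimonthly(as.Date("1985-12-31")),
               tibble::tibble(year = 1985L, bin = 6L))
  expect_error(assign_bimonthly("not-a-date"), "invalid date")
})

test_that("a survey is binned by its midpoint, not its tow dates", {
  # cruise spanning Feb 20 - Mar 10: midpoint Mar 1 -> whole survey in bin 2
  samples <- tibble::tibble(
    cruise_id = "C1", station_id = c("s1", "s2"),
    date = as.Date(c("1985-02-20", "1985-03-10")),
    lat = c(43, 43.5), lon = c(-68, -67), species = "CFIN",
    abundance = c(10, 30), temp = c(4, 5))
  ser <- build_series(samples, "CFIN", "GOM", years = c(1985L, 1985L))
  expect_equal(ser$mean_abundance[ser$bin == 2], 20)
  expect_true(all(is.na(ser$mean_abundance[ser$bin != 2])))
  expect_equal(sum(ser$n_samples), 2L)
})

test_that("region assignment respects containment, exclusion and priority", {
  expect_equal(assign_region(43, -68), "GOM")
  expect_true(is.na(assign_region(34, -76)))
  # a point on the shared GOM/GB latitude edge goes to the region listed first
  regions <- default_regions(c("GOM", "GB"))
  expect_equal(assign_region(42, -68, regions), "GOM")
  regions_rev <- region_spec(rev(regions$boundary))
  expect_equal(assign_region(42, -68, regions_rev), "GB")
  # overlapping interiors are rejected at validation time
  expect_error(region_spec(list(
    A = list(lat = c(40, 42), lon = c(-70, -68)),
    B = list(lat = c(41, 43), lon = c(-69, -67)))), "overlapping")
})

test_that("latitude bands are half-open two-degree bins on 35-45N", {
  expect_equal(bin_latitude(35.5), "[35,37)")
  expect_equal(bin_latitude(37.0), "[37,39)")
  expect_equal(bin_latitude(43.2), "[43,45)")
  expect_true(is.na(bin_latitude(34.9)))
  expect_true(is.na(bin_latitude(45)))
})

test_that("full synthetic coverage gives 198 bins and the gap 18 missing", {
  truth <- synthetic_truth(seed = 1, stations_per_bin = 2L)
  s <- generate_abundance(truth)
  for (rg in c("GOM", "MAB")) {
    ser <- build_series(s, "CFIN", rg, years = c(1977L, 2009L))
    expect_equal(nrow(ser), 198L)
  }
  mab <- build_series(s, "CTYP", "MAB", years = c(1977L, 2009L))
  gap <- is.na(mab$mean_abundance)
  expect_equal(sum(gap), 18L)
  expect_true(all(mab$year[gap] %in% 1989:1991))
})

test_that("bin means, sample conservation and permutation invariance hold", {
  samples <- tibble::tibble(
    cruise_id = "C1", station_id = paste0("s", 1:3),
    date = as.Date("1990-05-10") + 0:2,
    lat = 43.1, lon = -67.5, species = "CFIN",
    abundance = c(10, 20, 30), temp = 6)
  ser <- build_series(samples, "CFIN", "GOM", years = c(1990L, 1990L))
  expect_equal(ser$mean_abundance[ser$bin == 3], 20)
  expect_equal(sum(ser$n_samples), nrow(samples))
  shuffled <- samples[c(3, 1, 2), ]
  expect_equal(build_series(shuffled, "CFIN", "GOM",
                            years = c(1990L, 1990L)), ser)
})

test_that("missing is not zero", {
  base <- tibble::tibble(
    cruise_id = "C1", station_id = "s1", date = as.Date("1990-05-10"),
    lat = 43.1, lon = -67.5, species = "CFIN", abundance = 10, temp = 6)
  with_zero <- dplyr::bind_rows(base, dplyr::mutate(
    base, station_id = "s2", abundance = 0))
  s1 <- build_series(base, "CFIN", "GOM", years = c(1990L, 1990L))
  s2 <- build_series(with_zero, "CFIN", "GOM", years = c(1990L, 1990L))
  expect_equal(s1$mean_abundance[s1$bin == 3], 10)
  expect_equal(s2$mean_abundance[s2$bin == 3], 5)
  # deleting the region's samples makes the bin missing, not zero
  other <- dplyr::mutate(base, lat = 40.8, lon = -66)  # GB, not GOM
  s3 <- build_series(other, "CFIN", "GOM", years = c(1990L, 1990L))
  expect_true(all(is.na(s3$mean_abundance)))
  expect_error(build_series(base[0, ], "CFIN", "GOM"), "empty sample set")
})

test_that("temperature series averages stations and recovers the truth", {
  samples <- tibble::tibble(
    cruise_id = "C1", station_id = paste0("s", 1:2),
    date = as.Date("1990-01-10") + 0:1,
    lat = 43.1, lon = -67.5, species = "CFIN",
    abundance = 1, temp = c(5, 7))
  ts1 <- build_temperature_series(samples, "GOM", years = c(1990L, 1990L))
  expect_equal(ts1$mean_temp[ts1$bin == 1], 6)
  samples$temp <- NA_real_
  ts2 <- build_temperature_series(samples, "GOM", years = c(1990L, 1990L))
  expect_true(is.na(ts2$mean_temp[ts2$bin == 1]))
  # noiseless generator: bin means equal the configured seasonal cycle
  truth <- synthetic_truth(seed = 9, years = c(1996L, 1997L), temp_sd = 0,
                           stations_per_bin = 2L, gap_spec = list())
  s <- generate_abundance(truth)
  tg <- build_temperature_series(s, "GB", years = c(1996L, 1997L))
  expected <- truth$temp_mean[["GB"]] +
    truth$temp_amplitude[["GB"]] * cos(2 * pi * (tg$bin - 4) / 6)
  expect_equal(tg$mean_temp, expected, tolerance = 1e-10)
})

test_that("sample CSV round-trips through the documented schema", {
  truth <- small_truth(seed = 21)
  s <- generate_abundance(truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(s, path)
  s2 <- read_samples_csv(path)
  expect_equal(s2$abundance, s$abundance, tolerance = 1e-12)
  expect_equal(s2$date, s$date)
  expect_equal(s2$species, s$species)
})

test_that("invalid samples are rejected", {
  bad <- tibble::tibble(
    cruise_id = "C1", station_id = "s1", date = as.Date("1990-01-10"),
    lat = 20, lon = -67.5, species = "CFIN", abundance = 1, temp = 5)
  expect_error(build_series(bad, "CFIN", "GOM"), "latitude")
  bad$lat <- 43; bad$abundance <- -1
  expect_error(build_series(bad, "CFIN", "GOM"), "abundance")
})
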