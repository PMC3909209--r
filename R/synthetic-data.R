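#' Ground-truth parameters for the synthetic survey world
#'
#' Bundles every parameter of the synthetic data generator: regional mean
#' abundance levels with a slow multi-year trend, per-region trigonometric
#' seasonal cycles with a north--south amplitude gradient, AR(1) bin-level
#' noise, station-level observation noise, the southern survey gap, the mean
#' southward alongshore flow, and the (negative) coupling between the Gulf
#' Stream north-wall signal and the alongshore velocity. Identical seed and
#' parameters give bit-identical output from every generator.
#'
#' Default magnitudes are chosen to resemble shelf copepod surveys (regional
#' means of order 50--500 ind m\eqn{^{-3}}) without claiming to reproduce any
#' real series. The default seasonal truth moves the Mid-Atlantic Bight
#' *Centropages typicus* peak from Nov--Dec (bin 6) to Jan--Feb (bin 1)
#' starting in `peak_shift_year + 1`, emulating a phenology shift.
#'
#' @param seed integer seed; all generators derive their streams from it.
#' @param years inclusive survey year span `c(first, last)`.
#' @param velocity_years inclusive year span of the weekly velocity grid.
#' @param species species codes (default `"CFIN"`, `"CTYP"`).
#' @param regions region names, ordered by tie-break priority.
#' @param levels named-by-species list of named-by-region mean abundance
#'   levels (ind m^-3).
#' @param seasonal_amplitude same shape: seasonal peak height above the trend
#'   (ind m^-3).
#' @param peak_bin same shape: bi-monthly bin (1-6) of the seasonal peak.
#' @param peak_shift optional `list(species=, region=, year=, to_bin=)`:
#'   from `year + 1` onward the named series peaks in `to_bin` instead.
#' @param trend_rel_amplitude relative amplitude of the slow sinusoidal
#'   multi-year trend around each level (dimensionless).
#' @param trend_period_years period of that slow trend (years).
#' @param phi_true trend AR(1) autocorrelation, in (0, 1].
#' @param sigma_eta trend innovation SD (ind m^-3).
#' @param sigma_eps station observation SD (ind m^-3), applied as lognormal
#'   multiplicative noise around the bin mean.
#' @param gap_spec list of `list(region=, years=c(from, to))` with no samples.
#' @param stations_per_bin stations per region per bi-monthly survey (>= 0).
#' @param mean_alongshore mean alongshore (northward) velocity, cm s^-1;
#'   negative = southward.
#' @param coupling_gsnwi_velocity cm s^-1 per unit of the standardized
#'   north-wall signal; negative mimics the observed relationship.
#' @param sd_interannual SD of the per-year velocity anomaly (cm s^-1).
#' @param sd_week SD of weekly white noise in the velocity field (cm s^-1).
#' @param northwall_base latitudes (deg N) of the north wall at the six
#'   longitudes 79, 75, 72, 70, 67, 65 deg W.
#' @param northwall_signal_deg degrees of north-wall displacement per unit of
#'   the common signal.
#' @param northwall_noise_sd per-longitude independent noise SD (deg).
#' @param temp_mean,temp_amplitude named-by-region upper-3 m temperature mean
#'   and seasonal amplitude (deg C); the cycle peaks in Jul-Aug (bin 4).
#' @param temp_sd station temperature noise SD (deg C).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    seed = 1L,
    years = c(1977L, 2009L),
    velocity_years = c(1993L, 2010L),
    species = c("CFIN", "CTYP"),
    regions = c("GOM", "GB", "SNE", "MAB"),
    levels = list(
      CFIN = c(GOM = 230, GB = 180, SNE = 150, MAB = 55),
      CTYP = c(GOM = 170, GB = 210, SNE = 340, MAB = 490)),
    seasonal_amplitude = list(
      CFIN = c(GOM = 200, GB = 160, SNE = 120, MAB = 40),
      CTYP = c(GOM = 120, GB = 150, SNE = 250, MAB = 380)),
    peak_bin = list(
      CFIN = c(GOM = 3, GB = 3, SNE = 3, MAB = 3),
      CTYP = c(GOM = 6, GB = 6, SNE = 6, MAB = 6)),
    peak_shift = list(species = "CTYP", region = "MAB", year = 1985L,
                      to_bin = 1L),
    trend_rel_amplitude = 0.2,
    trend_period_years = 22,
    phi_true = 0.95,
    sigma_eta = 5,
    sigma_eps = 30,
    gap_spec = list(list(region = "MAB", years = c(1989L, 1991L)),
                    list(region = "SNE", years = c(1989L, 1991L))),
    stations_per_bin = 6L,
    mean_alongshore = -5,
    coupling_gsnwi_velocity = -1.5,
    sd_interannual = 2,
    sd_week = 4,
    northwall_base = c(35.2, 36.9, 38.3, 39.5, 40.4, 41.0),
    northwall_signal_deg = 0.5,
    northwall_noise_sd = 0.3,
    temp_mean = c(GOM = 9, GB = 10, SNE = 12, MAB = 14),
    temp_amplitude = c(GOM = 5, GB = 6, SNE = 7, MAB = 8),
    temp_sd = 0.8) {
  truth <- structure(
    list(seed = as.integer(seed), years = as.integer(years),
         velocity_years = as.integer(velocity_years), species = species,
         regions = regions, levels = levels,
         seasonal_amplitude = seasonal_amplitude, peak_bin = peak_bin,
         peak_shift = peak_shift,
         trend_rel_amplitude = trend_rel_amplitude,
         trend_period_years = trend_period_years,
         phi_true = phi_true, sigma_eta = sigma_eta, sigma_eps = sigma_eps,
         gap_spec = gap_spec, stations_per_bin = as.integer(stations_per_bin),
         mean_alongshore = mean_alongshore,
         coupling_gsnwi_velocity = coupling_gsnwi_velocity,
         sd_interannual = sd_interannual, sd_week = sd_week,
         northwall_base = northwall_base,
         northwall_signal_deg = northwall_signal_deg,
         northwall_noise_sd = northwall_noise_sd,
         temp_mean = temp_mean, temp_amplitude = temp_amplitude,
         temp_sd = temp_sd),
    class = "synthetic_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$years) != 2L || truth$years[2] < truth$years[1]) {
    stop("empty year span")
  }
  if (!(truth$phi_true > 0 && truth$phi_true <= 1)) {
    stop("phi_true must be in (0, 1]")
  }
  if (truth$sigma_eta < 0 || truth$sigma_eps < 0 || truth$temp_sd < 0 ||
      truth$northwall_noise_sd < 0 || truth$sd_interannual < 0 ||
      truth$sd_week < 0) {
    stop("all SDs must be >= 0")
  }
  if (truth$stations_per_bin < 0) stop("stations_per_bin must be >= 0")
  if (length(truth$northwall_base) != 6L) {
    stop("northwall_base must give latitudes at exactly 6 longitudes")
  }
  invisible(truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic survey truth: seed", x$seed, "| years",
      paste(x$years, collapse = "-"), "\n")
  cat("  species:", paste(x$species, collapse = ", "),
      "| regions:", paste(x$regions, collapse = ", "), "\n")
  cat(sprintf("  phi = %.2f, sigma_eta = %.1f, sigma_eps = %.1f, %d stations/bin\n",
              x$phi_true, x$sigma_eta, x$sigma_eps, x$stations_per_bin))
  invisible(x)
}

# Seasonal coefficients (a1, b1, a2, b2, a3) placing a single-harmonic peak
# of the given height at the given bi-monthly bin.
seasonal_peak_coef <- function(amplitude, peak_bin) {
  w <- 2 * pi / 6
  c(a1 = amplitude * cos(w * peak_bin), b1 = amplitude * sin(w * peak_bin),
    a2 = 0, b2 = 0, a3 = 0)
}

# Deterministic multi-year trend level (ind m^-3) at a decimal year.
truth_trend <- function(truth, species, region, year_frac) {
  lv <- truth$levels[[species]][[region]]
  lv * (1 + truth$trend_rel_amplitude *
          sin(2 * pi * (year_frac - truth$years[1]) / truth$trend_period_years))
}

# Seasonal coefficient vector for a species/region/calendar-year, honouring
# the configured peak shift.
truth_seasonal_coef <- function(truth, species, region, year) {
  pk <- truth$peak_bin[[species]][[region]]
  ps <- truth$peak_shift
  if (!is.null(ps) && identical(ps$species, species) &&
      identical(ps$region, region) && year > ps$year) {
    pk <- ps$to_bin
  }
  seasonal_peak_coef(truth$seasonal_amplitude[[species]][[region]], pk)
}

# Evaluate the seasonal component at global bin index t for calendar year.
truth_seasonal <- function(truth, species, region, year, t) {
  co <- truth_seasonal_coef(truth, species, region, year)
  B <- harmonic_basis(t, 6L, 3L)
  as.numeric(B %*% co[colnames(B)])
}

# Common monthly Gulf-Stream-north-wall signal shared by the north-wall and
# velocity generators: standardized AR(1), deterministic given the seed.
gs_common_signal <- function(truth) {
  y0 <- min(truth$years[1], truth$velocity_years[1])
  y1 <- max(truth$years[2], truth$velocity_years[2])
  months <- seq(as.Date(sprintf("%d-01-01", y0)),
                as.Date(sprintf("%d-12-01", y1)), by = "month")
  n <- length(months)
  g <- withr::with_seed(truth$seed + 7919L, {
    e <- rnorm(n)
    x <- numeric(n)
    x[1] <- e[1] / sqrt(1 - 0.9^2)
    for (t in 2:n) x[t] <- 0.9 * x[t - 1] + e[t]
    as.numeric(scale(x))
  })
  tibble::tibble(date = months, value = g)
}

#' Generate station-level plankton samples with known ground truth
#'
#' Emulates bi-monthly shelf-wide bongo surveys: one synthetic cruise per
#' bi-monthly period covers every region (except regions in `gap_spec` during
#' their gap years) with `stations_per_bin` stations each. The bin-level
#' abundance for each species x region is a deterministic multi-year trend
#' plus a 12-month trigonometric seasonal cycle plus AR(1) noise
#' (`phi_true`, `sigma_eta`); station values add lognormal multiplicative
#' observation noise calibrated to an additive SD of `sigma_eps` and are
#' truncated at zero. Station temperature follows a seasonal cycle peaking in
#' Jul--Aug.
#'
#' @param truth a [synthetic_truth()].
#' @return tibble of samples (`cruise_id`, `station_id`, `date`, `lat`,
#'   `lon`, `species`, `abundance`, `temp`) with the bin-level ground truth
#'   attached as `attr(, "truth_bins")`.
#' @export
generate_abundance <- function(truth) {
  validate_truth(truth)
  if (truth$stations_per_bin == 0L) {
    stop("stations_per_bin is 0: no samples to generate")
  }
  years <- seq(truth$years[1], truth$years[2])
  n_bins <- length(years) * 6L
  grid <- expand.grid(bin = 1:6, year = years)[, c("year", "bin")]
  grid$t <- seq_len(n_bins)

  regions <- default_regions(truth$regions)
  gap_key <- unlist(lapply(truth$gap_spec, function(g) {
    paste(g$region, seq(g$years[1], g$years[2]))
  }))

  withr::with_seed(truth$seed, {
    # bin-level AR(1) noise per species x region
    truth_bins <- list()
    for (sp in truth$species) {
      for (rg in truth$regions) {
        e <- numeric(n_bins)
        if (truth$sigma_eta > 0) {
          z <- rnorm(n_bins, sd = truth$sigma_eta)
          e[1] <- if (truth$phi_true < 1) {
            z[1] / sqrt(1 - truth$phi_true^2)
          } else 0
          for (t in 2:n_bins) e[t] <- truth$phi_true * e[t - 1] + z[t]
        }
        yf <- grid$year + (grid$bin - 0.5) / 6
        tr <- truth_trend(truth, sp, rg, yf)
        se <- vapply(seq_len(n_bins), function(i) {
          truth_seasonal(truth, sp, rg, grid$year[i], grid$t[i])
        }, numeric(1))
        truth_bins[[paste(sp, rg)]] <- tibble::tibble(
          species = sp, region = rg, year = grid$year, bin = grid$bin,
          t = grid$t, trend = tr, seasonal = se, ar_noise = e,
          latent = tr + se + e)
      }
    }
    truth_bins <- dplyr::bind_rows(truth_bins)

    rows <- list()
    for (i in seq_len(nrow(grid))) {
      yr <- grid$year[i]; bn <- grid$bin[i]
      cruise <- sprintf("SYN%d%02d", yr, bn)
      m1 <- 2L * bn - 1L
      first <- as.Date(sprintf("%d-%02d-01", yr, m1))
      # last day of the two-month window
      last <- seq(first, by = "2 months", length.out = 2)[2] - 1
      ndays <- as.integer(last - first)
      for (rg in truth$regions) {
        if (paste(rg, yr) %in% gap_key) next
        rect <- regions$boundary[[rg]]
        ns <- truth$stations_per_bin
        lat <- runif(ns, rect$lat[1] + 0.05, rect$lat[2] - 0.05)
        lon <- runif(ns, rect$lon[1] + 0.05, rect$lon[2] - 0.05)
        dates <- first + sample.int(ndays + 1L, ns, replace = TRUE) - 1L
        temp <- truth$temp_mean[[rg]] +
          truth$temp_amplitude[[rg]] * cos(2 * pi * (bn - 4) / 6) +
          if (truth$temp_sd > 0) rnorm(ns, sd = truth$temp_sd) else 0
        for (sp in truth$species) {
          lat_bin <- truth_bins$latent[truth_bins$species == sp &
                                         truth_bins$region == rg &
                                         truth_bins$t == grid$t[i]]
          ab <- if (lat_bin > 0 && truth$sigma_eps > 0) {
            sl2 <- log1p((truth$sigma_eps / lat_bin)^2)
            lat_bin * exp(rnorm(ns, sd = sqrt(sl2)) - sl2 / 2)
          } else {
            rep(max(0, lat_bin), ns)
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cruise_id = cruise,
            station_id = sprintf("%s-%s-%02d", cruise, rg, seq_len(ns)),
            date = dates, lat = lat, lon = lon, species = sp,
            abundance = pmax(0, ab), temp = temp)
        }
      }
    }
    samples <- dplyr::bind_rows(rows)
    attr(samples, "truth_bins") <- truth_bins
    samples
  })
}

#' Generate a weekly gridded velocity field
#'
#' Weekly eastward/northward velocity components on a 1/3-degree grid.
#' Northward component = `mean_alongshore` + a per-year interannual anomaly +
#' `coupling_gsnwi_velocity` x (standardized monthly north-wall signal) +
#' weekly white noise. Cells west of a linear synthetic coastline are land
#' (`land = TRUE`, velocities `NA`).
#'
#' @param truth a [synthetic_truth()].
#' @param lat_range,lon_range grid extents (cell centers, degrees); defaults
#'   cover 35--45 deg N.
#' @return tibble (`time`, `lat`, `lon`, `u_cm_s`, `v_cm_s`, `land`) with the
#'   monthly forcing signal attached as `attr(, "gs_signal")` and the
#'   per-year anomalies as `attr(, "year_anomaly")`.
#' @export
generate_velocity_grid <- function(truth, lat_range = c(35, 45),
                                   lon_range = c(-75, -71)) {
  validate_truth(truth)
  vy <- truth$velocity_years
  if (vy[1] < 1992L || vy[2] > 2011L) {
    message("velocity span ", vy[1], "-", vy[2],
            " lies outside the 1992-2011 altimetry analogue")
  }
  weeks <- seq(as.Date(sprintf("%d-01-06", vy[1])),
               as.Date(sprintf("%d-12-28", vy[2])), by = 7)
  lat <- seq(lat_range[1], lat_range[2], by = 1 / 3)
  lon <- seq(lon_range[1], lon_range[2], by = 1 / 3)
  sig <- gs_common_signal(truth)
  sig_key <- format(sig$date, "%Y-%m")
  g_week <- sig$value[match(format(weeks, "%Y-%m"), sig_key)]
  yrs <- as.integer(format(weeks, "%Y"))

  grid <- withr::with_seed(truth$seed + 2L, {
    year_anom <- setNames(
      if (truth$sd_interannual > 0) {
        rnorm(length(unique(yrs)), sd = truth$sd_interannual)
      } else rep(0, length(unique(yrs))),
      unique(yrs))
    cells <- expand.grid(lon = lon, lat = lat)
    coast_lon <- -75.1 + 0.2 * (cells$lat - 35)
    land <- cells$lon <= coast_lon
    nc <- nrow(cells); nw <- length(weeks)
    out <- tibble::tibble(
      time = rep(weeks, each = nc),
      lat = rep(cells$lat, nw),
      lon = rep(cells$lon, nw),
      land = rep(land, nw))
    base_v <- truth$mean_alongshore +
      rep(year_anom[as.character(yrs)], each = nc) +
      truth$coupling_gsnwi_velocity * rep(g_week, each = nc)
    out$v_cm_s <- base_v +
      if (truth$sd_week > 0) rnorm(nrow(out), sd = truth$sd_week) else 0
    out$u_cm_s <- if (truth$sd_week > 0) {
      rnorm(nrow(out), sd = truth$sd_week / 2)
    } else rep(0, nrow(out))
    out$u_cm_s[out$land] <- NA_real_
    out$v_cm_s[out$land] <- NA_real_
    attr(out, "year_anomaly") <- year_anom
    out
  })
  attr(grid, "gs_signal") <- sig
  grid
}

#' Generate the monthly Gulf Stream north-wall latitude series
#'
#' Monthly north-wall latitude at the six longitudes 79, 75, 72, 70, 67 and
#' 65 deg W: a shared standardized signal scaled to `northwall_signal_deg`
#' around each longitude's base latitude, plus independent per-longitude
#' noise.
#'
#' @param truth a [synthetic_truth()].
#' @param noise_sd override for the per-longitude noise SD (deg).
#' @return tibble with `date` and columns `lat_79W`, `lat_75W`, `lat_72W`,
#'   `lat_70W`, `lat_67W`, `lat_65W`; the common signal is attached as
#'   `attr(, "gs_signal")`.
#' @export
generate_northwall <- function(truth, noise_sd = truth$northwall_noise_sd) {
  validate_truth(truth)
  sig <- gs_common_signal(truth)
  lons <- c(79, 75, 72, 70, 67, 65)
  out <- withr::with_seed(truth$seed + 3L, {
    cols <- lapply(seq_along(lons), function(j) {
      truth$northwall_base[j] + truth$northwall_signal_deg * sig$value +
        if (noise_sd > 0) rnorm(nrow(sig), sd = noise_sd) else 0
    })
    names(cols) <- paste0("lat_", lons, "W")
    tibble::tibble(date = sig$date, !!!cols)
  })
  attr(out, "gs_signal") <- sig
  out
}

#' Simulate a bi-monthly series directly from the structural model
#'
#' Draws one series from the model fitted by [fit_structural()]: a zero-mean
#' stationary AR(1) trend (random walk from zero when `phi = 1`), a fixed
#' trigonometric seasonal cycle, and white observation noise. Used for
#' parameter-recovery experiments where the data-generating process must be
#' the model itself.
#'
#' @param n series length in bins.
#' @param phi trend autocorrelation in (0, 1].
#' @param sigma_eta trend innovation SD.
#' @param sigma_eps observation noise SD.
#' @param seasonal_amplitude peak height of the seasonal cycle.
#' @param peak_bin bin (1-6) of the seasonal peak.
#' @param level constant added to the trend (default 0, matching the model's
#'   zero-mean trend).
#' @param start_year first calendar year of the series.
#' @param seed integer seed.
#' @return series tibble (`year`, `bin`, `mean_abundance`) with true `mu` and
#'   `gamma` attached as `attr(, "truth")`.
#' @export
simulate_bin_series <- function(n = 198L, phi = 0.95, sigma_eta = 5,
                                sigma_eps = 30, seasonal_amplitude = 100,
                                peak_bin = 3L, level = 0, start_year = 1977L,
                                seed = 1L) {
  stopifnot(n >= 6, phi > 0, phi <= 1, sigma_eta >= 0, sigma_eps >= 0)
  co <- seasonal_peak_coef(seasonal_amplitude, peak_bin)
  B <- harmonic_basis(seq_len(n), 6L, 3L)
  gamma <- as.numeric(B %*% co[colnames(B)])
  withr::with_seed(as.integer(seed), {
    mu <- numeric(n)
    z <- rnorm(n, sd = sigma_eta)
    mu[1] <- if (phi < 1) z[1] / sqrt(1 - phi^2) else 0
    for (t in 2:n) mu[t] <- phi * mu[t - 1] + z[t]
    mu <- mu + level
    y <- mu + gamma + rnorm(n, sd = sigma_eps)
    out <- tibble::tibble(
      year = start_year + (seq_len(n) - 1L) %/% 6L,
      bin = (seq_len(n) - 1L) %% 6L + 1L,
      mean_abundance = y)
    attr(out, "truth") <- list(mu = mu, gamma = gamma, phi = phi,
                               sigma_eta = sigma_eta, sigma_eps = sigma_eps,
                               coef = co)
    out
  })
}
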