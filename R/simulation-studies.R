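#' Monte-Carlo parameter-recovery experiment
#'
#' Simulates `n_series` bi-monthly series from the structural model at the
#' given truth (via [simulate_bin_series()]) and refits each with
#' [fit_structural()], returning the estimated trend autocorrelation and
#' seasonal amplitude per replicate. Summarise with, e.g., the median
#' absolute error of `phi_hat` and the median relative error of
#' `amplitude_hat`.
#'
#' @param n_series number of simulated series.
#' @param n series length in bins.
#' @param phi,sigma_eta,sigma_eps,seasonal_amplitude,peak_bin simulation
#'   truth, passed to [simulate_bin_series()].
#' @param seed integer; replicate k uses seed `seed + k`.
#' @param n_starts optimizer starts per fit (the simulated-likelihood surface
#'   is well behaved, so fewer starts than the default are adequate).
#' @return tibble (`rep`, `phi_hat`, `sigma2_eta_hat`, `sigma2_eps_hat`,
#'   `amplitude_hat`, `converged`).
#' @export
recovery_experiment <- function(n_series = 200L, n = 198L, phi = 0.95,
                                sigma_eta = 5, sigma_eps = 30,
                                seasonal_amplitude = 100, peak_bin = 3L,
                                seed = 1L, n_starts = 3L) {
  rows <- lapply(seq_len(n_series), function(k) {
    sim <- simulate_bin_series(n = n, phi = phi, sigma_eta = sigma_eta,
                               sigma_eps = sigma_eps,
                               seasonal_amplitude = seasonal_amplitude,
                               peak_bin = peak_bin, seed = seed + k)
    f <- fit_structural(sim, n_starts = n_starts, seed = seed + k)
    tibble::tibble(rep = k, phi_hat = f$phi, sigma2_eta_hat = f$sigma2_eta,
                   sigma2_eps_hat = f$sigma2_eps,
                   amplitude_hat = seasonal_amplitude(f),
                   converged = f$converged)
  })
  dplyr::bind_rows(rows)
}

#' One GSNWI~velocity replicate at reduced grid size
#'
#' Generates a north-wall series and a narrow velocity grid around the
#' transport path from one truth, builds the GSNWI and the bi-monthly and
#' annual transport series, and regresses velocity on the index at both
#' timescales. Used for the null-calibration and coupling-sign simulation
#' studies.
#'
#' @param truth a [synthetic_truth()].
#' @return tibble of two [regress_pair()] rows (bimonthly, annual).
#' @export
gsnwi_velocity_replicate <- function(truth) {
  grid <- generate_velocity_grid(truth, lat_range = c(38.5, 40),
                                 lon_range = c(-74.5, -71.5))
  nw <- generate_northwall(truth)
  gs <- gsnwi(nw)
  transport <- to_bimonthly(path_velocity(grid))
  idx <- assign_bimonthly(gs$date)
  gs_bim <- tibble::tibble(year = idx$year, bin = idx$bin,
                           index = gs$index) |>
    dplyr::group_by(.data$year, .data$bin) |>
    dplyr::summarise(index = mean(.data$index), .groups = "drop")
  m <- dplyr::inner_join(transport, gs_bim, by = c("year", "bin"))
  m <- m[is.finite(m$v_cm_s) & is.finite(m$index), ]
  bim <- regress_pair(m$index, m$v_cm_s, response = "alongshore_velocity",
                      covariate = "gsnwi", timescale = "bimonthly")
  va <- annual_mean(transport, "v_cm_s")
  ga <- annual_mean(gs_bim, "index")
  ma <- dplyr::inner_join(va, ga, by = "year", suffix = c("_v", "_g"))
  ann <- regress_pair(ma$value_g, ma$value_v,
                      response = "alongshore_velocity",
                      covariate = "gsnwi", timescale = "annual")
  dplyr::bind_rows(bim, ann)
}
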