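#' Ordinary least-squares association between two paired series
#'
#' Pairs with a missing value in either series are removed; the remaining
#' complete pairs are fit by OLS, with Pearson r and the two-sided p-value
#' from the t distribution on n - 2 degrees of freedom.
#'
#' @param x covariate values.
#' @param y response values, same length.
#' @param response,covariate,region,timescale labels carried into the result.
#' @return one-row tibble (`response`, `covariate`, `region`, `timescale`,
#'   `n`, `slope`, `intercept`, `r`, `r_squared`, `p_value`).
#' @export
regress_pair <- function(x, y, response = "y", covariate = "x",
                         region = NA_character_, timescale = "annual") {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  if (sd(x) == 0) stop("zero-variance covariate")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r <- cor(x, y)
  pval <- sm$coefficients["x", "Pr(>|t|)"]
  tibble::tibble(
    response = response, covariate = covariate, region = region,
    timescale = timescale, n = n,
    slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
    r = r, r_squared = r^2, p_value = pval)
}

# Annual means of a bi-monthly series (NA bins dropped).
annual_mean <- function(bimonthly, value) {
  bimonthly |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(value = mean(.data[[value]], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
}

#' Full association table between biology and physical forcing
#'
#' Regresses annual peak abundance of every species in every sub-region (and
#' the across-region mean, `ENTIRE`) on the annual mean alongshore velocity,
#' the annual mean Gulf Stream North Wall Index, and the annual mean regional
#' temperature, and additionally regresses the alongshore velocity on the
#' GSNWI at both bi-monthly and annual scales. All results are returned,
#' none filtered by significance, and no multiple-testing correction is
#' applied.
#'
#' @param peaks peak-record tibble from [annual_peaks()] (rows for several
#'   species/regions stacked).
#' @param transport bi-monthly transport tibble (`year`, `bin`, `v_cm_s`).
#' @param gsnwi_series tibble (`date`, `index`) from [gsnwi()].
#' @param temperature optional stacked temperature tibble (`region`, `year`,
#'   `bin`, `mean_temp`).
#' @return tibble of [regress_pair()] rows.
#' @export
association_suite <- function(peaks, transport, gsnwi_series,
                              temperature = NULL) {
  stopifnot(all(c("species", "region", "year", "peak_value") %in%
                  names(peaks)))
  vel_ann <- annual_mean(transport, "v_cm_s")
  gs_idx <- assign_bimonthly(gsnwi_series$date)
  gs_bim <- tibble::tibble(year = gs_idx$year, bin = gs_idx$bin,
                           index = gsnwi_series$index) |>
    dplyr::group_by(.data$year, .data$bin) |>
    dplyr::summarise(index = mean(.data$index), .groups = "drop")
  gs_ann <- annual_mean(gs_bim, "index")

  peaks_all <- dplyr::bind_rows(
    peaks,
    peaks |>
      dplyr::group_by(.data$species, .data$year) |>
      dplyr::summarise(peak_value = mean(.data$peak_value),
                       .groups = "drop") |>
      dplyr::mutate(region = "ENTIRE"))

  temp_ann <- if (!is.null(temperature)) {
    ta <- temperature |>
      dplyr::group_by(.data$region, .data$year) |>
      dplyr::summarise(temp = mean(.data$mean_temp, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(temp = ifelse(is.nan(.data$temp), NA_real_, .data$temp))
    dplyr::bind_rows(
      ta,
      ta |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(temp = mean(.data$temp, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::mutate(region = "ENTIRE"))
  } else NULL

  rows <- list()
  for (sp in unique(peaks_all$species)) {
    for (rg in unique(peaks_all$region)) {
      pk <- peaks_all[peaks_all$species == sp & peaks_all$region == rg, ]
      if (nrow(pk) == 0) next
      resp <- paste0("peak_abundance_", sp)
      m <- dplyr::inner_join(pk, vel_ann, by = "year")
      if (nrow(m) >= 3 && sd(m$value, na.rm = TRUE) > 0) {
        rows[[length(rows) + 1L]] <- regress_pair(
          m$value, m$peak_value, response = resp,
          covariate = "alongshore_velocity", region = rg)
      }
      m <- dplyr::inner_join(pk, gs_ann, by = "year")
      if (nrow(m) >= 3 && sd(m$value, na.rm = TRUE) > 0) {
        rows[[length(rows) + 1L]] <- regress_pair(
          m$value, m$peak_value, response = resp,
          covariate = "gsnwi", region = rg)
      }
      if (!is.null(temp_ann)) {
        tr <- temp_ann[temp_ann$region == rg, ]
        m <- dplyr::inner_join(pk, tr, by = "year")
        m <- m[is.finite(m$temp), ]
        if (nrow(m) >= 3 && sd(m$temp) > 0) {
          rows[[length(rows) + 1L]] <- regress_pair(
            m$temp, m$peak_value, response = resp,
            covariate = "temperature", region = rg)
        }
      }
    }
  }

  # physical-physical rows: velocity ~ GSNWI at both timescales
  m <- dplyr::inner_join(transport, gs_bim, by = c("year", "bin"))
  m <- m[is.finite(m$v_cm_s) & is.finite(m$index), ]
  if (nrow(m) >= 3) {
    rows[[length(rows) + 1L]] <- regress_pair(
      m$index, m$v_cm_s, response = "alongshore_velocity",
      covariate = "gsnwi", timescale = "bimonthly")
  }
  m <- dplyr::inner_join(vel_ann, gs_ann, by = "year",
                         suffix = c("_v", "_g"))
  m <- m[is.finite(m$value_v) & is.finite(m$value_g), ]
  if (nrow(m) >= 3) {
    rows[[length(rows) + 1L]] <- regress_pair(
      m$value_g, m$value_v, response = "alongshore_velocity",
      covariate = "gsnwi", timescale = "annual")
  }

  if (length(rows) == 0) stop("no overlapping years between inputs")
  dplyr::bind_rows(rows)
}
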