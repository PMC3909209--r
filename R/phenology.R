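#' Annual peak abundance and timing from a fitted series
#'
#' For each calendar year of the fit, the peak value is the maximum of the
#' fitted series (smoothed trend + seasonal) over the year's six bi-monthly
#' bins and the peak bin is its argmax; exact ties go to the earliest bin.
#' Years with fewer than six fitted bins (period boundaries) are flagged
#' `partial`. Peaks are taken from the fitted, not observed, series so that
#' missing bins do not distort timing; set `use_observed = TRUE` to compare.
#'
#' @param fit a converged [fit_structural()] result carrying year/bin data.
#' @param use_observed take peaks from the observed series instead.
#' @return tibble (`species`, `region`, `period_label`, `year`, `peak_bin`,
#'   `peak_value`, `partial`).
#' @export
annual_peaks <- function(fit, use_observed = FALSE) {
  stopifnot(inherits(fit, "structural_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; no peaks extracted")
  d <- fit$data
  if (all(is.na(d$year))) stop("fit carries no year/bin index")
  vals <- if (use_observed) d$observed else fit$fitted
  out <- tibble::tibble(year = d$year, bin = d$bin, value = vals) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      peak_bin = .data$bin[which.max(.data$value)],
      peak_value = max(.data$value),
      partial = dplyr::n() < 6L,
      .groups = "drop")
  tibble::tibble(species = fit$species, region = fit$region,
                 period_label = fit$period_label, out)
}

#' Cross-tabulate peak timing by era
#'
#' Splits the peak records at `era_split_year` (years up to and including it
#' are the early era) and tabulates peak bins per era, with the modal peak
#' bin of each era (ties to the earliest bin).
#'
#' @param records peak-record tibble from [annual_peaks()].
#' @param era_split_year last year of the early era.
#' @param min_years minimum years per era to warn below.
#' @return list with `counts` (2 x 6 era-by-bin matrix), `modal_bin` (named
#'   length-2 vector) and `n_years` per era.
#' @export
peak_shift_table <- function(records, era_split_year, min_years = 3L) {
  stopifnot(is.data.frame(records),
            all(c("year", "peak_bin") %in% names(records)))
  era <- ifelse(records$year <= era_split_year, "pre", "post")
  if (!all(c("pre", "post") %in% era)) {
    stop("an era is empty at split year ", era_split_year)
  }
  n_years <- table(factor(era, levels = c("pre", "post")))
  if (any(n_years < min_years)) {
    warning("fewer than ", min_years, " years in an era")
  }
  counts <- table(factor(era, levels = c("pre", "post")),
                  factor(records$peak_bin, levels = 1:6))
  modal <- apply(counts, 1, function(r) as.integer(names(r)[which.max(r)]))
  list(counts = unclass(counts), modal_bin = modal,
       n_years = as.integer(n_years) |> setNames(c("pre", "post")))
}
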