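#' Weekly alongshore velocity on the coastal path
#'
#' On the grid row nearest `path_lat`, takes the first `coastal_extent`
#' degrees of ocean cells seaward of the coast (6 cells at 1/3-degree
#' spacing), discards the `n_discard` cells nearest the coast to avoid land
#' contamination, and returns the weekly mean alongshore (northward)
#' component of the remaining cells — 4 under the defaults.
#'
#' @param grid velocity tibble (`time`, `lat`, `lon`, `u_cm_s`, `v_cm_s`,
#'   optional `land`), as from [generate_velocity_grid()].
#' @param path_lat latitude of the path (deg N).
#' @param coastal_extent width of the coastal band (degrees of longitude).
#' @param n_discard cells nearest the coast to drop.
#' @param spacing grid spacing (degrees).
#' @return tibble (`time`, `v_cm_s`) with the longitudes used attached as
#'   `attr(, "cells")`.
#' @export
path_velocity <- function(grid, path_lat = 39.3, coastal_extent = 2,
                          n_discard = 2L, spacing = 1 / 3) {
  stopifnot(all(c("time", "lat", "lon", "v_cm_s") %in% names(grid)))
  lats <- sort(unique(grid$lat))
  if (path_lat < min(lats) - spacing / 2 || path_lat > max(lats) + spacing / 2) {
    stop("path latitude ", path_lat, " outside the grid")
  }
  row_lat <- lats[which.min(abs(lats - path_lat))]
  row <- grid[grid$lat == row_lat, , drop = FALSE]
  if (!"land" %in% names(row)) row$land <- FALSE
  ocean_lons <- sort(unique(row$lon[!row$land]))
  if (length(ocean_lons) == 0) stop("no ocean cells on the path row")
  n_path <- as.integer(round(coastal_extent / spacing))
  if (length(ocean_lons) < n_path) {
    stop("path row has only ", length(ocean_lons), " ocean cells; need ",
         n_path)
  }
  cells <- ocean_lons[seq_len(n_path)]
  keep <- cells[-seq_len(n_discard)]
  sel <- row[row$lon %in% keep, , drop = FALSE]
  if (any(is.na(sel$v_cm_s))) {
    bad <- sort(unique(sel$lon[is.na(sel$v_cm_s)]))
    stop("missing velocities on path cells at lon ",
         paste(bad, collapse = ", "))
  }
  sums <- rowsum(sel$v_cm_s, as.numeric(sel$time))
  cnts <- rowsum(rep(1, nrow(sel)), as.numeric(sel$time))
  out <- tibble::tibble(
    time = as.Date(as.numeric(rownames(sums)), origin = "1970-01-01"),
    v_cm_s = unname(sums[, 1] / cnts[, 1]))
  attr(out, "cells") <- keep
  attr(out, "row_lat") <- row_lat
  out
}

#' Aggregate a dated series to bi-monthly means
#'
#' Values are averaged over the bi-monthly bin containing their timestamp's
#' month; bins with no observations are explicitly missing.
#'
#' @param x tibble with a `time` (Date) column and one value column.
#' @param value name of the value column.
#' @return tibble (`year`, `bin`, `<value>`) over the observed year span.
#' @export
to_bimonthly <- function(x, value = "v_cm_s") {
  stopifnot("time" %in% names(x), value %in% names(x), nrow(x) > 0)
  idx <- assign_bimonthly(x$time)
  v <- x[[value]]
  key <- idx$year * 10L + idx$bin
  ok <- !is.na(v)
  out <- bimonthly_grid(range(idx$year))
  out[[value]] <- NA_real_
  if (any(ok)) {
    sums <- rowsum(v[ok], key[ok])
    cnts <- rowsum(rep(1, sum(ok)), key[ok])
    means <- setNames(sums[, 1] / cnts[, 1], rownames(sums))
    out[[value]] <- unname(means[as.character(out$year * 10L + out$bin)])
  }
  out
}

#' Annual cumulative northward and southward transport
#'
#' Per calendar year, the cumulative northward component is the sum of the
#' positive values and the cumulative southward component the sum of the
#' negative values, so that `north_sum + south_sum` equals the plain annual
#' sum. Years with missing bins are flagged partial.
#'
#' @param bimonthly tibble (`year`, `bin`, value column) from
#'   [to_bimonthly()].
#' @param value name of the value column.
#' @return tibble (`year`, `north_sum`, `south_sum`, `total`, `partial`).
#' @export
annual_cumulative <- function(bimonthly, value = "v_cm_s") {
  stopifnot(all(c("year", "bin", value) %in% names(bimonthly)))
  v <- bimonthly[[value]]
  tibble::tibble(year = bimonthly$year, v = v) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      north_sum = sum(pmax(.data$v, 0), na.rm = TRUE),
      south_sum = sum(pmin(.data$v, 0), na.rm = TRUE),
      total = sum(.data$v, na.rm = TRUE),
      partial = any(is.na(.data$v)) | dplyr::n() < 6L,
      .groups = "drop")
}

#' PCA-weighted Gulf Stream North Wall Index
#'
#' Standardizes the six north-wall latitude series (zero mean, unit SD over
#' the fitting span), takes the loadings of the first principal component,
#' fixes the arbitrary PC sign so the mean loading is positive, rescales the
#' loadings to sum to one, and returns their weighted average as the index.
#' The index is invariant to affine rescaling of any input series.
#'
#' @param northwall tibble with a `date` column and exactly six latitude
#'   columns, as from [generate_northwall()].
#' @return tibble (`date`, `index`) with the per-longitude `weights`
#'   (summing to 1) attached as an attribute.
#' @export
gsnwi <- function(northwall) {
  stopifnot(is.data.frame(northwall), "date" %in% names(northwall))
  latcols <- setdiff(names(northwall), "date")
  if (length(latcols) != 6L) {
    stop("need exactly 6 north-wall latitude series, got ", length(latcols))
  }
  if (nrow(northwall) < 24L) stop("need at least 24 common months")
  X <- as.matrix(northwall[, latcols])
  if (any(!is.finite(X))) stop("north-wall series contain missing values")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("constant north-wall series (zero SD): ",
         paste(latcols[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1]
  if (mean(w) < 0) w <- -w
  w <- w / sum(w)
  tibble::tibble(date = northwall$date,
                 index = as.numeric(Z %*% w)) |>
    structure(weights = setNames(as.numeric(w), latcols))
}
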