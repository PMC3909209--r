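#' Sub-region definitions
#'
#' Rectangular lat/lon boundaries for the four shelf sub-regions (Gulf of
#' Maine, Georges Bank, Southern New England, Mid-Atlantic Bight). The
#' shipped defaults are explicit approximations; they can be overridden, and
#' the listed order is the tie-break priority for stations that fall on a
#' shared boundary edge (first listed wins). Validation rejects regions whose
#' interiors overlap.
#'
#' @param boundaries named list of `list(lat = c(lo, hi), lon = c(lo, hi))`
#'   rectangles, in priority order.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(boundaries) {
  if (length(boundaries) == 0) stop("regions must be non-empty")
  if (is.null(names(boundaries)) || any(names(boundaries) == "")) {
    stop("every region needs a name")
  }
  for (b in boundaries) {
    if (!all(c("lat", "lon") %in% names(b)) ||
        b$lat[2] <= b$lat[1] || b$lon[2] <= b$lon[1]) {
      stop("each boundary needs increasing lat = c(lo, hi), lon = c(lo, hi)")
    }
  }
  nm <- names(boundaries)
  for (i in seq_along(boundaries)) {
    for (j in seq_along(boundaries)) {
      if (j <= i) next
      a <- boundaries[[i]]; b <- boundaries[[j]]
      lat_ov <- min(a$lat[2], b$lat[2]) - max(a$lat[1], b$lat[1])
      lon_ov <- min(a$lon[2], b$lon[2]) - max(a$lon[1], b$lon[1])
      if (lat_ov > 0 && lon_ov > 0) {
        stop("regions ", nm[i], " and ", nm[j], " have overlapping interiors")
      }
    }
  }
  structure(list(order = nm, boundary = boundaries), class = "region_spec")
}

#' @rdname region_spec
#' @param regions which of the default regions to keep, in priority order.
#' @export
default_regions <- function(regions = c("GOM", "GB", "SNE", "MAB")) {
  all <- list(
    GOM = list(lat = c(42, 45), lon = c(-70, -65)),
    GB  = list(lat = c(40.5, 42), lon = c(-69, -65)),
    SNE = list(lat = c(39, 41), lon = c(-72, -69)),
    MAB = list(lat = c(35, 39), lon = c(-76, -72)))
  missing <- setdiff(regions, names(all))
  if (length(missing)) stop("no default boundary for: ",
                            paste(missing, collapse = ", "))
  region_spec(all[regions])
}

#' Assign the bi-monthly bin of a date
#'
#' Bin 1 = Jan--Feb, ..., bin 6 = Nov--Dec; the year is the calendar year.
#'
#' @param date a `Date` vector (or something coercible).
#' @return tibble with `year` and `bin` columns.
#' @export
assign_bimonthly <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) stop("invalid date"))
  if (any(is.na(d))) stop("invalid date")
  lt <- as.POSIXlt(d)
  tibble::tibble(year = lt$year + 1900L, bin = lt$mon %/% 2L + 1L)
}

#' Assign samples to sub-regions
#'
#' A point inside exactly one boundary gets that region; a point outside all
#' boundaries gets `NA` (the sample is excluded downstream); a point on a
#' shared edge goes to the region listed first.
#'
#' @param lat,lon numeric degrees (lon negative west).
#' @param regions a [region_spec()].
#' @return character vector of region names (or `NA`).
#' @export
assign_region <- function(lat, lon, regions = default_regions()) {
  stopifnot(inherits(regions, "region_spec"), length(lat) == length(lon))
  out <- rep(NA_character_, length(lat))
  for (nm in regions$order) {
    b <- regions$boundary[[nm]]
    hit <- is.na(out) &
      lat >= b$lat[1] & lat <= b$lat[2] &
      lon >= b$lon[1] & lon <= b$lon[2]
    out[hit] <- nm
  }
  out
}

#' Assign samples to 2-degree latitude bands
#'
#' Half-open bands `[35 + 2k, 35 + 2k + 2)` over 35--45 deg N, labelled by
#' their bounds; latitudes outside the domain return `NA`.
#'
#' @param lat numeric degrees N.
#' @param width_deg band width (degrees).
#' @param domain inclusive-lower / exclusive-upper latitude domain.
#' @return character band labels like `"[35,37)"`.
#' @export
bin_latitude <- function(lat, width_deg = 2, domain = c(35, 45)) {
  k <- floor((lat - domain[1]) / width_deg)
  lo <- domain[1] + k * width_deg
  lab <- sprintf("[%g,%g)", lo, lo + width_deg)
  lab[lat < domain[1] | lat >= domain[2] | is.na(lat)] <- NA_character_
  lab
}

# Validate a sample table against the ingest invariants.
validate_samples <- function(samples) {
  need <- c("cruise_id", "station_id", "date", "lat", "lon", "species",
            "abundance")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) == 0) stop("empty sample set")
  if (any(!is.finite(samples$abundance)) || any(samples$abundance < 0)) {
    stop("abundance must be finite and >= 0")
  }
  if (any(samples$lat < 30 | samples$lat > 50, na.rm = TRUE)) {
    stop("latitude outside [30, 50]")
  }
  invisible(samples)
}

# Survey (cruise) midpoints: midpoint between the first and last tow date of
# each cruise; the whole cruise is assigned to the midpoint's bi-monthly bin.
cruise_bins <- function(samples) {
  d <- samples |>
    dplyr::group_by(.data$cruise_id) |>
    dplyr::summarise(
      midpoint = as.Date(mean(range(as.numeric(.data$date))),
                         origin = "1970-01-01"),
      .groups = "drop")
  dplyr::bind_cols(d, assign_bimonthly(d$midpoint))
}

# Complete (year, bin) grid over an inclusive year span.
bimonthly_grid <- function(years) {
  tidyr::expand_grid(year = seq(years[1], years[2]), bin = 1:6)
}

#' Build a bi-monthly mean-abundance series
#'
#' Reduces station-level samples of one species to the bi-monthly mean
#' abundance in one sub-region. Survey structure follows the cruise table:
#' each cruise is assigned to the bin containing its midpoint (mean of first
#' and last tow date), and the bin value is the unweighted arithmetic mean
#' over that cruise's in-region tows. Bins with no qualifying samples are
#' explicitly missing (`NA`), never zero.
#'
#' @param samples sample tibble (see [generate_abundance()] for the schema).
#' @param species species code to keep.
#' @param region region name the series is built for.
#' @param regions a [region_spec()].
#' @param years inclusive year span of the series; defaults to the span of
#'   the cruise midpoints in `samples`.
#' @return tibble (`species`, `region`, `year`, `bin`, `mean_abundance`,
#'   `n_samples`) covering the span contiguously.
#' @export
build_series <- function(samples, species, region,
                         regions = default_regions(), years = NULL) {
  validate_samples(samples)
  cb <- cruise_bins(samples)
  if (is.null(years)) years <- range(cb$year)
  x <- samples[samples$species == species, , drop = FALSE]
  x$region <- assign_region(x$lat, x$lon, regions)
  x <- x[!is.na(x$region) & x$region == region, , drop = FALSE]
  x <- dplyr::left_join(x, cb[, c("cruise_id", "year", "bin")],
                        by = "cruise_id")
  x <- x[x$year >= years[1] & x$year <= years[2], , drop = FALSE]
  agg <- x |>
    dplyr::group_by(.data$year, .data$bin) |>
    dplyr::summarise(mean_abundance = mean(.data$abundance),
                     n_samples = dplyr::n(), .groups = "drop")
  out <- bimonthly_grid(years) |>
    dplyr::left_join(agg, by = c("year", "bin")) |>
    dplyr::mutate(n_samples = ifelse(is.na(.data$n_samples), 0L,
                                     .data$n_samples))
  tibble::tibble(species = species, region = region, out)
}

#' Build a bi-monthly mean temperature series
#'
#' As [build_series()], but averaging the upper-3 m station temperature of
#' the distinct stations in the region (species rows share the station
#' temperature). Bins whose stations all lack a temperature are missing.
#'
#' @inheritParams build_series
#' @return tibble (`region`, `year`, `bin`, `mean_temp`, `n_samples`).
#' @export
build_temperature_series <- function(samples, region,
                                     regions = default_regions(),
                                     years = NULL) {
  validate_samples(samples)
  if (!"temp" %in% names(samples)) stop("samples have no 'temp' column")
  cb <- cruise_bins(samples)
  if (is.null(years)) years <- range(cb$year)
  x <- dplyr::distinct(samples, .data$cruise_id, .data$station_id,
                       .keep_all = TRUE)
  x$region <- assign_region(x$lat, x$lon, regions)
  x <- x[!is.na(x$region) & x$region == region, , drop = FALSE]
  x <- dplyr::left_join(x, cb[, c("cruise_id", "year", "bin")],
                        by = "cruise_id")
  x <- x[x$year >= years[1] & x$year <= years[2], , drop = FALSE]
  agg <- x |>
    dplyr::group_by(.data$year, .data$bin) |>
    dplyr::summarise(mean_temp = if (all(is.na(.data$temp))) NA_real_ else
                       mean(.data$temp, na.rm = TRUE),
                     n_samples = sum(!is.na(.data$temp)), .groups = "drop")
  out <- bimonthly_grid(years) |>
    dplyr::left_join(agg, by = c("year", "bin")) |>
    dplyr::mutate(n_samples = ifelse(is.na(.data$n_samples), 0L,
                                     .data$n_samples))
  tibble::tibble(region = region, out)
}

#' Read/write the station-sample CSV schema
#'
#' Columns: `cruise_id, station_id, date` (ISO-8601), `lat_deg, lon_deg,
#' species, abundance_ind_m3, temp_c`.
#'
#' @param samples sample tibble.
#' @param path file path.
#' @return `read_samples_csv` returns the sample tibble.
#' @export
write_samples_csv <- function(samples, path) {
  out <- data.frame(
    cruise_id = samples$cruise_id, station_id = samples$station_id,
    date = format(samples$date, "%Y-%m-%d"),
    lat_deg = samples$lat, lon_deg = samples$lon, species = samples$species,
    abundance_ind_m3 = samples$abundance,
    temp_c = if ("temp" %in% names(samples)) samples$temp else NA_real_)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    cruise_id = as.character(x$cruise_id),
    station_id = as.character(x$station_id),
    date = as.Date(x$date), lat = x$lat_deg, lon = x$lon_deg,
    species = x$species, abundance = x$abundance_ind_m3, temp = x$temp_c)
}
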