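#' Default pipeline configuration
#'
#' @param seed integer seed used by the simulation stage.
#' @param outdir output directory.
#' @param ... overrides merged over the defaults (e.g. `years`,
#'   `stations_per_bin`, `era_split_year`, `path_lat`).
#' @return a named configuration list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("shelfcope_run_"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    simulate = TRUE, samples_csv = NULL, velocity_csv = NULL,
    northwall_csv = NULL,
    years = c(1977L, 2009L), velocity_years = c(1993L, 2010L),
    stations_per_bin = 6L,
    regions = c("GOM", "GB", "SNE", "MAB"),
    species = c("CFIN", "CTYP"),
    trend_form = "ar1", error_ar1 = FALSE, scale = "raw",
    n_starts = 5L,
    path_lat = 39.3, coastal_extent = 2,
    era_split_year = 1985L,
    southern_regions = c("SNE", "MAB"),
    gap_years = c(1989L, 1991L))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    do.call(default_config, cfg)
  } else if (is.list(config)) {
    do.call(default_config, config)
  } else {
    stop("config must be a list or a path to a YAML/JSON file")
  }
}

validate_config <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    for (f in c("samples_csv", "velocity_csv", "northwall_csv")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop("config: ", f, " must exist when simulate = FALSE")
      }
    }
  } else if (is.null(cfg$seed)) {
    stop("config: seed required when simulating")
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> bin -> fit -> peaks -> forcing ->
#' associations from a single configuration, writing every stage's output
#' under `outdir` and a manifest recording the configuration hash, seed and
#' per-stage row counts. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a configuration list (see [default_config()]) or a path to
#'   a YAML/JSON file of overrides.
#' @param verbose print stage-boundary progress lines.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  cfg <- read_config(if (is.list(config)) config else config)
  validate_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  cfg_path <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("shelfcope")),
                   stages = list())
  add_stage <- function(name, files, rows) {
    manifest$stages[[name]] <<- list(files = files, rows = rows)
    say("stage ", name, ": ", rows, " rows")
  }

  # -- simulate / load ------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    truth <- synthetic_truth(
      seed = cfg$seed, years = cfg$years,
      velocity_years = cfg$velocity_years,
      stations_per_bin = cfg$stations_per_bin)
    samples <- generate_abundance(truth)
    grid <- generate_velocity_grid(truth)
    northwall <- generate_northwall(truth)
    write_samples_csv(samples, file.path(cfg$outdir, "samples.csv"))
    write.csv(grid, file.path(cfg$outdir, "velocity.csv"), row.names = FALSE)
    write.csv(northwall, file.path(cfg$outdir, "northwall.csv"),
              row.names = FALSE)
    truth_out <- truth
    class(truth_out) <- NULL
    jsonlite::write_json(truth_out, file.path(cfg$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    samples <- read_samples_csv(cfg$samples_csv)
    grid <- tibble::as_tibble(read.csv(cfg$velocity_csv)) |>
      dplyr::mutate(time = as.Date(.data$time))
    northwall <- tibble::as_tibble(read.csv(cfg$northwall_csv)) |>
      dplyr::mutate(date = as.Date(.data$date))
  }
  add_stage("simulate",
            c("samples.csv", "velocity.csv", "northwall.csv"),
            nrow(samples))

  # -- bin ------------------------------------------------------------------
  regions <- default_regions(cfg$regions)
  series <- list()
  temps <- list()
  for (sp in cfg$species) {
    for (rg in cfg$regions) {
      series[[paste(sp, rg)]] <-
        build_series(samples, sp, rg, regions, years = cfg$years)
    }
  }
  for (rg in cfg$regions) {
    temps[[rg]] <- build_temperature_series(samples, rg, regions,
                                            years = cfg$years)
  }
  series_tbl <- dplyr::bind_rows(series)
  temp_tbl <- dplyr::bind_rows(temps)
  write.csv(series_tbl, file.path(cfg$outdir, "series.csv"),
            row.names = FALSE)
  write.csv(temp_tbl, file.path(cfg$outdir, "temperature.csv"),
            row.names = FALSE)
  add_stage("bin", c("series.csv", "temperature.csv"), nrow(series_tbl))

  # -- fit ------------------------------------------------------------------
  spec <- model_spec(trend_form = cfg$trend_form, error_ar1 = cfg$error_ar1,
                     scale = cfg$scale)
  fits <- list()
  comp_rows <- list()
  par_rows <- list()
  for (key in names(series)) {
    subs <- split_periods(series[[key]],
                          southern_regions = cfg$southern_regions,
                          gap_years = cfg$gap_years)
    for (lab in names(subs)) {
      s <- subs[[lab]]
      if (sum(!is.na(s$mean_abundance)) < 24) next
      f <- fit_structural(s, spec, n_starts = cfg$n_starts,
                          seed = cfg$seed, period_label = lab)
      fits[[paste(key, lab)]] <- f
      comp_rows[[paste(key, lab)]] <- tibble::tibble(
        species = f$species, region = f$region, period = lab,
        year = f$data$year, bin = f$data$bin, observed = f$data$observed,
        trend = f$mu, seasonal = f$gamma, fitted = f$fitted)
      par_rows[[paste(key, lab)]] <- c(
        list(species = f$species, region = f$region, period = lab,
             phi = f$phi, sigma2_eta = f$sigma2_eta,
             sigma2_eps = f$sigma2_eps, loglik = f$loglik,
             converged = f$converged),
        as.list(f$coef))
    }
  }
  if (length(fits) == 0) stop("fit stage: no series had enough coverage")
  components <- dplyr::bind_rows(comp_rows)
  write.csv(components, file.path(cfg$outdir, "components.csv"),
            row.names = FALSE)
  jsonlite::write_json(unname(par_rows),
                       file.path(cfg$outdir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  add_stage("fit", c("components.csv", "parameters.json"), nrow(components))

  # -- peaks ----------------------------------------------------------------
  peaks <- dplyr::bind_rows(lapply(fits, annual_peaks))
  write.csv(peaks, file.path(cfg$outdir, "peaks.csv"), row.names = FALSE)
  add_stage("peaks", "peaks.csv", nrow(peaks))

  # -- forcing --------------------------------------------------------------
  pv <- path_velocity(grid, path_lat = cfg$path_lat,
                      coastal_extent = cfg$coastal_extent)
  transport <- to_bimonthly(pv)
  cumul <- annual_cumulative(transport)
  gs <- gsnwi(northwall)
  write.csv(transport, file.path(cfg$outdir, "transport_bimonthly.csv"),
            row.names = FALSE)
  write.csv(cumul, file.path(cfg$outdir, "transport_annual.csv"),
            row.names = FALSE)
  write.csv(gs, file.path(cfg$outdir, "gsnwi.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(attr(gs, "weights")),
                       file.path(cfg$outdir, "gsnwi_weights.json"),
                       auto_unbox = TRUE, digits = NA)
  add_stage("forcing",
            c("transport_bimonthly.csv", "transport_annual.csv",
              "gsnwi.csv", "gsnwi_weights.json"),
            nrow(transport) + nrow(gs))

  # -- associate ------------------------------------------------------------
  assoc <- association_suite(peaks, transport, gs, temperature = temp_tbl)
  write.csv(assoc, file.path(cfg$outdir, "associations.csv"),
            row.names = FALSE)
  add_stage("associate", "associations.csv", nrow(assoc))

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
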