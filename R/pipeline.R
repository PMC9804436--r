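#' Run the stranding range-shift pipeline end to end
#'
#' Orchestrates the stages over a configuration (a list or a YAML file):
#' `simulate` (synthetic world, strandings, SST cube, census), `clean`
#' (CSV round-trip through the Level-A reader, coordinate normalization,
#' gazetteer cross-check, region assignment), `distance` (shelf distance
#' field and poleward-distance assignment), `velocity` (SST gradients,
#' climate velocity, regional summaries, anomaly series), `shifts` (center
#' and trailing-edge trends with bootstrap CIs and Dunn-Sidak adjustment,
#' composition trends, convergence and censoring diagnostics), `power`
#' (minimum-sample-size table), and `bias` (census regression). Given the
#' same configuration and seed the output tables are byte-identical across
#' runs; every table carries the configuration hash and seed.
#'
#' @param config list or path to a YAML file. Recognised keys: `seed`
#'   (required), `out_dir`, `stages` (default all), `world` (arguments to
#'   [world_spec()]), `species` (list of [species_sim_spec()] argument
#'   lists), `sst` (arguments to [gen_sst_cube()], or `csv` pointing at a
#'   cube written by [write_sst_cube_csv()]), `census` (arguments to
#'   [gen_census()]), `split_latitude`, `snap_km`, `alpha`, `bootstrap_B`,
#'   `power` (`reps`, `slopes`, `n_max`, `target`).
#' @param out_dir output directory (overrides `config$out_dir`); created if
#'   needed. `NULL` writes nothing and returns results in memory.
#' @return (invisibly) a list with the per-stage results and the paths of
#'   the files written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config_(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # hash the analysis-relevant configuration; where outputs land must not
  # change what they contain
  provenance <- list(
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed)
  res <- list(config = cfg, provenance = provenance, files = character())
  log_ <- function(...) message("[strandshift] ", sprintf(...))
  emit <- function(df, name) {
    df$config_hash <- provenance$config_hash
    df$seed <- provenance$seed
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      res$files <<- c(res$files, p)
    }
    df
  }

  world <- do.call(world_spec, cfg$world)
  res$world <- world

  if ("simulate" %in% cfg$stages) {
    log_("stage simulate: %d species, %d years", length(cfg$species), world$n_years)
    specs <- lapply(cfg$species, function(a) do.call(species_sim_spec, a))
    res$specs <- specs
    res$truth <- emit(dplyr::bind_rows(lapply(specs, function(s) tibble::tibble(
      species_id = s$species_id, slope_b = s$slope_b,
      intercept_a = s$intercept_a, sd_sigma = s$sd_sigma,
      climatic_category = s$climatic_category,
      trailing_edge = s$trailing_edge))), "ground_truth")
    raw <- dplyr::bind_rows(lapply(seq_along(specs), function(i) {
      gen_strandings(specs[[i]], world, seed = cfg$seed + i)
    }))
    res$raw_strandings <- raw
    res$census <- do.call(gen_census,
                          c(list(world = world, seed = cfg$seed + 1001L),
                            cfg$census))
    res$cube <- do.call(gen_sst_cube,
                        c(list(world = world, seed = cfg$seed + 1002L),
                          cfg$sst[setdiff(names(cfg$sst), "csv")]))
  }

  if ("clean" %in% cfg$stages) {
    log_("stage clean")
    if (!is.null(cfg$strandings_csv)) {
      if (!file.exists(cfg$strandings_csv)) {
        stop("strandings_csv not found: ", cfg$strandings_csv, call. = FALSE)
      }
      parsed <- read_level_a(cfg$strandings_csv)
    } else {
      if (is.null(res$raw_strandings)) {
        stop("clean stage needs the simulate stage or `strandings_csv`",
             call. = FALSE)
      }
      tmp <- tempfile(fileext = ".csv")
      df <- res$raw_strandings
      df$date <- as.character(df$date)
      utils::write.csv(df, tmp, row.names = FALSE)
      parsed <- read_level_a(tmp)
      unlink(tmp)
    }
    recs <- normalize_coordinates(parsed$records)
    recs <- validate_locations(recs, gazetteer_from_census(res$census),
                               max_km = cfg$gazetteer_max_km)
    recs <- assign_region(recs, cfg$split_latitude)
    res$records <- recs
    res$rejects <- parsed$rejects
    emit(recs, "records_clean")
  }

  if ("distance" %in% cfg$stages) {
    log_("stage distance")
    grid <- synthetic_shelf_grid(world)
    field <- build_distance_field(grid, origin = world$origin)
    res$field <- field
    if (!is.null(res$records)) {
      res$records <- poleward_distance(res$records, field,
                                       snap_km = cfg$snap_km)
      emit(res$records, "records_distance")
    }
  }

  if ("velocity" %in% cfg$stages) {
    log_("stage velocity")
    cube <- res$cube
    if (!is.null(cfg$sst$csv)) {
      if (!file.exists(cfg$sst$csv)) {
        stop("SST cube file not found: ", cfg$sst$csv, call. = FALSE)
      }
      cube <- read_sst_cube_csv(cfg$sst$csv)
    }
    if (is.null(cube)) {
      stop("velocity stage needs the simulate stage or `sst$csv`", call. = FALSE)
    }
    gt <- temporal_gradient(cube)
    sg <- spatial_gradient(cube)
    vel <- climate_velocity(gt, sg$magnitude)
    north <- matrix(cube$lat >= cfg$split_latitude, length(cube$lat),
                    length(cube$lon))
    res$velocity <- vel
    res$velocity_summary <- emit(dplyr::bind_rows(
      dplyr::mutate(regional_summary(vel$velocity, north), region = "NEUS"),
      dplyr::mutate(regional_summary(vel$velocity, !north), region = "SEUS")),
      "velocity_summary")
    res$anomaly <- list(
      NEUS = sst_anomaly_series(cube, north),
      SEUS = sst_anomaly_series(cube, !north))
    emit(dplyr::bind_rows(
      dplyr::mutate(res$anomaly$NEUS$series, region = "NEUS"),
      dplyr::mutate(res$anomaly$SEUS$series, region = "SEUS")),
      "sst_anomaly")
  }

  if ("shifts" %in% cfg$stages) {
    log_("stage shifts")
    recs <- res$records
    if (is.null(recs) || is.null(recs$poleward_distance_km)) {
      stop("shifts stage needs the distance stage", call. = FALSE)
    }
    counts <- recs |>
      dplyr::filter(!is.na(.data$poleward_distance_km)) |>
      dplyr::count(.data$species_id) |>
      dplyr::mutate(mean_annual_n = .data$n / world$n_years)
    elig <- eligible_species(stats::setNames(counts$mean_annual_n,
                                             counts$species_id))
    trailing <- if (!is.null(res$specs)) {
      vapply(res$specs, function(s) s$trailing_edge, logical(1)) |>
        stats::setNames(vapply(res$specs, function(s) s$species_id, character(1)))
    } else {
      stats::setNames(rep(FALSE, length(elig)), elig)
    }
    tests <- lapply(elig, function(sp) {
      kinds <- if (isTRUE(trailing[sp])) c("mean", "q05") else "mean"
      lapply(kinds, function(k) list(species = sp, statistic = k))
    })
    tests <- unlist(tests, recursive = FALSE)
    m <- length(tests)
    a_adj <- if (m >= 1) sidak_adjust(cfg$alpha, m) else NA_real_
    shift_rows <- lapply(seq_along(tests), function(i) {
      sp <- tests[[i]]$species; k <- tests[[i]]$statistic
      fit <- fit_shift(recs[recs$species_id == sp, ], statistic = k,
                       B = cfg$bootstrap_B, seed = cfg$seed + 2000L + i,
                       alpha_adjusted = a_adj)
      tibble::tibble(species_id = sp, statistic = k, slope = fit$slope,
                     p_value = fit$p_value, r_squared = fit$r_squared,
                     boot_ci_low = fit$boot_ci_low,
                     boot_ci_high = fit$boot_ci_high, n_boot = fit$n_boot,
                     alpha_adjusted = a_adj,
                     significant = fit$p_value < a_adj)
    })
    res$shift_table <- emit(dplyr::bind_rows(shift_rows), "shift_trends")
    anom <- if (!is.null(res$anomaly)) res$anomaly$NEUS$series else NULL
    comp <- composition_series(recs, registry = pipeline_registry_(recs, res$specs),
                               anomaly = anom)
    res$composition <- comp
    emit(comp$series, "composition_series")
    emit(comp$trends_year, "composition_trends_year")
    conv_rows <- lapply(names(trailing)[trailing & names(trailing) %in% elig],
                        function(sp) {
      rr <- recs[recs$species_id == sp, ]
      cv <- convergence_check(annual_statistic(rr, "mean"),
                              annual_statistic(rr, "q05"))
      tibble::tibble(species_id = sp, converged = cv$converged,
                     min_recent_gap_km = cv$min_recent_gap_km,
                     edge_censoring = edge_censoring_diagnostic(
                       rr, world$max_distance_km))
    })
    if (length(conv_rows) > 0) {
      res$convergence <- emit(dplyr::bind_rows(conv_rows), "convergence")
    }
  }

  if ("power" %in% cfg$stages) {
    log_("stage power (reps = %d)", cfg$power$reps)
    profiles <- if (!is.null(res$specs)) {
      dplyr::bind_rows(lapply(res$specs, function(s) {
        kinds <- if (s$trailing_edge) c("mean", "q05") else "mean"
        tibble::tibble(species_id = s$species_id, statistic = kinds,
                       sd_km = s$sd_sigma)
      }))
    } else {
      species_profiles()[, c("species_id", "statistic", "sd_km")]
    }
    res$power_table <- emit(power_table(
      profiles, slopes = cfg$power$slopes,
      n_grid = seq(2L, cfg$power$n_max), target = cfg$power$target,
      reps = cfg$power$reps, seed = cfg$seed + 3000L), "power_table")
  }

  if ("bias" %in% cfg$stages) {
    log_("stage bias")
    if (is.null(res$census)) stop("bias stage needs the simulate stage",
                                  call. = FALSE)
    windows <- list()
    if (!is.null(res$shift_table) && !is.null(res$records)) {
      sig <- res$shift_table[res$shift_table$significant &
                               res$shift_table$statistic == "mean", ]
      for (sp in sig$species_id) {
        d <- res$records$poleward_distance_km[res$records$species_id == sp]
        d <- d[!is.na(d)]
        if (length(d) >= 3) windows[[sp]] <- range(d)
      }
    }
    res$bias <- emit(bias_report(res$census, windows, alpha = cfg$alpha),
                     "bias_report")
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(provenance = provenance, stages = cfg$stages,
           files = basename(res$files)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  }
  invisible(res)
}

# registry for pipeline data: known species from the built-in registry,
# synthetic species from their sim specs
#' @noRd
pipeline_registry_ <- function(records, specs) {
  reg <- species_registry()
  if (!is.null(specs)) {
    extra <- dplyr::bind_rows(lapply(specs, function(s) tibble::tibble(
      species_id = s$species_id, common_name = s$species_id,
      scientific_name = s$species_id,
      climatic_category = s$climatic_category,
      trailing_edge = s$trailing_edge)))
    reg <- dplyr::bind_rows(reg[!reg$species_id %in% extra$species_id, ], extra)
  }
  reg
}

#' @noRd
validate_config_ <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  problem <- function(path, msg) {
    stop("config error at `", path, "`: ", msg, call. = FALSE)
  }
  if (is.null(config$seed)) problem("seed", "a seed is required")
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    problem("seed", "must be a single integer")
  }
  defaults <- list(
    stages = c("simulate", "clean", "distance", "velocity", "shifts",
               "power", "bias"),
    world = list(),
    species = list(list(species_id = "syn_cool", slope_b = 10,
                        intercept_a = 600, sd_sigma = 250, annual_n = 30,
                        climatic_category = "cool", trailing_edge = TRUE),
                  list(species_id = "syn_warm", slope_b = 5,
                       intercept_a = 300, sd_sigma = 250, annual_n = 30,
                       climatic_category = "warm", trailing_edge = FALSE)),
    sst = list(noise_sd = 0.2),
    census = list(noise_sd = 5),
    strandings_csv = NULL,
    split_latitude = 35.25,
    snap_km = 25,
    gazetteer_max_km = 50,
    alpha = 0.05,
    bootstrap_B = 1000,
    power = list(),
    out_dir = NULL
  )
  known <- c(names(defaults), "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    problem(unknown[1], "unknown configuration key")
  }
  cfg <- utils::modifyList(defaults, config)
  power_defaults <- list(reps = 200, slopes = c(4, 8, 16),
                         n_max = 200L, target = 0.95)
  cfg$power <- utils::modifyList(power_defaults, cfg$power)
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage) > 0) problem("stages", paste("unknown stage", bad_stage[1]))
  cfg$seed <- as.integer(config$seed)
  cfg
}
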