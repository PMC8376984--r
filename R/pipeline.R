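# End-to-end synthetic experiment: generate the two-arm study, run the
# centralized genomic benchmark and the decentralized ranking pipeline, and
# emit the comparison report. Everything is driven by one config list with
# explicit seeds.

#' Default pipeline configuration
#'
#' Returns the full parameter list of the synthetic experiment. The defaults
#' reproduce the study design the generator emulates: 400 station genotypes
#' (41 distributed on farm) in 2 stations x 2 seasons x 2 replicates (3,200
#' station plots, 800 per station-season field), 1,165 farmer fields x 4
#' ranked plots (4,660 farm plots) over 3 seasons, and a night-temperature
#' worth switch at 11.5 deg C.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param ... named overrides of any default.
#' @return a named list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genotypes and markers
    n_station_genotypes = 400, n_farm_genotypes = 41,
    n_snps = 500, maf_low = 0.05, maf_high = 0.5,
    # trial design
    n_fields = 1165, n_seasons = 3, n_stations = 2,
    station_seasons = 2, n_reps = 2, block_size = 20, n_raters = 10,
    # environment and latent model
    cold_fraction = 0.35, switch_covariate = "minNT_veg",
    switch_threshold = 11.5, base_sd = 1, shift_sd = 1.2,
    yield_scale = 0.8, noise_sd = 0.4,
    # tree and selection
    alpha = 0.01, min_size = 0.20, prior_scale = 1, use_kinship = TRUE,
    candidates = c("minNT_veg", "rain_total_veg", "rain_total_rep",
                   "rain_total_full", "rain_days_veg", "rain_days_full",
                   "max_dry_run_full", "max_wet_run_full",
                   "rain_max_5d_full", "DTR_full"),
    benchmark_ranks = FALSE,
    # scenario extrapolation
    scenario_years = 2001:2015, n_sowing_windows = 3, n_points = 1200,
    top_k = 3)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override the defaults of [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(default_config, c(list(seed = vals$seed %||% 1),
                            vals[setdiff(names(vals), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the full synthetic study
#'
#' Runs every generator with seeds derived from `config$seed`: markers and
#' kinship, the latent worth model, environments and daily weather,
#' per-field agroclimatic covariates, the tricot design and trial, and the
#' station trial. The check variety is the genotype with the best station
#' (warm-regime) genetic value outside the on-farm subset, mirroring an
#' improved variety recommended from centralized results.
#'
#' @param config a [default_config()] list.
#' @return list with `config`, `markers`, `kinship`, `model`, `env`,
#'   `covariates` (per-field data.frame), `farm_genotypes`, `check`
#'   (the upper-quartile station performer outside the on-farm subset),
#'   `design`, `tricot` (`rankings`, `yield`), `station` (`plots`, `oa`).
#' @export
sim_study <- function(config = default_config()) {
  cfg <- config
  markers <- sim_markers(cfg$n_station_genotypes, cfg$n_snps,
                         cfg$maf_low, cfg$maf_high, seed = cfg$seed)
  kinship <- kinship_vanraden(clean_markers(markers))
  model <- sim_true_model(markers, base_sd = cfg$base_sd,
                          shift_sd = cfg$shift_sd, seed = cfg$seed + 1,
                          switch_covariate = cfg$switch_covariate,
                          switch_threshold = cfg$switch_threshold,
                          yield_scale = cfg$yield_scale,
                          noise_sd = cfg$noise_sd)
  env <- sim_environment(cfg$n_fields, cfg$n_seasons, cfg$n_stations,
                         cold_fraction = cfg$cold_fraction,
                         seed = cfg$seed + 2)
  covariates <- field_covariates(env)
  gen_all <- rownames(markers)
  farm <- withr::with_seed(cfg$seed + 3,
                           sort(sample(gen_all, cfg$n_farm_genotypes)))
  # the check emulates a currently recommended improved variety: strong on
  # station (upper quartile of the warm-regime genetic value) but not the
  # extreme of the panel
  station_value <- model$log_worth_base + model$log_worth_shift
  pool <- setdiff(gen_all, farm)
  check <- pool[which.min(abs(station_value[pool] -
                                quantile(station_value[pool], 0.75)))]
  design <- sim_tricot_design(env$fields, farm, check, seed = cfg$seed + 4)
  worths <- sim_true_worths(model, covariates)[, c(farm, check), drop = FALSE]
  worths <- worths / rowSums(worths)
  tricot <- sim_tricot_trial(design, worths, model, seed = cfg$seed + 5)
  sdesign <- sim_station_design(gen_all, n_locations = cfg$n_stations,
                                n_seasons = cfg$station_seasons,
                                n_reps = cfg$n_reps,
                                block_size = cfg$block_size)
  station <- sim_station_trial(sdesign, model, seed = cfg$seed + 6,
                               n_raters = cfg$n_raters)
  list(config = cfg, markers = markers, kinship = kinship, model = model,
       env = env, covariates = covariates, farm_genotypes = farm,
       check = check, design = design, worths = worths, tricot = tricot,
       station = station)
}

#' Export a synthetic study as plain CSV files plus its config
#'
#' Writes the canonical tables of the generated experiment: the farmer
#' rankings (long dialect), the farm per-plot grain yields, the station
#' plots with their rater scores, the marker matrix, the combined daily
#' weather table, the per-field covariates, and the full generator
#' configuration as JSON.
#'
#' @param study a [sim_study()] result; @param dir output directory.
#' @return invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rankings = file.path(dir, "rankings.csv"),
             farm_yield = file.path(dir, "farm_yield.csv"),
             station_plots = file.path(dir, "station_plots.csv"),
             station_oa = file.path(dir, "station_oa.csv"),
             markers = file.path(dir, "markers.csv"),
             weather = file.path(dir, "weather.csv"),
             covariates = file.path(dir, "covariates.csv"),
             config = file.path(dir, "config.json"))
  write_rankings(study$tricot$rankings, paths["rankings"], "long")
  write.csv(study$tricot$yield, paths["farm_yield"], row.names = FALSE)
  write.csv(study$station$plots, paths["station_plots"], row.names = FALSE)
  write.csv(study$station$oa, paths["station_oa"], row.names = FALSE)
  write.csv(data.frame(genotype = rownames(study$markers), study$markers,
                       check.names = FALSE),
            paths["markers"], row.names = FALSE)
  write.csv(study$env$weather, paths["weather"], row.names = FALSE)
  write.csv(cbind(study$env$fields[, c("field_id", "season")],
                  study$covariates),
            paths["covariates"], row.names = FALSE)
  jsonlite::write_json(unclass(study$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Agroclimatic covariates for every farmer field
#'
#' @param env a [sim_environment()] result.
#' @param gdd_base passed to [climate_indices()].
#' @return data.frame, one row per field in `env$fields` order.
#' @export
field_covariates <- function(env, gdd_base = 0) {
  wsplit <- split(env$weather, env$weather$site_id)
  ph <- env$phases
  rows <- lapply(seq_len(nrow(env$fields)), function(i) {
    f <- env$fields[i, ]
    p <- ph[ph$site_id == f$site_id & ph$season == f$season, ]
    climate_indices(wsplit[[f$site_id]],
                    phase_windows(p$planting_date, p$flowering_date,
                                  p$maturity_date, p$harvest_date),
                    gdd_base = gdd_base)
  })
  do.call(rbind, rows)
}

station_plot_oa <- function(station) {
  agg <- aggregate(list(oa = station$oa$score),
                   by = list(plot_id = station$oa$plot_id), FUN = mean)
  merge(station$plots, agg, by = "plot_id", sort = FALSE)
}

#' Run the centralized genomic-prediction benchmark
#'
#' Station plot data are reduced to per-genotype BLUPs (grain yield, and
#' overall appreciation pooled across raters and genders), a GBLUP model is
#' trained on the full station panel, and the on-farm genotypes are
#' predicted from the kinship matrix alone. Accuracy is the per-season mean
#' field-level Kendall tau between the (environment-free) predicted values
#' and the observed farm rankings, combined across seasons with sqrt(n)
#' weights.
#'
#' @param study a [sim_study()] result.
#' @param train `"all"` (default: full station panel), `"subset"` (only the
#'   on-farm genotypes) or `"disjoint"` (panel minus on-farm genotypes).
#' @return list with `accuracy` (method/trait/season/n/tau), `blups`,
#'   `models`, `predictions`.
#' @export
run_benchmark <- function(study, train = c("all", "subset", "disjoint")) {
  train <- match.arg(train)
  cfg <- study$config
  plots <- station_plot_oa(study$station)
  targets <- c(study$farm_genotypes, study$check)
  out_pred <- list(); out_acc <- list(); blups <- list(); models <- list()
  for (trait in c("OA", "GY")) {
    col <- if (trait == "OA") "oa" else "gy"
    sb <- station_blup(plots, col)
    y <- sb$blup
    keep <- switch(train,
                   all = names(y),
                   subset = intersect(names(y), targets),
                   disjoint = setdiff(names(y), targets))
    mod <- fit_gblup(y[keep], study$kinship, ranks = cfg$benchmark_ranks)
    pred <- predict_gblup(mod, targets, study$kinship)
    obs <- if (trait == "OA") study$tricot$rankings else
      rank_from_measures(data.frame(field_id = study$tricot$yield$field_id,
                                    season = study$tricot$yield$season,
                                    item = study$tricot$yield$genotype,
                                    value = study$tricot$yield$gy))
    acc <- mean_field_tau(pred, obs)
    acc <- data.frame(method = "benchmark", trait = trait,
                      season = acc$season, n = acc$n, tau = acc$tau)
    out_acc[[trait]] <- acc
    out_pred[[trait]] <- pred
    blups[[trait]] <- sb
    models[[trait]] <- mod
  }
  list(accuracy = do.call(rbind, out_acc), blups = blups, models = models,
       predictions = out_pred)
}

#' Station-to-station benchmark validation
#'
#' The within-station scenario: train GBLUP on one station season, predict
#' the next season's BLUPs of the on-farm subset, and report Kendall tau.
#'
#' @param study a [sim_study()] result; @param trait `"GY"` or `"OA"`.
#' @return list with `tau` and the two BLUP sets.
#' @export
run_benchmark_station <- function(study, trait = "GY") {
  col <- if (trait == "OA") "oa" else "gy"
  plots <- station_plot_oa(study$station)
  seasons <- sort(unique(plots$season))
  if (length(seasons) < 2) stop("needs at least two station seasons")
  b1 <- station_blup(plots[plots$season == seasons[1], ], col)
  b2 <- station_blup(plots[plots$season == seasons[2], ], col)
  mod <- fit_gblup(b1$blup, study$kinship)
  sub <- intersect(c(study$farm_genotypes, study$check), names(b2$blup))
  pred <- predict_gblup(mod, sub, study$kinship)
  obs <- b2$blup[sub]
  list(tau = kendall_tau(pred, names(sort(obs, decreasing = TRUE))),
       train_blup = b1$blup, test_blup = b2$blup)
}

#' Benchmark accuracy stratified by environmental distance from stations
#'
#' Splits farmer fields into strata by the absolute difference between the
#' field's switch-phase night temperature and the station average of the
#' same index, then reports the benchmark's field-level accuracy per
#' stratum — the near-station fields are the ones a centralized model
#' should predict best.
#'
#' @param study a [sim_study()] result; @param bench a [run_benchmark()]
#'   result; @param n_strata number of equal-count strata (default 2).
#' @param covariate the index used for the distance (default the
#'   generator's switch covariate).
#' @return data.frame `trait, stratum, n, tau` with stratum 1 closest to
#'   the stations.
#' @export
run_benchmark_by_distance <- function(study, bench, n_strata = 2,
                                      covariate = NULL) {
  covariate <- covariate %||% study$config$switch_covariate
  ph <- study$env$phases
  st <- ph[ph$type == "station", ]
  wsplit <- split(study$env$weather, study$env$weather$site_id)
  st_vals <- vapply(seq_len(nrow(st)), function(i) {
    climate_indices(wsplit[[st$site_id[i]]],
                    phase_windows(st$planting_date[i], st$flowering_date[i],
                                  st$maturity_date[i],
                                  st$harvest_date[i]))[[covariate]]
  }, numeric(1))
  dist <- abs(study$covariates[[covariate]] - mean(st_vals))
  stratum <- cut(rank(dist, ties.method = "first"),
                 breaks = n_strata, labels = FALSE)
  out <- list()
  for (tr in c("OA", "GY")) {
    obs <- if (tr == "OA") study$tricot$rankings else
      rank_from_measures(data.frame(field_id = study$tricot$yield$field_id,
                                    season = study$tricot$yield$season,
                                    item = study$tricot$yield$genotype,
                                    value = study$tricot$yield$gy))
    for (s in seq_len(n_strata)) {
      sub <- obs[stratum == s]
      sub$group$season <- "all"
      a <- mean_field_tau(bench$predictions[[tr]], sub)
      out[[paste(tr, s)]] <- data.frame(trait = tr, stratum = s,
                                        n = a$n[1], tau = a$tau[1])
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the decentralized ranking pipeline
#'
#' Forward covariate selection (seasons as cross-validation blocks, Akaike
#' weights on holdout deviance), then for every season a Plackett-Luce tree
#' trained on the remaining seasons predicts the held-out fields; accuracy
#' is the per-season mean field Kendall tau for both farmer rankings (OA)
#' and yield-derived rankings (GY). A final tree on all seasons is returned
#' for extrapolation.
#'
#' @param study a [sim_study()] result.
#' @param select run forward selection (default `TRUE`); otherwise use
#'   `covariates` as given.
#' @param covariates covariate names used when `select = FALSE` (default:
#'   the configured candidate list).
#' @param train_fraction fraction of training records used (supports the
#'   data-degradation scenarios; default 1).
#' @return list with `accuracy`, `tree` (final OA tree), `selection`
#'   (trail or `NULL`), `selected`.
#' @export
run_3db <- function(study, select = TRUE, covariates = NULL,
                    train_fraction = 1) {
  cfg <- study$config
  cov <- study$covariates
  K <- if (cfg$use_kinship)
    study$kinship[c(study$farm_genotypes, study$check),
                  c(study$farm_genotypes, study$check)] else NULL
  r_oa <- study$tricot$rankings
  r_gy <- rank_from_measures(data.frame(
    field_id = study$tricot$yield$field_id,
    season = study$tricot$yield$season,
    item = study$tricot$yield$genotype,
    value = study$tricot$yield$gy))
  blocks <- r_oa$group$season
  selection <- NULL
  if (select) {
    selection <- forward_select(r_oa, cov, blocks, cfg$candidates,
                                alpha = cfg$alpha, min_size = cfg$min_size,
                                kinship = K, prior_scale = cfg$prior_scale)
    covariates <- selection$selected
  } else if (is.null(covariates)) covariates <- cfg$candidates
  seasons <- sort(unique(blocks))
  acc <- list()
  for (trait in c("OA", "GY")) {
    r <- if (trait == "OA") r_oa else r_gy
    rows <- lapply(seasons, function(s) {
      hold <- r$group$season == s
      tr_idx <- which(!hold)
      if (train_fraction < 1)
        tr_idx <- withr::with_seed(cfg$seed + 7,
          sort(sample(tr_idx, max(2, round(train_fraction * length(tr_idx))))))
      tree <- pl_tree(r[tr_idx], cov[tr_idx, , drop = FALSE],
                      alpha = cfg$alpha, min_size = cfg$min_size,
                      covariates = covariates, kinship = K,
                      prior_scale = cfg$prior_scale)
      pred <- predict(tree, cov[hold, , drop = FALSE])
      a <- mean_field_tau(pred, r[hold])
      data.frame(method = "3db", trait = trait, season = s,
                 n = a$n[1], tau = a$tau[1])
    })
    acc[[trait]] <- do.call(rbind, rows)
  }
  final_tree <- pl_tree(r_oa, cov, alpha = cfg$alpha,
                        min_size = cfg$min_size, covariates = covariates,
                        kinship = K, prior_scale = cfg$prior_scale)
  list(accuracy = do.call(rbind, acc), tree = final_tree,
       selection = selection, selected = covariates)
}

#' Emit the comparison report and scenario outputs
#'
#' Writes the across-season comparison table, the selection trail, the
#' serialized tree, the scenario and reliability tables, and a run log with
#' record counts and seeds.
#'
#' @param study,bench,tdb results of [sim_study()], [run_benchmark()] and
#'   [run_3db()].
#' @param outdir output directory (created if needed).
#' @param n_points number of extrapolation points (default from config).
#' @return invisibly, a list with the comparison table, the scenario
#'   summary and the written file paths.
#' @export
run_report <- function(study, bench, tdb, outdir, n_points = NULL) {
  cfg <- study$config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- comparison_table(bench$accuracy, tdb$accuracy)
  files <- c(comparison = file.path(outdir, "comparison.csv"),
             trail = file.path(outdir, "selection_trail.csv"),
             tree = file.path(outdir, "tree.json"),
             scenarios = file.path(outdir, "scenario_worths.csv"),
             reliability = file.path(outdir, "reliability.csv"),
             log = file.path(outdir, "run_log.txt"))
  write.csv(tab, files["comparison"], row.names = FALSE)
  if (!is.null(tdb$selection))
    write.csv(tdb$selection$trail, files["trail"], row.names = FALSE)
  pl_tree_json(tdb$tree, files["tree"])
  n_points <- n_points %||% cfg$n_points
  wx <- sim_point_weather(n_points, years = cfg$scenario_years,
                          cold_fraction = cfg$cold_fraction,
                          seed = cfg$seed + 8)
  sow <- sowing_windows(study$env$fields$planting_date,
                        k = cfg$n_sowing_windows)
  scen <- simulate_scenarios(tdb$tree, wx, seasons = cfg$scenario_years,
                             sowing_dates = sow)
  rel <- top_k_vs_check(scen$average, k = cfg$top_k, check = study$check,
                        yield_model = study$model)
  scen_long <- data.frame(scen$grid[rep(seq_len(nrow(scen$grid)),
                                        each = ncol(scen$worths)), ],
                          item = rep(colnames(scen$worths),
                                     nrow(scen$grid)),
                          worth = as.vector(t(scen$worths)))
  write.csv(scen_long, files["scenarios"], row.names = FALSE)
  write.csv(rel, files["reliability"], row.names = FALSE)
  writeLines(c(
    paste("pltricot", as.character(utils::packageVersion("pltricot"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed:", cfg$seed),
    paste("farm fields:", nrow(study$env$fields)),
    paste("farm plots:", nrow(study$tricot$yield)),
    paste("station plots:", nrow(study$station$plots)),
    paste("station plots per station-season field:",
          nrow(study$station$plots) /
            (length(unique(study$station$plots$location)) *
               length(unique(study$station$plots$season)))),
    paste("scenarios per point:",
          nrow(scen$grid) / length(unique(scen$grid$point_id))),
    paste("selected covariates:", paste(tdb$selected, collapse = ", "))),
    files["log"])
  invisible(list(comparison = tab, scenarios = scen, reliability = rel,
                 files = files))
}
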