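# Synthetic two-arm trial generator. Emulates the structure the analysis
# assumes: a large station genotype panel with SNP markers, a subset
# distributed to farmer fields in incomplete blocks of 3 test genotypes plus
# a check, latent Plackett-Luce worths with a night-temperature-threshold
# genotype-by-environment switch, farmer rankings drawn by Luce sampling,
# and replicated station trials with grain yield and 1-5 appreciation
# scores. All generators take explicit integer seeds and leave the global
# RNG untouched.

#' Simulate a biallelic SNP dosage matrix
#'
#' Per-SNP minor allele frequencies are drawn uniformly in
#' `[maf_low, maf_high]`; dosages are Binomial(2, p) counts (Hardy-Weinberg).
#'
#' @param n_genotypes,n_snps counts (>= 2).
#' @param maf_low,maf_high allele-frequency bounds, `0 < low <= high <= 0.5`.
#' @param seed integer seed.
#' @return genotype x SNP integer matrix with dosages in \{0, 1, 2\}.
#' @export
sim_markers <- function(n_genotypes, n_snps, maf_low = 0.05, maf_high = 0.5,
                        seed = 1) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  stopifnot(n_genotypes >= 2, n_snps >= 2)
  withr::with_seed(seed, {
    p <- runif(n_snps, maf_low, maf_high)
    m <- matrix(rbinom(n_genotypes * n_snps, 2, rep(p, each = n_genotypes)),
                n_genotypes, n_snps)
    dimnames(m) <- list(sprintf("G%03d", seq_len(n_genotypes)),
                        sprintf("SNP%04d", seq_len(n_snps)))
    attr(m, "maf") <- p
    m
  })
}

#' Simulate sites, daily weather and growth-phase windows
#'
#' Every farmer field is its own site observed in one season; stations are
#' additional sites observed in every season. A configurable fraction of
#' farm sites is colder than every station (site-mean minimum temperature
#' below the coldest station mean), emulating highland farms outside the
#' stations' temperature range. Daily `tmin <= tmax` always holds.
#'
#' @param n_fields,n_seasons,n_stations counts (>= 1).
#' @param cold_fraction probability that a farm site is cold (default 0.3).
#' @param seed integer seed.
#' @param start_year first season's calendar year.
#' @param phase_days days from planting to flowering/maturity/harvest.
#' @param station_tmin target mean night temperature at stations (deg C).
#' @param daily_sd day-to-day temperature standard deviation.
#' @return list with `fields` (field_id, season, site_id, planting_date,
#'   cold), `stations`, `phases` (per site-season phase dates), `weather`
#'   (site_id, date, tmin, tmax, precip).
#' @export
sim_environment <- function(n_fields, n_seasons = 3, n_stations = 2,
                            cold_fraction = 0.3, seed = 1,
                            start_year = 2016,
                            phase_days = c(flowering = 70, maturity = 110,
                                           harvest = 140),
                            station_tmin = 16, daily_sd = 1.5) {
  stopifnot(n_fields >= 1, n_seasons >= 1, n_stations >= 1,
            cold_fraction >= 0, cold_fraction <= 1)
  withr::with_seed(seed, {
    seasons <- paste0("S", seq_len(n_seasons))
    season_start <- as.Date(sprintf("%d-06-15", start_year + seq_len(n_seasons) - 1))
    st_mean <- rnorm(n_stations, station_tmin, 0.5)
    coldest <- min(st_mean)
    field_id <- sprintf("F%04d", seq_len(n_fields))
    season <- rep(seasons, length.out = n_fields)
    cold <- runif(n_fields) < cold_fraction
    site_mean <- ifelse(cold, coldest - runif(n_fields, 1.5, 4),
                        coldest + runif(n_fields, 0.5, 3))
    planting <- season_start[match(season, seasons)] +
      sample(-10:10, n_fields, replace = TRUE)
    fields <- data.frame(field_id = field_id, season = season,
                         site_id = field_id, planting_date = planting,
                         cold = cold)
    mk_series <- function(site, mean_tmin, from, to) {
      dates <- seq(from, to, by = "day")
      nd <- length(dates)
      tmin <- mean_tmin + rnorm(nd, 0, daily_sd)
      tmax <- tmin + 8 + abs(rnorm(nd, 0, 2))
      precip <- ifelse(runif(nd) < 0.4, rgamma(nd, shape = 0.8, scale = 8), 0)
      data.frame(site_id = site, date = dates, tmin = tmin, tmax = tmax,
                 precip = round(precip, 2))
    }
    phases <- list(); weather <- list()
    for (i in seq_len(n_fields)) {
      p <- planting[i]
      phases[[i]] <- data.frame(
        site_id = field_id[i], season = season[i], type = "farm",
        planting_date = p, flowering_date = p + phase_days[["flowering"]],
        maturity_date = p + phase_days[["maturity"]],
        harvest_date = p + phase_days[["harvest"]])
      weather[[i]] <- mk_series(field_id[i], site_mean[i], p - 5,
                                p + phase_days[["harvest"]] + 5)
    }
    st_id <- sprintf("ST%d", seq_len(n_stations))
    for (j in seq_len(n_stations)) {
      for (s in seq_len(n_seasons)) {
        p <- season_start[s]
        phases[[length(phases) + 1]] <- data.frame(
          site_id = st_id[j], season = seasons[s], type = "station",
          planting_date = p, flowering_date = p + phase_days[["flowering"]],
          maturity_date = p + phase_days[["maturity"]],
          harvest_date = p + phase_days[["harvest"]])
        weather[[length(weather) + 1]] <-
          mk_series(st_id[j], st_mean[j], p - 5,
                    p + phase_days[["harvest"]] + 5)
      }
    }
    list(fields = fields,
         stations = data.frame(station_id = st_id, mean_tmin = st_mean),
         phases = do.call(rbind, phases),
         weather = do.call(rbind, weather))
  })
}

#' Latent genotype-by-environment model behind the generators
#'
#' Each genotype has a base log-worth (its additive genetic value) and a
#' shift that is added when the switch covariate strictly exceeds the
#' threshold; fields at or below the threshold take base worths only. Grain
#' yield is linked linearly to log-worth (scale-stable in worth ratios),
#' with Gaussian plot noise truncated at zero.
#'
#' @param log_worth_base,log_worth_shift named per-genotype numerics (the
#'   two must cover the same genotypes).
#' @param switch_covariate covariate name (default `"minNT_veg"`, the
#'   minimum night temperature over the vegetative phase).
#' @param switch_threshold threshold in covariate units (default 11.5 deg C).
#' @param yield_scale t/ha per unit log-worth (> 0); @param noise_sd plot
#'   noise (t/ha, >= 0); @param gy_intercept mean yield; @param field_sd
#'   between-field yield standard deviation.
#' @return a `true_model` list.
#' @export
true_model <- function(log_worth_base, log_worth_shift,
                       switch_covariate = "minNT_veg",
                       switch_threshold = 11.5, yield_scale = 0.8,
                       noise_sd = 0.4, gy_intercept = 3, field_sd = 0.3) {
  if (is.null(names(log_worth_base)) ||
      !setequal(names(log_worth_base), names(log_worth_shift)))
    stop("base and shift must be named and cover the same genotypes")
  stopifnot(noise_sd >= 0, yield_scale > 0, field_sd >= 0)
  structure(list(log_worth_base = log_worth_base,
                 log_worth_shift = log_worth_shift[names(log_worth_base)],
                 switch_covariate = switch_covariate,
                 switch_threshold = switch_threshold,
                 yield_scale = yield_scale, noise_sd = noise_sd,
                 gy_intercept = gy_intercept, field_sd = field_sd),
            class = "true_model")
}

#' Draw a true model from marker data
#'
#' Base log-worths are additive genetic values `u = Z beta` with
#' marker effects `beta ~ N(0, 1)`, centered and scaled to `base_sd`; shifts
#' are drawn from an independent marker-effect vector scaled to `shift_sd`
#' (so genetically similar genotypes respond similarly to the environment
#' switch). `shift_sd = 0` disables genotype-by-environment interaction.
#'
#' @param markers a [sim_markers()] matrix.
#' @param base_sd,shift_sd standard deviations of base and shift log-worths.
#' @param seed integer seed.
#' @param ... passed to [true_model()].
#' @export
sim_true_model <- function(markers, base_sd = 1, shift_sd = 1.2, seed = 1,
                           ...) {
  withr::with_seed(seed, {
    Z <- scale(markers, center = TRUE, scale = FALSE)
    mk <- function(s) {
      u <- drop(Z %*% rnorm(ncol(Z)))
      u <- u - mean(u)
      if (s == 0 || sd(u) == 0) u * 0 else u / sd(u) * s
    }
    base <- mk(base_sd)
    shift <- mk(shift_sd)
    names(base) <- names(shift) <- rownames(markers)
    true_model(log_worth_base = base, log_worth_shift = shift, ...)
  })
}

#' Per-field true worth vectors
#'
#' For each field, `log-worth(i) = base(i) + shift(i) * [covariate >
#' threshold]` (strict inequality; a field exactly at the threshold takes
#' base worths), normalized to sum to one.
#'
#' @param model a [true_model()].
#' @param covariates data.frame of per-field covariates containing
#'   `model$switch_covariate`.
#' @return numeric matrix, one row per field, columns = genotypes, rows
#'   summing to 1.
#' @export
sim_true_worths <- function(model, covariates) {
  x <- covariates[[model$switch_covariate]]
  if (is.null(x) || anyNA(x))
    stop("covariate '", model$switch_covariate,
         "' missing or incomplete in 'covariates'")
  lam <- outer(as.numeric(x > model$switch_threshold),
               model$log_worth_shift) +
    matrix(model$log_worth_base, nrow = length(x),
           ncol = length(model$log_worth_base), byrow = TRUE)
  a <- exp(lam)
  a <- a / rowSums(a)
  colnames(a) <- names(model$log_worth_base)
  a
}

#' Balanced tricot design: 3 test genotypes + 1 check per field
#'
#' Assigns each field three distinct test genotypes (greedy least-used-first
#' allocation with random tie-breaking, so test genotype frequencies differ
#' by at most one) plus the common check.
#'
#' @param fields data.frame with `field_id` and `season` (e.g.
#'   `sim_environment()$fields`).
#' @param genotypes test genotype ids; @param check check variety id (not a
#'   test genotype).
#' @param seed integer seed.
#' @return `fields` with added columns `geno1`, `geno2`, `geno3`, `check`.
#' @export
sim_tricot_design <- function(fields, genotypes, check, seed = 1) {
  stopifnot(length(genotypes) >= 3, !(check %in% genotypes))
  withr::with_seed(seed, {
    counts <- setNames(numeric(length(genotypes)), genotypes)
    picks <- matrix("", nrow(fields), 3)
    for (i in seq_len(nrow(fields))) {
      pr <- order(counts + runif(length(counts)))
      g <- genotypes[pr[1:3]]
      counts[g] <- counts[g] + 1
      picks[i, ] <- g
    }
    fields$geno1 <- picks[, 1]; fields$geno2 <- picks[, 2]
    fields$geno3 <- picks[, 3]; fields$check <- check
    fields
  })
}

#' Sample best-first orderings by the Luce rule
#'
#' Winners are drawn sequentially with probability proportional to the
#' remaining items' worths — exactly the Plackett-Luce generative model.
#'
#' @param n number of orderings; @param worths named positive worths.
#' @param seed integer seed.
#' @return character matrix, one best-first ordering per row.
#' @export
rluce <- function(n, worths, seed = 1) {
  if (any(worths <= 0)) stop("worths must be positive")
  withr::with_seed(seed, {
    t(replicate(n, sample(names(worths), length(worths), prob = worths)))
  })
}

#' Simulate a decentralized tricot trial
#'
#' For each field the four entries are ranked by Luce sampling from the
#' field's true worths, and each plot's grain yield is
#' `gy_intercept + field effect + yield_scale * centered log-worth + noise`,
#' truncated at zero.
#'
#' @param design a [sim_tricot_design()] data.frame.
#' @param worths per-field worth matrix from [sim_true_worths()] (rows
#'   aligned with `design`).
#' @param model the [true_model()]; @param seed integer seed.
#' @return list with `rankings` (a [ranking_set()], group = field/season)
#'   and `yield` (data.frame field_id, season, genotype, gy; 4 rows per
#'   field).
#' @export
sim_tricot_trial <- function(design, worths, model, seed = 1) {
  n <- nrow(design)
  if (nrow(worths) != n) stop("'worths' rows must align with 'design'")
  entries <- cbind(design$geno1, design$geno2, design$geno3, design$check)
  if (!all(entries %in% colnames(worths)))
    stop("design entries must all have worths")
  if (any(worths <= 0)) stop("worths must be positive")
  withr::with_seed(seed, {
    lw_all <- log(worths) - rowMeans(log(worths))
    ords <- vector("list", n)
    gy <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      e <- entries[i, ]
      w <- worths[i, e]
      ords[[i]] <- sample(e, 4, prob = w)
      feff <- rnorm(1, 0, model$field_sd)
      gy[i, ] <- pmax(0, model$gy_intercept + feff +
                        model$yield_scale * lw_all[i, e] +
                        rnorm(4, 0, model$noise_sd))
    }
    rankings <- ranking_set(ords, items = colnames(worths),
                            group = design[, c("field_id", "season")])
    yield <- data.frame(field_id = rep(design$field_id, each = 4),
                        season = rep(design$season, each = 4),
                        genotype = as.vector(t(entries)),
                        gy = as.vector(t(gy)))
    list(rankings = rankings, yield = yield)
  })
}

#' Replicated station design
#'
#' Full factorial of genotypes x replicates x locations x seasons, with
#' genotypes grouped into incomplete blocks of `block_size` within each
#' replicate (no lattice efficiency optimization).
#'
#' @param genotypes genotype ids; @param n_locations,n_seasons,n_reps
#'   design counts; @param block_size genotypes per block.
#' @return data.frame `location, season, replicate, block, genotype`
#'   (`n_genotypes * n_reps` plots per location-season).
#' @export
sim_station_design <- function(genotypes, n_locations = 2, n_seasons = 2,
                               n_reps = 2, block_size = 20) {
  d <- expand.grid(genotype = genotypes,
                   replicate = seq_len(n_reps),
                   location = paste0("L", seq_len(n_locations)),
                   season = paste0("Y", seq_len(n_seasons)),
                   stringsAsFactors = FALSE)
  d$block <- ceiling(match(d$genotype, genotypes) / block_size)
  d[, c("location", "season", "replicate", "block", "genotype")]
}

#' Simulate a centralized station trial
#'
#' Grain yield per plot is location + season + replicate + block effects
#' plus the genotype's genetic value (scaled as in the tricot arm) and
#' Gaussian noise. Stations are assumed to sit in the above-threshold
#' (warm) regime of the environment switch, so the station genetic value is
#' `base + shift`; the overall-appreciation score of each rater is a
#' discretized noisy monotone transform of the same genetic value on a 1-5
#' integer scale (no half values).
#'
#' @param design a [sim_station_design()] data.frame.
#' @param model the [true_model()]; @param seed integer seed.
#' @param n_raters raters per location-season (genders alternate M/F).
#' @param sd_loc,sd_season,sd_rep,sd_block effect standard deviations.
#' @param oa_slope latent-scale slope of the appreciation transform;
#'   @param oa_rater_sd rater noise on the latent scale.
#' @param shifted `FALSE` places stations in the below-threshold regime.
#' @return list with `plots` (design + `plot_id`, `gy`) and `oa`
#'   (plot_id, genotype, location, season, rater, gender, score).
#' @export
sim_station_trial <- function(design, model, seed = 1, n_raters = 10,
                              sd_loc = 0.5, sd_season = 0.3, sd_rep = 0.2,
                              sd_block = 0.1, oa_slope = 1.2,
                              oa_rater_sd = 0.5, shifted = TRUE) {
  g <- model$log_worth_base
  if (shifted) g <- g + model$log_worth_shift
  miss <- setdiff(unique(design$genotype), names(g))
  if (length(miss)) stop("genotype(s) without genetic value: ",
                         paste(head(miss, 5), collapse = ", "))
  withr::with_seed(seed, {
    locs <- unique(design$location); seas <- unique(design$season)
    le <- setNames(rnorm(length(locs), 0, sd_loc), locs)
    se <- setNames(rnorm(length(seas), 0, sd_season), seas)
    repkey <- interaction(design$location, design$season, design$replicate)
    re <- setNames(rnorm(nlevels(repkey), 0, sd_rep), levels(repkey))
    blkkey <- interaction(repkey, design$block)
    be <- setNames(rnorm(nlevels(blkkey), 0, sd_block), levels(blkkey))
    gv <- g[design$genotype]
    gy <- pmax(0, model$gy_intercept + le[design$location] +
                 se[design$season] + re[as.character(repkey)] +
                 be[as.character(blkkey)] + model$yield_scale * gv +
                 rnorm(nrow(design), 0, model$noise_sd))
    plots <- cbind(plot_id = sprintf("P%05d", seq_len(nrow(design))),
                   design, gy = as.numeric(gy))
    # raters score every plot of their location-season
    gz <- if (sd(g) > 0) (gv - mean(g)) / sd(g) else gv * 0
    oa <- do.call(rbind, lapply(seq_len(n_raters), function(k) {
      latent <- 3 + oa_slope * gz + rnorm(nrow(plots), 0, oa_rater_sd)
      data.frame(plot_id = plots$plot_id, genotype = plots$genotype,
                 location = plots$location, season = plots$season,
                 rater = sprintf("R%02d", k),
                 gender = if (k %% 2 == 1) "M" else "F",
                 score = pmin(5L, pmax(1L, as.integer(round(latent)))))
    }))
    list(plots = plots, oa = oa)
  })
}

#' Long-run point weather for scenario extrapolation
#'
#' Daily series per point over whole calendar years, drawn from the same
#' climate family as [sim_environment()] (a `cold_fraction` of points sits
#' below the coldest station's temperature regime).
#'
#' @param n_points number of target points; @param years calendar years to
#'   cover; @param cold_fraction fraction of cold points;
#' @param station_tmin,daily_sd as in [sim_environment()];
#' @param seed integer seed.
#' @return data.frame `point_id, date, tmin, tmax, precip`.
#' @export
sim_point_weather <- function(n_points, years = 2001:2015,
                              cold_fraction = 0.3, station_tmin = 16,
                              daily_sd = 1.5, seed = 1) {
  withr::with_seed(seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
                 as.Date(sprintf("%d-12-31", max(years) + 1)), by = "day")
    nd <- length(dates)
    cold <- runif(n_points) < cold_fraction
    mean_tmin <- ifelse(cold, station_tmin - runif(n_points, 1.5, 4),
                        station_tmin + runif(n_points, 0.5, 3))
    do.call(rbind, lapply(seq_len(n_points), function(i) {
      tmin <- mean_tmin[i] + rnorm(nd, 0, daily_sd)
      data.frame(point_id = sprintf("PT%04d", i), date = dates,
                 tmin = tmin, tmax = tmin + 8 + abs(rnorm(nd, 0, 2)),
                 precip = ifelse(runif(nd) < 0.4,
                                 round(rgamma(nd, 0.8, scale = 8), 2), 0))
    }))
  })
}
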