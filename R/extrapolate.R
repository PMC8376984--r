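# Applying a fitted Plackett-Luce tree across simulated seasonal scenarios:
# win probabilities, reliability against a check variety, scenario averaging
# and expected yield gain of the top-k recommendation.

#' Probability of winning against all other genotypes in the set
#'
#' Under the Plackett-Luce model the probability that genotype i beats all
#' others is its normalized worth `alpha_i / sum(alpha)`.
#'
#' @param worths positive named worths.
#' @return named probabilities summing to 1.
#' @export
win_probability <- function(worths) {
  if (any(worths <= 0)) stop("worths must be positive")
  normalize_worths(worths)
}

#' Reliability: probability of outperforming a check variety
#'
#' `P(i beats j) = alpha_i / (alpha_i + alpha_j)`, so
#' `reliability(i, j) + reliability(j, i) = 1`.
#'
#' @param worths positive named worths; @param item,check genotype ids.
#' @return probability in (0, 1).
#' @examples
#' reliability(c(A = 0.3, B = 0.1), "A", "B")  # 0.75
#' @export
reliability <- function(worths, item, check) {
  if (!all(c(item, check) %in% names(worths)))
    stop("unknown genotype id")
  worths[[item]] / (worths[[item]] + worths[[check]])
}

#' Predict genotype worths across seasonal scenarios
#'
#' For every point x season x sowing date (excluded seasons dropped), builds
#' growth-phase windows from the sowing date plus fixed phase durations,
#' computes the agroclimatic covariates from the point's historical weather,
#' routes the scenario through the tree, and averages the win probabilities
#' per point (and per point x sowing date).
#'
#' @param tree a [pl_tree()] (or deserialized tree).
#' @param weather data.frame `point_id, date, tmin, tmax, precip` covering
#'   every scenario's growing window (see [sim_point_weather()]).
#' @param seasons season labels = calendar years (integers).
#' @param sowing_dates `Date`s whose month-day templates define the sowing
#'   windows within each season (typically from [sowing_windows()]).
#' @param phase_days days from sowing to flowering/maturity/harvest.
#' @param exclude_seasons seasons (years) to drop, e.g. those used as test
#'   data.
#' @param gdd_base passed to [climate_indices()].
#' @return list with `grid` (one row per scenario: point_id, season,
#'   sowing_date, leaf), `worths` (matrix aligned with `grid` rows),
#'   `average` (point x genotype mean win probabilities, rows sum to 1) and
#'   `by_sowing` (point x sowing-window list of averages).
#' @export
simulate_scenarios <- function(tree, weather, seasons, sowing_dates,
                               phase_days = c(flowering = 70, maturity = 110,
                                              harvest = 140),
                               exclude_seasons = NULL, gdd_base = 0) {
  seasons <- setdiff(seasons, exclude_seasons)
  if (!length(seasons)) stop("no seasons left after exclusion")
  points <- unique(weather$point_id)
  weather$date <- as.Date(weather$date)
  md <- format(as.Date(sowing_dates), "%m-%d")
  grid <- expand.grid(point_id = points, season = seasons,
                      sowing = seq_along(md), stringsAsFactors = FALSE)
  grid$sowing_date <- as.Date(sprintf("%d-%s", grid$season, md[grid$sowing]))
  n <- nrow(grid)
  W <- matrix(NA_real_, n, length(tree$items),
              dimnames = list(NULL, tree$items))
  leaf <- integer(n)
  wsplit <- split(weather, weather$point_id)
  for (i in seq_len(n)) {
    p <- grid$sowing_date[i]
    pw <- phase_windows(p, p + phase_days[["flowering"]],
                        p + phase_days[["maturity"]],
                        p + phase_days[["harvest"]])
    wtab <- wsplit[[grid$point_id[i]]]
    cov <- tryCatch(climate_indices(wtab, pw, gdd_base = gdd_base),
                    error = function(e)
                      stop("scenario ", grid$point_id[i], "/", grid$season[i],
                           "/sowing ", grid$sowing[i], ": ",
                           conditionMessage(e)))
    pr <- predict(tree, cov)
    W[i, ] <- pr[1, ]
    leaf[i] <- attr(pr, "leaf")[1]
  }
  grid$leaf <- leaf
  avg <- rowsum(W, grid$point_id) / as.vector(table(grid$point_id)[
    sort(unique(grid$point_id))])
  by_sowing <- lapply(seq_along(md), function(k) {
    sel <- grid$sowing == k
    rowsum(W[sel, , drop = FALSE], grid$point_id[sel]) /
      as.vector(table(grid$point_id[sel])[sort(unique(grid$point_id[sel]))])
  })
  names(by_sowing) <- md
  list(grid = grid[, c("point_id", "season", "sowing_date", "leaf")],
       worths = W, average = avg, by_sowing = by_sowing)
}

#' Top-k recommendation versus the check variety
#'
#' Picks the k genotypes with the highest scenario-averaged worth at each
#' point (the check is never part of the recommendation), computes the mean
#' reliability of the top-k against the check, and — when the latent yield
#' model is supplied (synthetic runs) — the expected percentage grain-yield
#' gain of the recommendation over the check under the log-worth yield
#' link. On real data the yield gain is descriptive only.
#'
#' @param average point x genotype matrix of averaged win probabilities
#'   (from [simulate_scenarios()]).
#' @param k recommendation size (default 3, must be < number of genotypes).
#' @param check check genotype id (a column of `average`).
#' @param yield_model optional [true_model()] providing `gy_intercept` and
#'   `yield_scale` for the yield link.
#' @return data.frame per point: `point_id`, `top` (comma-joined ids),
#'   `reliability` (mean of top-k vs check), `yield_gain_pct` (`NA` without
#'   a yield model).
#' @export
top_k_vs_check <- function(average, k = 3, check, yield_model = NULL) {
  if (!(check %in% colnames(average))) stop("check not among genotypes")
  if (k >= ncol(average)) stop("k must be smaller than the genotype count")
  out <- lapply(rownames(average), function(pt) {
    w <- average[pt, ]
    cand <- sort(w[setdiff(names(w), check)], decreasing = TRUE)
    top <- names(cand)[seq_len(k)]
    rel <- mean(vapply(top, function(i) reliability(w, i, check), 0))
    gain <- NA_real_
    if (!is.null(yield_model)) {
      lw <- log(w) - mean(log(w))
      gy <- yield_model$gy_intercept + yield_model$yield_scale * lw
      gain <- (mean(gy[top]) - gy[[check]]) / gy[[check]] * 100
    }
    data.frame(point_id = pt, top = paste(top, collapse = ","),
               reliability = rel, yield_gain_pct = gain)
  })
  do.call(rbind, out)
}
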