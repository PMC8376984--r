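# Accuracy metrics: per-field Kendall tau between predicted and observed
# orderings, season aggregation with sqrt(n) weights, and the benchmark /
# decentralized-model comparison table.

scores_to_ordering <- function(scores) {
  # ties in predicted scores are broken lexicographically by item id
  names(scores)[order(-scores, names(scores))]
}

#' Kendall rank correlation between two orderings
#'
#' `tau = (concordant - discordant) / (m (m - 1) / 2)` over all pairs of the
#' common item set. A named numeric first argument is interpreted as
#' predicted scores and converted to a best-first ordering (ties broken by
#' item id).
#'
#' @param predicted best-first character ordering, or named numeric scores.
#' @param observed best-first character ordering.
#' @return tau in \[-1, 1\].
#' @examples
#' kendall_tau(c("A", "B", "C", "D"), c("A", "C", "B", "D"))  # 4/6
#' @export
kendall_tau <- function(predicted, observed) {
  if (is.numeric(predicted)) predicted <- scores_to_ordering(predicted)
  common <- intersect(predicted, observed)
  m <- length(common)
  if (m < 2) stop("fewer than 2 common items: tau undefined")
  rp <- match(common, predicted)
  ro <- match(common, observed)
  conc <- disc <- 0
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    s <- sign(rp[a] - rp[b]) * sign(ro[a] - ro[b])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / (m * (m - 1) / 2)
}

#' Per-season mean field-level Kendall tau
#'
#' Computes, for every ranked field, the Kendall tau between the predicted
#' worths (restricted to the field's items) and the observed ordering, then
#' averages within season.
#'
#' @param predictions numeric matrix of predicted worths/scores, one row per
#'   record of `observed`, columns named by item (e.g. from
#'   [predict.pl_tree()]), or a single named vector recycled across fields.
#' @param observed a [ranking_set()] whose `group` has a `season` column
#'   (a single season `"all"` is assumed when absent).
#' @return data.frame with columns `season`, `tau` (mean field tau), `n`
#'   (fields evaluated).
#' @export
mean_field_tau <- function(predictions, observed) {
  n <- length(observed)
  if (is.numeric(predictions) && is.null(dim(predictions)))
    predictions <- matrix(predictions, n, length(predictions), byrow = TRUE,
                          dimnames = list(NULL, names(predictions)))
  if (nrow(predictions) != n)
    stop("predictions must have one row per observed field")
  os <- orderings(observed)
  taus <- numeric(n)
  for (i in seq_len(n)) {
    items <- os[[i]]
    miss <- setdiff(items, colnames(predictions))
    if (length(miss))
      stop("missing prediction for item(s) ", paste(miss, collapse = ", "),
           " in field ", observed$group$field_id[i])
    taus[i] <- kendall_tau(predictions[i, items], items)
  }
  season <- if ("season" %in% names(observed$group))
    as.character(observed$group$season) else rep("all", n)
  agg <- aggregate(list(tau = taus), by = list(season = season), FUN = mean)
  agg$n <- as.integer(table(season)[agg$season])
  agg[order(agg$season), ]
}

#' Combine per-season accuracies with square-root sample-size weights
#'
#' `combined = sum(sqrt(n_s) tau_s) / sum(sqrt(n_s))`, the across-season
#' summary used to compare approaches evaluated on seasons of different
#' sizes.
#'
#' @param taus per-season accuracies; @param ns per-season field counts.
#' @return the weighted mean (always within `range(taus)`).
#' @examples
#' combine_weighted(c(0.270, 0.276, 0.203), c(179, 651, 335))  # 0.251
#' @export
combine_weighted <- function(taus, ns) {
  if (!length(taus) || length(taus) != length(ns) || any(ns <= 0))
    stop("need equal-length inputs with positive counts")
  sum(sqrt(ns) * taus) / sum(sqrt(ns))
}

#' Method comparison table across seasons and traits
#'
#' Binds the per-season accuracies of two approaches and appends
#' sqrt(n)-weighted `combined` rows per method and trait.
#'
#' @param benchmark_acc,tdb_acc data.frames with columns `method`, `trait`,
#'   `season`, `n`, `tau` covering the same seasons and traits.
#' @return data.frame `method, trait, season, n, tau` including `combined`
#'   rows.
#' @export
comparison_table <- function(benchmark_acc, tdb_acc) {
  need <- c("method", "trait", "season", "n", "tau")
  for (d in list(benchmark_acc, tdb_acc))
    if (!all(need %in% names(d)))
      stop("accuracy tables need columns ", paste(need, collapse = ", "))
  if (!setequal(unique(benchmark_acc$season), unique(tdb_acc$season)) ||
      !setequal(unique(benchmark_acc$trait), unique(tdb_acc$trait)))
    stop("season/trait sets differ between the two accuracy tables")
  all <- rbind(benchmark_acc[, need], tdb_acc[, need])
  combined <- do.call(rbind, lapply(
    split(all, list(all$method, all$trait), drop = TRUE),
    function(d) data.frame(method = d$method[1], trait = d$trait[1],
                           season = "combined", n = sum(d$n),
                           tau = combine_weighted(d$tau, d$n))))
  out <- rbind(all, combined)
  rownames(out) <- NULL
  out[order(out$method, out$trait, out$season), ]
}
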