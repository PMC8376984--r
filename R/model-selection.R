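# Forward covariate selection for the Plackett-Luce tree using blocked
# cross-validation (seasons as blocks) scored by Akaike weights of the mean
# holdout deviance.

#' Holdout deviance of a tree grown on training rankings
#'
#' Grows a Plackett-Luce tree on the training records using the candidate
#' covariates (a root-only fit when the set is empty), routes the test
#' records through it, and returns `-2 *` the summed test log-likelihood
#' under the leaf worths. Items unseen in a training leaf are only scoreable
#' when leaves are genomic MAP fits (kinship supplied); otherwise an error
#' is raised.
#'
#' @param train,test [ranking_set()]s; @param train_cov,test_cov aligned
#'   covariate data.frames.
#' @param covariates candidate covariate names (possibly empty).
#' @param alpha,min_size,kinship,prior_scale passed to [pl_tree()].
#' @return the holdout deviance (a positive number; uniform worths on
#'   m-item rankings give `2 n log(m!)`).
#' @export
holdout_deviance <- function(train, train_cov, test, test_cov,
                             covariates = character(0), alpha = 0.01,
                             min_size = 0.20, kinship = NULL,
                             prior_scale = 1) {
  if (length(covariates)) {
    miss <- setdiff(covariates, names(test_cov))
    if (length(miss)) stop("test covariates missing: ",
                           paste(miss, collapse = ", "))
  }
  tree <- pl_tree(train, train_cov, alpha = alpha, min_size = min_size,
                  covariates = covariates, kinship = kinship,
                  prior_scale = prior_scale)
  tree_holdout_deviance(tree, test, test_cov)
}

# deviance of test records routed through an already-grown tree
tree_holdout_deviance <- function(tree, test, test_cov) {
  pred <- predict(tree, test_cov)
  ranked <- test$items[sort(unique(test$ord[test$ord > 0]))]
  unseen <- setdiff(ranked, colnames(pred))
  if (length(unseen))
    stop("test item(s) never ranked in training: ",
         paste(unseen, collapse = ", "),
         "; supply a kinship matrix for genomic leaf fits")
  ll <- 0
  os <- orderings(test)
  for (i in seq_along(os)) {
    w <- pred[i, os[[i]]]
    m <- length(w)
    S <- rev(cumsum(rev(w)))
    ll <- ll + test$weights[i] * sum(log(w[-m]) - log(S[-m]))
  }
  -2 * ll
}

#' Akaike weights of candidate models
#'
#' `AIC_m = deviance_m + 2 penalty_m`; weights are
#' `exp(-(AIC_m - min AIC) / 2)` normalized to sum 1 — the probability that
#' candidate m is the best of the set.
#'
#' @param deviances per-candidate (mean holdout) deviances.
#' @param penalty per-candidate effective parameter counts (default 0, i.e.
#'   weights on the raw deviances).
#' @return numeric weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2))  # (0.731, 0.269)
#' @export
akaike_weights <- function(deviances, penalty = 0) {
  if (!length(deviances)) stop("need at least one candidate")
  aic <- deviances + 2 * penalty
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Forward covariate selection by blocked cross-validation
#'
#' Greedy forward selection with seasons as cross-validation blocks: at each
#' step every unused candidate is scored by its leave-one-season-out mean
#' holdout deviance (tree grown on the remaining seasons with the incumbent
#' set plus the candidate); Akaike weights are computed across the incumbent
#' model and all extensions, and the best extension is accepted only if its
#' weight strictly exceeds the incumbent's. Ties are broken by covariate
#' name order, so the procedure is deterministic.
#'
#' The AIC penalty of a model is the mean (over folds) number of leaves
#' times `n_items - 1`, making the criterion sensitive to tree size.
#'
#' @param r a [ranking_set()]; @param cov aligned covariate data.frame.
#' @param blocks per-record block labels (seasons); at least 2 distinct.
#' @param candidates covariate names to select among.
#' @param alpha,min_size,kinship,prior_scale passed to [pl_tree()].
#' @return list with `selected` (character, possibly empty) and `trail`
#'   (data.frame: step, candidate, mean_deviance, penalty, weight,
#'   accepted).
#' @export
forward_select <- function(r, cov, blocks, candidates, alpha = 0.01,
                           min_size = 0.20, kinship = NULL,
                           prior_scale = 1) {
  blocks <- as.character(blocks)
  if (length(blocks) != length(r)) stop("one block label per record required")
  ub <- sort(unique(blocks))
  if (length(ub) < 2) stop("blocked cross-validation needs >= 2 blocks")
  candidates <- sort(candidates)

  cv_model <- function(covset) {
    devs <- numeric(length(ub))
    nleaves <- numeric(length(ub))
    for (b in seq_along(ub)) {
      hold <- blocks == ub[b]
      tr <- r[!hold]; te <- r[hold]
      trc <- cov[!hold, , drop = FALSE]; tec <- cov[hold, , drop = FALSE]
      tree <- pl_tree(tr, trc, alpha = alpha, min_size = min_size,
                      covariates = covset, kinship = kinship,
                      prior_scale = prior_scale)
      nleaves[b] <- length(tree_apply_leaves(tree$node, identity))
      devs[b] <- tree_holdout_deviance(tree, te, tec)
    }
    n_items <- length(unique(r$ord[r$ord > 0]))
    list(mean_dev = mean(devs), devs = devs,
         penalty = mean(nleaves) * (n_items - 1))
  }

  selected <- character(0)
  incumbent <- cv_model(selected)
  trail <- data.frame(step = 0L, candidate = "(null)",
                      mean_deviance = incumbent$mean_dev,
                      penalty = incumbent$penalty, weight = NA_real_,
                      accepted = TRUE)
  step <- 0L
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    step <- step + 1L
    fits <- lapply(remaining, function(v) cv_model(c(selected, v)))
    devs <- c(incumbent$mean_dev, vapply(fits, `[[`, 0, "mean_dev"))
    pens <- c(incumbent$penalty, vapply(fits, `[[`, 0, "penalty"))
    w <- akaike_weights(devs, pens)
    best <- which.max(w[-1])  # ties: first in name order (candidates sorted)
    accepted <- w[1 + best] > w[1]
    trail <- rbind(trail, data.frame(
      step = step, candidate = remaining,
      mean_deviance = devs[-1], penalty = pens[-1], weight = w[-1],
      accepted = accepted & seq_along(remaining) == best))
    if (!accepted) break
    selected <- c(selected, remaining[best])
    incumbent <- fits[[best]]
  }
  list(selected = selected, trail = trail)
}
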