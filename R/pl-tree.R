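# Plackett-Luce trees: recursive binary partitioning of grouped rankings on
# numeric covariates. Each candidate split refits the PL model in both
# children; the split is kept when the Bonferroni-adjusted likelihood-ratio
# test clears the significance gate and both children hold the minimum
# fraction of all records.

# restrict a ranking_set to the items actually ranked in it
restrict_to_present <- function(r) {
  pos <- r$ord > 0
  present <- sort(unique(r$ord[pos]))
  if (length(present) == length(r$items)) return(r)
  items <- r$items[present]
  ord <- r$ord
  remap <- integer(length(r$items))
  remap[present] <- seq_along(present)
  ord[pos] <- remap[ord[pos]]
  structure(list(items = items, ord = ord, group = r$group,
                 weights = r$weights, ties = r$ties), class = "ranking_set")
}

node_fit <- function(r, kinship = NULL, prior_scale = 1) {
  if (!is.null(kinship))
    return(fit_pl_genomic(r, kinship, prior_scale = prior_scale))
  fit_pl(restrict_to_present(r))
}

#' Best threshold for one covariate
#'
#' Scans every candidate threshold (midpoints between consecutive distinct
#' sorted covariate values) whose children both contain at least `min_size_n`
#' records, refits the Plackett-Luce model in each child, and returns the
#' threshold maximizing the log-likelihood gain
#' `(LL_left + LL_right) - LL_parent`.
#'
#' @param r a [ranking_set()] (the records of the current node).
#' @param cov data.frame of covariates aligned row-by-row with the records.
#' @param covariate name of the numeric covariate to scan.
#' @param min_size_n minimum number of records per child.
#' @param parent_fit optional `pl_fit` of the node (refit when omitted).
#' @param scan_tol,scan_iter MM tolerance/iteration cap used during the
#'   warm-started scan; the winning threshold is refit exactly.
#' @return `NULL` when no admissible split exists (constant covariate or
#'   `min_size_n` unattainable); otherwise a list with `covariate`,
#'   `threshold`, `gain` (>= 0), `n_thresholds` (candidates scanned), and the
#'   exact child log-likelihoods `ll_left`, `ll_right`.
#' @export
pl_split_search <- function(r, cov, covariate, min_size_n,
                            parent_fit = NULL, scan_tol = 1e-4,
                            scan_iter = 10) {
  x <- cov[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not found")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("covariate '", covariate, "' must be numeric and complete")
  n <- length(r)
  if (length(x) != n) stop("covariate rows must align with rankings")
  o <- order(x)
  xs <- x[o]
  # candidate boundaries: left = rows 1..t, admissible when both sides fit
  tcand <- which(xs[-n] < xs[-1])
  tcand <- tcand[tcand >= min_size_n & (n - tcand) >= min_size_n]
  if (!length(tcand)) return(NULL)
  rs <- r[o]
  if (is.null(parent_fit)) parent_fit <- fit_pl(restrict_to_present(r),
                                                check_connected = FALSE)
  n_items <- length(r$items)
  parent_alpha <- rep(1e-6, n_items)
  parent_alpha[match(names(parent_fit$worths), r$items)] <- parent_fit$worths
  ll_parent <- cpp_pl_ll(rs$ord, parent_alpha, rs$weights)
  scan <- cpp_split_scan(rs$ord, n_items, rs$weights, tcand, parent_alpha,
                         scan_tol, scan_iter)
  gains <- scan$ll_left + scan$ll_right - ll_parent
  # the scan uses loose warm-started fits to rank candidates; the leaders
  # are refit exactly and the best exact gain wins
  shortlist <- order(gains, decreasing = TRUE)[seq_len(min(5, length(gains)))]
  best <- NULL
  for (j in shortlist) {
    t <- tcand[j]
    fl <- cpp_pl_mm(rs$ord[seq_len(t), , drop = FALSE], n_items,
                    rs$weights[seq_len(t)], parent_alpha, 1e-9, 2000)
    fr <- cpp_pl_mm(rs$ord[(t + 1):n, , drop = FALSE], n_items,
                    rs$weights[(t + 1):n], parent_alpha, 1e-9, 2000)
    g <- fl$loglik + fr$loglik - ll_parent
    if (is.null(best) || g > best$gain)
      best <- list(covariate = covariate,
                   threshold = (xs[t] + xs[t + 1]) / 2, gain = g,
                   n_thresholds = length(tcand),
                   ll_left = fl$loglik, ll_right = fr$loglik)
  }
  best$gain <- max(0, best$gain)
  best
}

#' Significance of a split's likelihood-ratio gain
#'
#' Treats twice the log-likelihood gain as a chi-square statistic with
#' `df` degrees of freedom (one free worth vector per child, gauge fixed:
#' `df = n_items - 1`) and Bonferroni-adjusts across the
#' `n_thresholds * n_covariates` candidates searched, controlling the
#' optimism of threshold selection.
#'
#' @param gain log-likelihood gain (>= 0).
#' @param n_thresholds,n_covariates number of thresholds and covariates
#'   searched over (default 1 each).
#' @param df degrees of freedom of the reference chi-square.
#' @return a p-value in (0, 1], non-increasing in `gain`.
#' @examples
#' pl_split_test(10, df = 3)  # chi-square(3) upper tail at 20
#' @export
pl_split_test <- function(gain, n_thresholds = 1, n_covariates = 1, df) {
  stopifnot(gain >= 0, df >= 1)
  min(1, n_thresholds * n_covariates *
        pchisq(2 * gain, df = df, lower.tail = FALSE))
}

#' Grow a Plackett-Luce tree
#'
#' Recursively splits the rankings on covariate thresholds while the best
#' covariate's Bonferroni-adjusted likelihood-ratio p-value stays below
#' `alpha` and both children retain at least `min_size` of all records.
#' Records with covariate value `<= threshold` go left. Each leaf carries a
#' Plackett-Luce fit of its records; when a kinship matrix is supplied the
#' leaf fits are genomic MAP fits (see [fit_pl_genomic()]), which also covers
#' leaves whose comparison graph would otherwise be disconnected.
#'
#' @param r a [ranking_set()].
#' @param cov data.frame of numeric covariates, one row per ranking record.
#' @param alpha significance gate for a split (default 0.01).
#' @param min_size minimum leaf size as a fraction of the total record count
#'   (default 0.20).
#' @param covariates covariate names to consider (default: all numeric
#'   columns of `cov`).
#' @param kinship optional additive relationship matrix for genomic leaf
#'   fits; @param prior_scale its prior scale.
#' @return a `pl_tree` object; see [predict.pl_tree()].
#' @export
pl_tree <- function(r, cov, alpha = 0.01, min_size = 0.20,
                    covariates = NULL, kinship = NULL, prior_scale = 1) {
  stopifnot(inherits(r, "ranking_set"))
  if (nrow(cov) != length(r)) stop("covariate rows must align with rankings")
  if (is.null(covariates))
    covariates <- names(cov)[vapply(cov, is.numeric, logical(1))]
  N <- length(r)
  min_n <- max(1L, ceiling(min_size * N))
  next_id <- local({ i <- 0L; function() { i <<- i + 1L; i } })
  grow <- function(rr, cc) {
    fit <- node_fit(rr, kinship, prior_scale)
    id <- next_id()
    best <- NULL
    if (length(covariates) && length(rr) >= 2 * min_n) {
      # likelihood-ratio gains are measured against the node's ML fit even
      # when leaves are reported as genomic MAP fits
      sfit <- if (is.null(kinship)) fit else
        fit_pl(restrict_to_present(rr), check_connected = FALSE)
      for (v in covariates) {
        cand <- pl_split_search(rr, cc, v, min_n, parent_fit = sfit)
        if (!is.null(cand) && (is.null(best) || cand$gain > best$gain))
          best <- cand
      }
    }
    if (!is.null(best)) {
      df <- length(unique(rr$ord[rr$ord > 0])) - 1
      p <- pl_split_test(best$gain, best$n_thresholds,
                         length(covariates), df)
      if (p < alpha) {
        left <- best$covariate
        go_left <- cc[[left]] <= best$threshold
        return(list(id = id, type = "split", covariate = best$covariate,
                    threshold = best$threshold, gain = best$gain,
                    p_value = p, n = length(rr),
                    left = grow(rr[go_left], cc[go_left, , drop = FALSE]),
                    right = grow(rr[!go_left], cc[!go_left, , drop = FALSE])))
      }
    }
    list(id = id, type = "leaf", n = length(rr), fit = fit)
  }
  structure(list(node = grow(r, cov), items = r$items, alpha = alpha,
                 min_size = min_size, n_records = N,
                 covariates = covariates),
            class = "pl_tree")
}

tree_apply_leaves <- function(node, f) {
  if (node$type == "leaf") return(list(f(node)))
  c(tree_apply_leaves(node$left, f), tree_apply_leaves(node$right, f))
}

#' @export
print.pl_tree <- function(x, ...) {
  cat("Plackett-Luce tree:", x$n_records, "rankings,",
      length(tree_apply_leaves(x$node, identity)), "leaf/leaves\n")
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      top <- names(sort(node$fit$worths, decreasing = TRUE))
      cat(pad, "leaf [", node$id, "] n=", node$n, " top: ",
          paste(head(top, 3), collapse = " > "), "\n", sep = "")
    } else {
      cat(pad, node$covariate, " <= ", signif(node$threshold, 5),
          "  (p=", format(node$p_value, digits = 3), ")\n", sep = "")
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  rec(x$node, 0)
  invisible(x)
}

#' Leaf-level log-likelihood of a tree (sum over leaves)
#' @param tree a `pl_tree`.
#' @export
pl_tree_loglik <- function(tree) {
  sum(unlist(tree_apply_leaves(tree$node, function(l) l$fit$loglik)))
}

# worths of a leaf expanded to the full tree item set; items the leaf never
# ranked are imputed at the smallest observed leaf worth and flagged
leaf_worths_full <- function(leaf_fit, items) {
  w <- leaf_fit$worths
  out <- setNames(rep(min(w), length(items)), items)
  out[names(w)] <- w
  normalize_worths(out)
}

#' Predict per-row worth vectors from a Plackett-Luce tree
#'
#' Routes each covariate row down the tree (`<=` goes left, `>` right; a row
#' exactly at a threshold goes left) and returns the normalized worths of the
#' leaf it lands in.
#'
#' @param object a `pl_tree`.
#' @param newdata data.frame containing every split covariate.
#' @param ... unused.
#' @return numeric matrix, one row per input row, one column per tree item,
#'   rows summing to 1; attribute `"leaf"` gives the landing leaf id per row.
#' @export
predict.pl_tree <- function(object, newdata, ...) {
  route <- function(node, row) {
    if (node$type == "leaf") return(node)
    v <- row[[node$covariate]]
    if (is.null(v) || is.na(v))
      stop("missing split covariate '", node$covariate, "'")
    if (v <= node$threshold) route(node$left, row) else route(node$right, row)
  }
  n <- nrow(newdata)
  out <- matrix(NA_real_, n, length(object$items),
                dimnames = list(NULL, object$items))
  leaf_ids <- integer(n)
  cache <- list()
  for (i in seq_len(n)) {
    nd <- route(object$node, newdata[i, , drop = FALSE])
    key <- as.character(nd$id)
    if (is.null(cache[[key]]))
      cache[[key]] <- leaf_worths_full(nd$fit, object$items)
    out[i, ] <- cache[[key]]
    leaf_ids[i] <- nd$id
  }
  attr(out, "leaf") <- leaf_ids
  out
}

#' Serialize / deserialize a Plackett-Luce tree as JSON
#'
#' Stores split covariates, thresholds and leaf worths, enough to reproduce
#' predictions exactly; fit diagnostics are not preserved.
#'
#' @param tree a `pl_tree`; @param path optional file to write to.
#' @return `pl_tree_json` returns the JSON string (invisibly when `path` is
#'   given); `pl_tree_from_json` rebuilds a predict-capable `pl_tree`.
#' @export
pl_tree_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (node$type == "leaf")
      return(list(id = node$id, type = "leaf", n = node$n,
                  worths = as.list(node$fit$worths)))
    list(id = node$id, type = "split", covariate = node$covariate,
         threshold = node$threshold, p_value = node$p_value, n = node$n,
         left = strip(node$left), right = strip(node$right))
  }
  js <- jsonlite::toJSON(list(items = tree$items, alpha = tree$alpha,
                              min_size = tree$min_size,
                              n_records = tree$n_records,
                              node = strip(tree$node)),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @param json a JSON string or file path produced by [pl_tree_json()].
#' @rdname pl_tree_json
#' @export
pl_tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rebuild <- function(node) {
    if (node$type == "leaf") {
      w <- unlist(node$worths)
      return(list(id = node$id, type = "leaf", n = node$n,
                  fit = list(worths = w)))
    }
    list(id = node$id, type = "split", covariate = node$covariate,
         threshold = node$threshold, p_value = node$p_value, n = node$n,
         left = rebuild(node$left), right = rebuild(node$right))
  }
  structure(list(node = rebuild(x$node), items = unlist(x$items),
                 alpha = x$alpha, min_size = x$min_size,
                 n_records = x$n_records, covariates = NULL),
            class = "pl_tree")
}
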