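# Core Plackett-Luce likelihood and fitting. The model assigns each item i a
# positive worth alpha_i; a best-first ordering is built by repeatedly picking
# the winner among the remaining items with probability alpha_i / sum(alpha).
# Normalized worths equal the probability of winning against all others.

normalize_worths <- function(alpha) alpha / sum(alpha)

worths_as_vector <- function(w, items) {
  if (is.null(names(w))) {
    if (length(w) != length(items)) stop("worth length mismatch")
    names(w) <- items
  }
  miss <- setdiff(items, names(w))
  if (length(miss))
    stop("item(s) without worth: ", paste(head(miss, 5), collapse = ", "))
  w <- w[items]
  if (any(!is.finite(w)) || any(w <= 0)) stop("worths must be positive")
  w
}

#' Plackett-Luce log-likelihood of a ranking set
#'
#' The likelihood of a full ordering is the product of stagewise choice
#' probabilities: at each stage the observed winner is drawn from the
#' remaining items with probability proportional to its worth. Single-item
#' (or final-stage) choices contribute zero.
#'
#' @param r a [ranking_set()].
#' @param worths positive numeric vector of worths, named by item (any
#'   positive scale; the likelihood is invariant to a common factor).
#' @return the weighted log-likelihood (<= 0 for normalized stage choices).
#' @examples
#' r <- ranking_set(list(c("A", "B", "C")))
#' pl_loglik(r, c(A = 0.5, B = 0.3, C = 0.2))  # log(0.3)
#' @export
pl_loglik <- function(r, worths) {
  a <- worths_as_vector(worths, r$items)
  cpp_pl_ll(r$ord, as.numeric(a), r$weights)
}

new_pl_fit <- function(alpha, items, loglik, iter, converged, method) {
  alpha <- normalize_worths(alpha)
  names(alpha) <- items
  structure(list(worths = alpha, log_worths = log(alpha) - mean(log(alpha)),
                 loglik = loglik, deviance = -2 * loglik,
                 iterations = iter, converged = converged, method = method),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  cat("Plackett-Luce fit (", x$method, "), ", length(x$worths), " items\n",
      "log-likelihood ", format(x$loglik), ", deviance ", format(x$deviance),
      ", ", x$iterations, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(round(sort(x$worths, decreasing = TRUE), 4))
  invisible(x)
}

#' Maximum-likelihood Plackett-Luce fit
#'
#' Fits worths by the monotone MM (minorize-maximize) algorithm of Hunter.
#' The MLE exists only when the pairwise win/loss graph is strongly
#' connected; disconnected data raise an error naming the components (use
#' [fit_pl_genomic()] for a regularized fit in that case).
#'
#' @param r a [ranking_set()].
#' @param tol convergence tolerance on the maximum absolute change of
#'   log-worths between iterations.
#' @param max_iter iteration cap; non-convergence is flagged and the best
#'   iterate returned.
#' @param check_connected set `FALSE` to skip the connectivity check (used
#'   internally during tree split scans).
#' @return a `pl_fit`: normalized `worths` (summing to 1), centered
#'   `log_worths`, `loglik`, `deviance` (-2 log-likelihood), `iterations`,
#'   `converged`.
#' @examples
#' r <- ranking_set(list(c("A", "B"), c("A", "B"), c("A", "B"), c("B", "A")))
#' fit_pl(r)$worths  # (0.75, 0.25): the two-item closed form wins/(wins+losses)
#' @export
fit_pl <- function(r, tol = 1e-9, max_iter = 1000, check_connected = TRUE) {
  if (check_connected) {
    conn <- check_connectivity(r)
    if (!conn$connected) {
      comps <- split(names(conn$membership), conn$membership)
      stop("comparison graph not strongly connected; components: ",
           paste(vapply(comps, function(x) paste(head(x, 4), collapse = ","),
                        character(1)), collapse = " | "),
           ". Consider fit_pl_genomic() with a kinship prior.")
    }
  }
  n_items <- length(r$items)
  res <- cpp_pl_mm(r$ord, n_items, r$weights, rep(1 / n_items, n_items),
                   tol, max_iter)
  new_pl_fit(res$alpha, r$items, res$loglik, res$iter, res$converged, "MM")
}

#' MAP Plackett-Luce fit with an additive genomic-relationship prior
#'
#' Maximizes `loglik(lambda) - 0.5 * lambda' solve(prior_scale * K + ridge I)
#' lambda` over log-worths `lambda`, i.e. a maximum a-posteriori fit under a
#' multivariate normal prior whose covariance is proportional to the additive
#' relationship matrix K. Genetically similar genotypes are shrunk towards
#' each other, which keeps the fit identifiable even when the comparison
#' graph is disconnected or some genotypes are unranked (their worths are
#' inferred from relatives).
#'
#' @param r a [ranking_set()]; every ranked item must appear in `K`.
#' @param K symmetric positive semi-definite relationship matrix with
#'   dimnames; worths are returned for all its genotypes.
#' @param prior_scale prior variance multiplier (default 1). Large values
#'   approach the unpenalized [fit_pl()] solution; small values pull worths
#'   towards uniform.
#' @param tol,max_iter convergence control passed to the BFGS optimizer.
#' @param ridge small diagonal added to the prior covariance for
#'   invertibility.
#' @return a `pl_fit` over the genotypes of `K` (method `"MAP"`). `loglik`
#'   and `deviance` refer to the data likelihood at the MAP worths.
#' @export
fit_pl_genomic <- function(r, K, prior_scale = 1, tol = 1e-8,
                           max_iter = 500, ridge = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K) || is.null(rownames(K)))
    stop("'K' must be a square matrix with dimnames")
  if (max(abs(K - t(K))) > 1e-8) stop("'K' must be symmetric")
  if (!is.numeric(prior_scale) || prior_scale <= 0)
    stop("'prior_scale' must be > 0")
  items <- rownames(K)
  miss <- setdiff(r$items, items)
  if (length(miss))
    stop("ranked item(s) missing from K: ", paste(head(miss, 5), collapse = ", "))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("'K' is not positive semi-definite")
  n <- length(items)
  # map ranking item codes into K's genotype order
  ord <- r$ord
  remap <- match(r$items, items)
  pos <- ord > 0
  ord[pos] <- remap[ord[pos]]
  Sigma <- prior_scale * (K + t(K)) / 2 + diag(ridge, n)
  Omega <- chol2inv(chol(Sigma))
  P <- function(v) v - mean(v)           # mean-zero gauge on log-worths
  negpost <- function(z) {
    lam <- P(z)
    alpha <- exp(lam)
    ll <- cpp_pl_ll(ord, alpha, r$weights)
    -(ll - 0.5 * sum(lam * (Omega %*% lam)))
  }
  neggrad <- function(z) {
    lam <- P(z)
    alpha <- exp(lam)
    parts <- cpp_pl_grad_parts(ord, n, alpha, r$weights)
    g <- parts$wins - alpha * parts$den - as.numeric(Omega %*% lam)
    -P(g)
  }
  opt <- optim(rep(0, n), negpost, neggrad, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  lam <- P(opt$par)
  alpha <- exp(lam)
  ll <- cpp_pl_ll(ord, alpha, r$weights)
  new_pl_fit(alpha, items, ll, opt$counts[["function"]],
             opt$convergence == 0, "MAP")
}

#' Export fitted worths as CSV
#'
#' Writes columns `item`, `worth` (normalized), `log_worth` (centered).
#'
#' @param fit a `pl_fit`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_worths <- function(fit, path) {
  write.csv(data.frame(item = names(fit$worths),
                       worth = as.numeric(fit$worths),
                       log_worth = as.numeric(fit$log_worths)),
            path, row.names = FALSE)
  invisible(path)
}
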