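# Centralized genomic-prediction benchmark: marker QC, VanRaden additive
# relationship matrix, GBLUP via eigendecomposition + 1-D REML profile on the
# variance ratio, station-trial BLUPs and heritability.

#' Clean a SNP dosage matrix
#'
#' Drops SNPs, then samples, whose missing-call rate exceeds `max_missing`
#' or whose heterozygosity (fraction of dosage-1 calls) exceeds `max_het`,
#' then mean-imputes the remaining missing dosages per SNP.
#'
#' @param m genotype x SNP matrix of dosages in \{0, 1, 2\} with `NA` for
#'   missing calls; rownames are genotype ids.
#' @param max_missing,max_het thresholds in \[0, 1\] (defaults 0.8 and 0.5).
#' @return the cleaned, imputed numeric matrix.
#' @export
clean_markers <- function(m, max_missing = 0.8, max_het = 0.5) {
  stopifnot(is.matrix(m), max_missing >= 0, max_missing <= 1,
            max_het >= 0, max_het <= 1)
  het_col <- colMeans(m == 1, na.rm = TRUE)
  het_col[is.nan(het_col)] <- 1  # all-missing SNP: uninformative, drop
  keep_snp <- colMeans(is.na(m)) <= max_missing & het_col <= max_het
  m <- m[, keep_snp, drop = FALSE]
  if (!ncol(m)) stop("all SNPs removed by quality filters")
  het_row <- rowMeans(m == 1, na.rm = TRUE)
  het_row[is.nan(het_row)] <- 1
  keep_g <- rowMeans(is.na(m)) <= max_missing & het_row <= max_het
  m <- m[keep_g, , drop = FALSE]
  if (!nrow(m)) stop("all samples removed by quality filters")
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    na <- which(is.na(m), arr.ind = TRUE)
    m[na] <- mu[na[, 2]]
  }
  m
}

#' VanRaden additive relationship matrix
#'
#' Method-1 genomic relationship: `K = Z Z' / (2 sum p(1-p))` with
#' `Z = dosages - 2p` and `p` the observed allele frequency per SNP.
#' Monomorphic SNPs carry no relationship information and are dropped with a
#' warning.
#'
#' @param m cleaned genotype x SNP dosage matrix (no missing values).
#' @return symmetric positive semi-definite `kinship` matrix with genotype
#'   dimnames; mean diagonal ~ 1 under Hardy-Weinberg.
#' @examples
#' kinship_vanraden(matrix(c(0, 2, 2, 0), 2, 2,
#'                         dimnames = list(c("g1", "g2"), NULL)))
#' @export
kinship_vanraden <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  p <- colMeans(m) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped")
    m <- m[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (!ncol(m)) stop("no polymorphic SNPs left")
  Z <- sweep(m, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(m), rownames(m))
  K
}

# REML profile log-likelihood for y = mu + u + e, u ~ (0, s2u K), using the
# eigendecomposition K = U diag(d) U'. delta = s2e / s2u.
reml_profile <- function(y, Uty, Ut1, d, n) {
  function(log_delta) {
    delta <- exp(log_delta)
    dv <- d + delta
    # GLS mean and residual quadratic form in the eigenbasis
    w1 <- Ut1 / dv
    mu <- sum(w1 * Uty) / sum(w1 * Ut1)
    res <- Uty - mu * Ut1
    q <- sum(res^2 / dv)
    s2u <- q / (n - 1)
    -0.5 * ((n - 1) * log(s2u) + sum(log(dv)) + log(sum(Ut1^2 / dv)) +
              (n - 1))
  }
}

#' Fit a GBLUP model
#'
#' Restricted maximum likelihood for `y = mu + u + e`, `u ~ N(0, s2u K)`,
#' `e ~ N(0, s2e I)`, profiling the REML criterion over the variance ratio
#' `delta = s2e / s2u` after an eigendecomposition of `K` (so the fit is a
#' cheap 1-D optimization). Genotype BLUPs are
#' `u = K (K + delta I)^{-1} (y - mu)`.
#'
#' @param y named numeric vector of per-genotype phenotypes (station BLUPs
#'   or means); names must be genotypes of `K`; `n >= 3`.
#' @param K additive relationship matrix covering at least the phenotyped
#'   genotypes.
#' @param ranks fit on rank-transformed phenotypes instead of raw values
#'   (default `FALSE`).
#' @return a `gblup_model`: `mu`, `sigma2_u`, `sigma2_e`, `delta`, `blup`
#'   (named, training genotypes), `train` (ids), plus cached solver pieces
#'   used by [predict_gblup()].
#' @export
fit_gblup <- function(y, K, ranks = FALSE) {
  if (is.null(names(y))) stop("'y' must be named by genotype")
  train <- names(y)
  miss <- setdiff(train, rownames(K))
  if (length(miss)) stop("genotype(s) absent from K: ",
                         paste(head(miss, 5), collapse = ", "))
  n <- length(y)
  if (n < 3) stop("need at least 3 phenotyped genotypes")
  if (ranks) y <- setNames(rank(y), names(y))
  Kt <- K[train, train]
  eg <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Uty <- drop(crossprod(eg$vectors, y))
  Ut1 <- drop(crossprod(eg$vectors, rep(1, n)))
  if (var(y) == 0) {
    mod <- list(mu = y[[1]], sigma2_u = 0, sigma2_e = 0, delta = Inf,
                blup = setNames(rep(0, n), train), train = train,
                ranks = ranks)
    class(mod) <- "gblup_model"
    return(mod)
  }
  obj <- reml_profile(y, Uty, Ut1, d, n)
  opt <- optimize(obj, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  dv <- d + delta
  w1 <- Ut1 / dv
  mu <- sum(w1 * Uty) / sum(w1 * Ut1)
  res <- Uty - mu * Ut1
  s2u <- sum(res^2 / dv) / (n - 1)
  # Vinv_r = (K + delta I)^{-1} (y - mu), in the original basis
  vinv_r <- drop(eg$vectors %*% (res / dv))
  blup <- drop(Kt %*% vinv_r)
  mod <- list(mu = mu, sigma2_u = s2u, sigma2_e = delta * s2u, delta = delta,
              blup = setNames(blup, train), train = train, ranks = ranks,
              vinv_r = vinv_r)
  class(mod) <- "gblup_model"
  mod
}

#' @export
print.gblup_model <- function(x, ...) {
  cat("GBLUP model:", length(x$train), "training genotypes\n",
      "mu =", format(x$mu), " sigma2_u =", format(x$sigma2_u),
      " sigma2_e =", format(x$sigma2_e), "\n")
  invisible(x)
}

#' Predict genotypes from a fitted GBLUP model
#'
#' `prediction = mu + K[target, train] (K[train, train] + delta I)^{-1}
#' (y - mu)`. A target with an all-zero relationship row to the training set
#' receives the grand mean and is flagged.
#'
#' @param model a [fit_gblup()] result.
#' @param targets genotype ids to predict (must be rows of `K`).
#' @param K the relationship matrix covering training and target genotypes.
#' @return named numeric predictions; attribute `"uninformed"` lists targets
#'   with no relatedness to the training set.
#' @export
predict_gblup <- function(model, targets, K) {
  miss <- setdiff(targets, rownames(K))
  if (length(miss)) stop("target(s) absent from K: ",
                         paste(head(miss, 5), collapse = ", "))
  if (model$sigma2_u == 0 || is.null(model$vinv_r))
    return(setNames(rep(model$mu, length(targets)), targets))
  Ktt <- K[targets, model$train, drop = FALSE]
  pred <- model$mu + drop(Ktt %*% model$vinv_r)
  flat <- rowSums(abs(Ktt)) < 1e-12
  out <- setNames(pred, targets)
  if (any(flat)) {
    out[flat] <- model$mu
    attr(out, "uninformed") <- targets[flat]
  }
  out
}

#' Per-genotype BLUPs from a station trial
#'
#' Fits `trait ~ environment (fixed) + genotype (random) +
#' replicate-within-environment (random)` with \pkg{lme4}, where the
#' environment factor is the location (crossed with season when a `season`
#' column is present), and returns the genotype BLUPs and variance
#' components.
#'
#' @param plots data.frame with columns `location`, `replicate`, `genotype`,
#'   optionally `season`, and the trait column.
#' @param trait name of the trait column (e.g. `"gy"` or `"oa"`).
#' @return list with `blup` (named numeric, sums to ~ 0), `varcomp`
#'   (`sigma2_g`, `sigma2_rep`, `sigma2_e`), `n_env`, `n_reps`, and the
#'   fitted `model`.
#' @export
station_blup <- function(plots, trait) {
  need <- c("location", "replicate", "genotype", trait)
  if (!all(need %in% names(plots)))
    stop("'plots' needs columns ", paste(need, collapse = ", "))
  d <- plots
  d$env <- if ("season" %in% names(d))
    interaction(d$location, d$season, drop = TRUE) else factor(d$location)
  d$genotype <- factor(d$genotype)
  d$rep_in_env <- interaction(d$env, d$replicate, drop = TRUE)
  d$y <- d[[trait]]
  if (nlevels(d$env) == 1 && max(table(d$genotype)) < 2)
    stop("variance components not estimable: single environment, single replicate")
  fit <- lme4::lmer(y ~ 0 + env + (1 | genotype) + (1 | rep_in_env),
                    data = d,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  re <- lme4::ranef(fit)$genotype
  blup <- setNames(re[, 1], rownames(re))
  list(blup = blup,
       varcomp = c(sigma2_g = getv("genotype"),
                   sigma2_rep = getv("rep_in_env"),
                   sigma2_e = getv("Residual")),
       n_env = nlevels(d$env),
       n_reps = length(unique(d$replicate)),
       model = fit)
}

#' Broad- and narrow-sense heritability on the trial-mean basis
#'
#' `H2 = s2g / (s2g + s2gl / l + s2e / (l r))` with `l` locations and `r`
#' replicates (the genotype-by-location term is dropped when computed per
#' location). The narrow-sense `h2` substitutes the additive (genomic)
#' variance `s2a` into the same ratio.
#'
#' @param sigma2_g genotypic variance; @param sigma2_e residual variance;
#' @param sigma2_gl genotype-by-location variance (default 0);
#' @param n_reps,n_locs replicate and location counts;
#' @param sigma2_a optional additive genomic variance for `h2`.
#' @return list with `H2`, `h2` (`NA` when `sigma2_a` absent), and the
#'   inputs.
#' @examples
#' heritability(1, 1, n_reps = 2, n_locs = 1)$H2  # 2/3
#' @export
heritability <- function(sigma2_g, sigma2_e, sigma2_gl = 0,
                         n_reps = 1, n_locs = 1, sigma2_a = NULL) {
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, sigma2_gl >= 0,
            n_reps >= 1, n_locs >= 1)
  denom_env <- sigma2_gl / n_locs + sigma2_e / (n_locs * n_reps)
  tot <- sigma2_g + denom_env
  if (tot == 0) stop("zero total variance: heritability undefined")
  H2 <- sigma2_g / tot
  h2 <- if (is.null(sigma2_a)) NA_real_ else sigma2_a / (sigma2_a + denom_env)
  list(H2 = H2, h2 = h2, sigma2_g = sigma2_g, sigma2_gl = sigma2_gl,
       sigma2_e = sigma2_e, sigma2_a = sigma2_a,
       n_reps = n_reps, n_locs = n_locs)
}
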