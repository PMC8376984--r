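# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood/fitting code paths.

# product-form Plackett-Luce log-likelihood of best-first orderings
ll_manual <- function(ords, worths) {
  sum(vapply(ords, function(o) {
    w <- worths[o]
    sum(log(w[-length(w)] / rev(cumsum(rev(w)))[-length(w)]))
  }, numeric(1)))
}

# exact Plackett-Luce probability of one full ordering
pl_prob_manual <- function(o, worths) {
  w <- worths[o]
  prod(w[-length(w)] / rev(cumsum(rev(w)))[-length(w)])
}

# brute-force ML worths for 3 items: coarse simplex grid, then local refine
brute_pl_3 <- function(ords, items) {
  eval_grid <- function(a1s, a2s) {
    best <- c(NA, NA); bll <- -Inf
    for (a1 in a1s) for (a2 in a2s) {
      a3 <- 1 - a1 - a2
      if (a3 <= 0) next
      w <- setNames(c(a1, a2, a3), items)
      ll <- ll_manual(ords, w)
      if (ll > bll) { bll <- ll; best <- c(a1, a2) }
    }
    best
  }
  g <- seq(0.01, 0.98, by = 0.01)
  b <- eval_grid(g, g)
  f <- seq(-0.012, 0.012, by = 0.0002)
  b <- eval_grid(b[1] + f, b[2] + f)
  setNames(c(b[1], b[2], 1 - sum(b)), items)
}

# a quick bundle of Luce-sampled 4-item rankings over a worth vector
quick_rankings <- function(worths, n, seed, covariate = NULL) {
  items <- names(worths)
  ords <- vector("list", n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      sub <- sample(items, min(4, length(items)))
      w <- if (is.null(covariate)) worths else worths
      ords[[i]] <- sample(sub, length(sub), prob = w[sub])
    }
  })
  ranking_set(ords, items = items)
}

# rankings whose true worths flip when x > threshold
switch_rankings <- function(n, seed, n_items = 10, threshold = 0.5,
                            shift_size = 2.5, n_noise = 2) {
  withr::with_seed(seed, {
    items <- sprintf("G%02d", seq_len(n_items))
    base <- setNames(rnorm(n_items, 0, 0.8), items)
    shift <- setNames(rnorm(n_items, 0, shift_size), items)
    x <- runif(n)
    cov <- data.frame(x = x)
    for (k in seq_len(n_noise)) cov[[paste0("noise", k)]] <- runif(n)
    ords <- vector("list", n)
    for (i in seq_len(n)) {
      lam <- base + if (x[i] > threshold) shift else 0
      sub <- sample(items, 4)
      ords[[i]] <- sample(sub, 4, prob = exp(lam[sub]))
    }
    list(rankings = ranking_set(ords, items = items), cov = cov,
         base = base, shift = shift, threshold = threshold)
  })
}
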