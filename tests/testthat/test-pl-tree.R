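test_that("constant covariates admit no split", {
  sw <- switch_rankings(80, seed = 1)
  cov <- data.frame(flat = rep(1, 80))
  expect_null(pl_split_search(sw$rankings, cov, "flat", min_size_n = 16))
})

test_that("returned threshold attains the maximal gain over all candidates", {
  sw <- switch_rankings(60, seed = 2)
  res <- pl_split_search(sw$rankings, sw$cov, "x", min_size_n = 12,
                         scan_tol = 1e-9, scan_iter = 3000)
  # exhaustive oracle: refit both children at every admissible threshold
  x <- sw$cov$x
  xs <- sort(x)
  parent <- fit_pl(sw$rankings, check_connected = FALSE)
  llp <- pl_loglik(sw$rankings, parent$worths)
  cands <- which(xs[-60] < xs[-1])
  cands <- cands[cands >= 12 & 60 - cands >= 12]
  gains <- vapply(cands, function(t) {
    thr <- (xs[t] + xs[t + 1]) / 2
    left <- sw$rankings[x <= thr]; right <- sw$rankings[x > thr]
    fl <- fit_pl(pltricot:::restrict_to_present(left), check_connected = FALSE)
    fr <- fit_pl(pltricot:::restrict_to_present(right), check_connected = FALSE)
    fl$loglik + fr$loglik - llp
  }, numeric(1))
  expect_equal(res$n_thresholds, length(cands))
  expect_gte(res$gain + 1e-6, max(gains))
})

test_that("split significance behaves like a Bonferroni chi-square gate", {
  expect_equal(pl_split_test(0, df = 3), 1)
  expect_equal(pl_split_test(10, df = 3),
               pchisq(20, 3, lower.tail = FALSE))
  # non-increasing in gain; adjustment multiplies the tail
  g <- seq(0, 10, by = 0.5)
  p <- vapply(g, pl_split_test, 0, n_thresholds = 7, n_covariates = 3, df = 3)
  expect_true(all(diff(p) <= 0))
  expect_equal(pl_split_test(2, 5, 2, df = 4),
               min(1, 10 * pchisq(4, 4, lower.tail = FALSE)))
})

test_that("the tree recovers a strong worth switch and its threshold", {
  sw <- switch_rankings(800, seed = 3)
  tree <- pl_tree(sw$rankings, sw$cov)
  expect_equal(tree$node$type, "split")
  expect_equal(tree$node$covariate, "x")
  expect_lt(abs(tree$node$threshold - 0.5), 0.05)
  # leaf sizes respect min_size and partition the records
  sizes <- unlist(pltricot:::tree_apply_leaves(tree$node, function(l) l$n))
  expect_true(all(sizes >= 0.2 * 800))
  expect_equal(sum(sizes), 800)
  # tree log-likelihood dominates the root-only fit
  expect_gte(pl_tree_loglik(tree), fit_pl(sw$rankings)$loglik)
})

test_that("homogeneous worths yield a single leaf at alpha = 0.01", {
  for (seed in 1:10) {
    w <- withr::with_seed(seed, exp(rnorm(8, 0, 0.6)))
    names(w) <- LETTERS[1:8]
    r <- quick_rankings(w, 200, seed + 50)
    cov <- withr::with_seed(seed, data.frame(u1 = runif(200), u2 = runif(200)))
    tree <- pl_tree(r, cov)
    expect_equal(tree$node$type, "leaf")
  }
})

test_that("min_size = 0.5 allows at most a root split", {
  sw <- switch_rankings(400, seed = 4)
  tree <- pl_tree(sw$rankings, sw$cov, min_size = 0.5)
  if (tree$node$type == "split") {
    expect_equal(tree$node$left$type, "leaf")
    expect_equal(tree$node$right$type, "leaf")
  } else expect_equal(tree$node$type, "leaf")
})

test_that("prediction routes rows by <=-left thresholds", {
  sw <- switch_rankings(800, seed = 5)
  tree <- pl_tree(sw$rankings, sw$cov)
  thr <- tree$node$threshold
  pred <- predict(tree, data.frame(x = c(thr, thr + 1e-9),
                                   noise1 = 0, noise2 = 0))
  expect_equal(attr(pred, "leaf")[1], tree$node$left$id)   # boundary: left
  expect_equal(attr(pred, "leaf")[2], tree$node$right$id)
  expect_equal(unname(rowSums(pred)), c(1, 1))
  # routing agrees with brute-force predicate evaluation
  rows <- data.frame(x = runif(50), noise1 = runif(50), noise2 = runif(50))
  pred2 <- predict(tree, rows)
  manual <- ifelse(rows$x <= thr, tree$node$left$id, tree$node$right$id)
  expect_equal(attr(pred2, "leaf"), manual)
  expect_error(predict(tree, data.frame(noise1 = 1)), "missing split covariate")
})

test_that("single-leaf trees predict identical worths everywhere", {
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  r <- quick_rankings(w, 60, 6)
  tree <- pl_tree(r, data.frame(z = runif(60)))
  pred <- predict(tree, data.frame(z = c(-1, 0.5, 2)))
  expect_equal(pred[1, ], pred[3, ])
})

test_that("JSON serialization preserves predictions exactly", {
  sw <- switch_rankings(500, seed = 7)
  tree <- pl_tree(sw$rankings, sw$cov)
  path <- withr::local_tempfile(fileext = ".json")
  pl_tree_json(tree, path)
  back <- pl_tree_from_json(path)
  rows <- data.frame(x = seq(0, 1, length.out = 11), noise1 = 0, noise2 = 0)
  expect_equal(predict(back, rows), predict(tree, rows),
               ignore_attr = TRUE)
})
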