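test_that("log-likelihood matches the stagewise product form", {
  r2 <- ranking_set(list(c("A", "B")))
  expect_equal(pl_loglik(r2, c(A = 0.5, B = 0.5)), log(0.5))
  r3 <- ranking_set(list(c("A", "B", "C")))
  expect_equal(pl_loglik(r3, c(A = 0.5, B = 0.3, C = 0.2)), log(0.3))
  # single-item rankings contribute nothing
  r1 <- ranking_set(list("A", c("A", "B")), items = c("A", "B"))
  expect_equal(pl_loglik(r1, c(A = 0.7, B = 0.3)), log(0.7))
  expect_error(pl_loglik(r3, c(A = 1, B = 1)), "without worth")
})

test_that("log-likelihood is invariant to the worth scale", {
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  set.seed(42)
  r <- ranking_set(replicate(20, sample(names(w), 3, prob = w),
                             simplify = FALSE))
  for (c0 in c(0.1, 7, 1e3))
    expect_equal(pl_loglik(r, w * c0), pl_loglik(r, w))
})

test_that("two-item fit equals the wins/(wins+losses) closed form", {
  r <- ranking_set(list(c("A", "B"), c("A", "B"), c("A", "B"), c("B", "A")))
  expect_equal(unname(fit_pl(r)$worths), c(0.75, 0.25), tolerance = 1e-7)
})

test_that("symmetric data give uniform worths", {
  perms <- list(c("A","B","C"), c("A","C","B"), c("B","A","C"),
                c("B","C","A"), c("C","A","B"), c("C","B","A"))
  fit <- fit_pl(ranking_set(perms))
  expect_equal(unname(fit$worths), rep(1 / 3, 3), tolerance = 1e-7)
  expect_equal(fit$deviance, -2 * fit$loglik)
})

test_that("MM fit matches brute-force likelihood maximization on 3-item toys", {
  for (seed in 1:3) {
    w <- withr::with_seed(seed, {
      a <- exp(rnorm(3, 0, 0.7)); setNames(a / sum(a), c("A", "B", "C"))
    })
    ords <- withr::with_seed(seed + 100, replicate(
      20, sample(names(w), 3, prob = w), simplify = FALSE))
    fit <- fit_pl(ranking_set(ords))
    oracle <- brute_pl_3(ords, c("A", "B", "C"))
    expect_equal(unname(fit$worths[c("A", "B", "C")]), unname(oracle),
                 tolerance = 1e-3)
  }
})

test_that("fitted log-likelihood never falls below the uniform baseline", {
  for (seed in 1:5) {
    w <- withr::with_seed(seed, exp(rnorm(6)))
    names(w) <- LETTERS[1:6]
    r <- quick_rankings(w, 40, seed)
    fit <- fit_pl(r, check_connected = FALSE)
    expect_gte(fit$loglik,
               pl_loglik(r, setNames(rep(1 / 6, 6), LETTERS[1:6])))
  }
})

test_that("disconnected data raise an identifiability error naming components", {
  r <- ranking_set(list(c("A", "B"), c("B", "A"), c("C", "D"), c("D", "C")))
  expect_error(fit_pl(r), "not strongly connected")
})

test_that("genomic MAP fit approaches the MLE as the prior widens", {
  w <- c(A = 0.45, B = 0.35, C = 0.2)
  r <- quick_rankings(w, 150, 7)
  K <- diag(3); dimnames(K) <- list(names(w), names(w))
  mle <- fit_pl(r)
  wide <- fit_pl_genomic(r, K, prior_scale = 1e5)
  expect_equal(wide$worths, mle$worths, tolerance = 0.01)
  narrow <- fit_pl_genomic(r, K, prior_scale = 1e-6)
  expect_equal(unname(narrow$worths), rep(1 / 3, 3), tolerance = 0.01)
})

test_that("kinship-exchangeable genotypes with symmetric data get equal worths", {
  # A and B have identical marker rows; data treat them symmetrically
  ords <- c(replicate(10, c("A", "C"), simplify = FALSE),
            replicate(10, c("B", "C"), simplify = FALSE),
            replicate(4, c("C", "A"), simplify = FALSE),
            replicate(4, c("C", "B"), simplify = FALSE))
  r <- ranking_set(ords)
  m <- rbind(A = c(0, 1, 2, 1), B = c(0, 1, 2, 1), C = c(2, 1, 0, 1))
  K <- kinship_vanraden(m)
  fit <- fit_pl_genomic(r, K)
  expect_equal(fit$worths[["A"]], fit$worths[["B"]], tolerance = 1e-4)
})

test_that("genomic fit stays identifiable on disconnected comparison graphs", {
  r <- ranking_set(list(c("A", "B"), c("A", "B"), c("C", "D"), c("D", "C")))
  K <- diag(4); dimnames(K) <- list(LETTERS[1:4], LETTERS[1:4])
  fit <- fit_pl_genomic(r, K)
  expect_true(all(fit$worths > 0))
  expect_gt(fit$worths[["A"]], fit$worths[["B"]])
})

test_that("non-PSD prior matrices are rejected", {
  r <- ranking_set(list(c("A", "B")))
  K <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(fit_pl_genomic(r, K), "positive semi-definite")
})
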