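test_that("win probability is the normalized worth", {
  expect_equal(unname(win_probability(c(A = 2, B = 2, C = 2, D = 2))),
               rep(0.25, 4))
  expect_equal(win_probability(c(A = 0.5, B = 0.3, C = 0.2)),
               c(A = 0.5, B = 0.3, C = 0.2))
  # empirical first-place frequency in Luce sampling
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  firsts <- rluce(3e4, w, seed = 1)[, 1]
  emp <- as.numeric(table(factor(firsts, levels = names(w)))) / 3e4
  se <- sqrt(w * (1 - w) / 3e4)
  expect_true(all(abs(emp - unname(w)) <= 3 * se))
})

test_that("reliability follows the two-item win probability", {
  expect_equal(reliability(c(A = 0.2, B = 0.2), "A", "B"), 0.5)
  expect_equal(reliability(c(A = 0.3, B = 0.1), "A", "B"), 0.75)
  w <- withr::with_seed(2, setNames(runif(6, 0.1, 2), LETTERS[1:6]))
  for (i in LETTERS[1:5]) for (j in LETTERS[(match(i, LETTERS) + 1):6])
    expect_equal(reliability(w, i, j) + reliability(w, j, i), 1)
  expect_error(reliability(c(A = 1), "A", "Z"), "unknown")
})

test_that("scenario grids have points x seasons x sowing-dates rows", {
  sw <- switch_rankings(300, seed = 4, shift_size = 0)  # single-leaf tree
  tree <- pl_tree(sw$rankings, sw$cov)
  wx <- sim_point_weather(2, years = 2001:2015, seed = 5)
  sow <- as.Date(c("2001-06-05", "2001-06-20", "2001-07-05"))
  scen <- simulate_scenarios(tree, wx, seasons = 2001:2015,
                             sowing_dates = sow)
  expect_equal(nrow(scen$grid), 2 * 15 * 3)
  expect_equal(nrow(scen$grid) / length(unique(scen$grid$point_id)), 45)
  excl <- simulate_scenarios(tree, wx, seasons = 2001:2015,
                             sowing_dates = sow,
                             exclude_seasons = 2013:2015)
  expect_equal(nrow(excl$grid) / length(unique(excl$grid$point_id)), 36)
  # all scenarios route to the only leaf: averages equal the leaf worths
  leafw <- sort(predict(tree, data.frame(x = 0, noise1 = 0, noise2 = 0))[1, ])
  expect_equal(sort(scen$average[1, ]), leafw, tolerance = 1e-12)
  expect_equal(unname(rowSums(scen$average)), rep(1, 2))
})

test_that("top-k recommendation never beats a dominant check", {
  avg <- matrix(c(0.4, 0.3, 0.2, 0.1,
                  0.5, 0.25, 0.15, 0.1), 2, 4, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("CHK", "g1", "g2", "g3")))
  out <- top_k_vs_check(avg, k = 3, check = "CHK")
  expect_true(all(out$reliability < 0.5))
  out1 <- top_k_vs_check(avg, k = 1, check = "CHK")
  expect_equal(out1$reliability[1],
               reliability(avg["p1", ], "g1", "CHK"))
  expect_error(top_k_vs_check(avg, k = 4, check = "CHK"), "smaller")
})

test_that("expected yield gain recovers a constructed 20% advantage", {
  # construct worths whose yield link puts the top 3 at +20% over the check
  g <- c("t1", "t2", "t3", "CHK", "d1", "d2")
  model <- true_model(setNames(rep(0, 6), g), setNames(rep(0, 6), g),
                      yield_scale = 1, gy_intercept = 3)
  # under gy = intercept + scale * centered log-worth, these log worths put
  # the top three at 3.6 t/ha and the check at 3.0 (a 20% advantage)
  lw <- c(0.6, 0.6, 0.6, 0, -0.9, -0.9)
  gy <- 3 + lw
  w <- exp(lw); w <- w / sum(w)
  avg <- matrix(w, 1, 6, dimnames = list("p1", g))
  out <- top_k_vs_check(avg, k = 3, check = "CHK", yield_model = model)
  truth <- (mean(gy[1:3]) - gy[4]) / gy[4] * 100
  expect_equal(out$yield_gain_pct, truth, tolerance = 1e-8)
  # and via estimated worths from sampled rankings at large n
  worths <- setNames(w, g)
  r <- quick_rankings(worths, 3000, 9)
  fit <- fit_pl(r)
  est <- top_k_vs_check(matrix(fit$worths, 1,
                               dimnames = list("p1", names(fit$worths))),
                        k = 3, check = "CHK", yield_model = model)
  expect_lt(abs(est$yield_gain_pct - truth), 5)
})
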