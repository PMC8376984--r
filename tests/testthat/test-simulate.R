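test_that("marker generator respects frequency bounds and determinism", {
  expect_error(sim_markers(10, 10, 0.6, 0.5), "maf")
  expect_error(sim_markers(10, 10, 0, 0.5), "maf")
  expect_identical(sim_markers(20, 30, seed = 1), sim_markers(20, 30, seed = 1))
  m <- sim_markers(10, 100, 0.5, 0.5, seed = 2)
  expect_true(all(m %in% 0:2))
  expect_equal(mean(m), 1, tolerance = 0.05)  # symmetric at MAF 0.5
  # empirical per-column frequency within 3 binomial SE of its drawn MAF
  m2 <- sim_markers(200, 500, 0.05, 0.5, seed = 3)
  maf <- attr(m2, "maf")
  se <- sqrt(maf * (1 - maf) / (2 * 200))
  inside <- abs(colMeans(m2) / 2 - maf) <= 3 * se
  expect_gte(mean(inside), 0.99)
})

test_that("environment generator meets its climate contracts", {
  env <- sim_environment(100, 3, 2, cold_fraction = 0.3, seed = 4)
  expect_true(all(env$weather$tmin <= env$weather$tmax))
  env2 <- sim_environment(100, 3, 2, cold_fraction = 0.3, seed = 4)
  expect_identical(env, env2)
  # realized site-mean tmin: the cold fraction sits below every station
  farm_means <- tapply(env$weather$tmin, env$weather$site_id, mean)
  coldest <- min(tapply(env$weather$tmin[grepl("^ST", env$weather$site_id)],
                        env$weather$site_id[grepl("^ST", env$weather$site_id)],
                        mean))
  n_cold <- sum(farm_means[env$fields$site_id] < coldest)
  se3 <- 3 * sqrt(100 * 0.3 * 0.7)
  expect_gte(n_cold, 30 - se3)
  expect_lte(n_cold, 30 + se3)
  expect_equal(n_cold, sum(env$fields$cold))
})

test_that("true worths switch strictly above the threshold", {
  g <- sprintf("G%02d", 1:5)
  base <- setNames(c(0, 0.5, -0.5, 1, -1), g)
  shift <- setNames(c(3, 0, 0, 0, 0), g)
  model <- true_model(base, shift, switch_covariate = "x",
                      switch_threshold = 2)
  w <- sim_true_worths(model, data.frame(x = c(1, 2, 2.001, 5)))
  expect_equal(unname(rowSums(w)), rep(1, 4))
  expect_equal(w[1, ], w[2, ])           # boundary field: base worths only
  expect_gt(w[3, "G01"], w[1, "G01"])    # strictly above: shift active
  expect_equal(w[3, ], w[4, ])
  # rank of the shifted genotype strictly improves above the threshold
  expect_gt(rank(w[3, ])[["G01"]], rank(w[1, ])[["G01"]])
  # zero shifts: identical worths in every field
  m0 <- true_model(base, shift * 0, switch_covariate = "x",
                   switch_threshold = 2)
  w0 <- sim_true_worths(m0, data.frame(x = c(1, 5)))
  expect_equal(w0[1, ], w0[2, ])
  expect_error(sim_true_worths(model, data.frame(y = 1)), "missing")
})

test_that("tricot designs are balanced with distinct entries", {
  fields <- data.frame(field_id = sprintf("F%04d", 1:300),
                       season = rep(c("S1", "S2", "S3"), 100))
  for (seed in 1:3) {
    des <- sim_tricot_design(fields, sprintf("G%02d", 1:41), "CHECK",
                             seed = seed)
    ent <- cbind(des$geno1, des$geno2, des$geno3, des$check)
    expect_true(all(apply(ent, 1, function(x) length(unique(x)) == 4)))
    counts <- table(c(des$geno1, des$geno2, des$geno3))
    expect_lte(max(counts) / min(counts), 1.5)
  }
})

test_that("Luce sampling matches product-form ranking probabilities", {
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  n <- 1e5
  draws <- rluce(n, w, seed = 5)
  keys <- apply(draws, 1, paste, collapse = "")
  perms <- c("ABC", "ACB", "BAC", "BCA", "CAB", "CBA")
  emp <- as.numeric(table(factor(keys, levels = perms))) / n
  theo <- vapply(perms, function(k)
    pl_prob_manual(strsplit(k, "")[[1]], w), numeric(1))
  se <- sqrt(theo * (1 - theo) / n)
  expect_true(all(abs(emp - theo) <= 3 * se + 1e-12))
})

test_that("tricot trials produce 4 yield rows per field and honor worth order", {
  g <- sprintf("G%02d", 1:10)
  base <- setNames(seq(-1, 1, length.out = 10), g)
  model <- true_model(base, setNames(rep(0, 10), g), noise_sd = 0)
  fields <- data.frame(field_id = sprintf("F%03d", 1:200),
                       season = rep(c("S1", "S2"), 100))
  des <- sim_tricot_design(fields, g[1:9], g[10], seed = 6)
  worths <- sim_true_worths(model, data.frame(minNT_veg = rep(0, 200)))
  trial <- sim_tricot_trial(des, worths, model, seed = 7)
  expect_equal(nrow(trial$yield), 800)
  expect_equal(length(trial$rankings), 200)
  # noise_sd = 0: within-field yield order equals the true worth order
  for (i in c(1, 57, 200)) {
    sub <- trial$yield[trial$yield$field_id == des$field_id[i], ]
    expect_equal(sub$genotype[order(-sub$gy)],
                 sub$genotype[order(-worths[i, sub$genotype])])
  }
})

test_that("an overwhelming worth wins virtually every field", {
  g <- c("BIG", "b1", "b2", "b3")
  w <- matrix(c(1e6, 1, 1, 1) / (1e6 + 3), 1000, 4, byrow = TRUE,
              dimnames = list(NULL, g))
  model <- true_model(setNames(c(10, 0, 0, 0), g), setNames(rep(0, 4), g))
  des <- data.frame(field_id = sprintf("F%04d", 1:1000), season = "S1",
                    geno1 = "b1", geno2 = "b2", geno3 = "b3", check = "BIG")
  trial <- sim_tricot_trial(des, w, model, seed = 8)
  firsts <- vapply(orderings(trial$rankings), `[`, "", 1)
  expect_gte(sum(firsts == "BIG"), 999)
})

test_that("station trials have the factorial plot count and 1-5 integer scores", {
  g <- sprintf("G%03d", 1:50)
  des <- sim_station_design(g, n_locations = 2, n_seasons = 2, n_reps = 2)
  expect_equal(nrow(des), 50 * 2 * 2 * 2)
  per_ls <- table(des$location, des$season)
  expect_true(all(per_ls == 50 * 2))
  model <- true_model(setNames(rnorm(50), g), setNames(rep(0, 50), g))
  trial <- sim_station_trial(des, model, seed = 9, n_raters = 4)
  expect_true(all(trial$oa$score %in% 1:5))
  expect_equal(nrow(trial$plots), nrow(des))
  expect_true(all(trial$oa$gender %in% c("M", "F")))
  # degenerate: all variance components zero -> OA constant per genotype
  quiet <- sim_station_trial(des, model, seed = 10, n_raters = 3,
                             sd_loc = 0, sd_season = 0, sd_rep = 0,
                             sd_block = 0, oa_rater_sd = 0)
  per_geno <- tapply(quiet$oa$score, quiet$oa$genotype,
                     function(s) length(unique(s)))
  expect_true(all(per_geno == 1))
})
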