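test_that("marker cleaning filters and mean-imputes", {
  m <- matrix(c(0, 1, 2, 0, 2, 2, 2, 0, 0), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(clean_markers(m), m)  # no missing data: identity
  m2 <- m; m2[1:3, 2] <- NA  # 100% missing > 0.8 cap
  expect_equal(colnames(clean_markers(m2)), c("s1", "s3"))
  m3 <- m; m3[1, 1] <- NA
  expect_equal(clean_markers(m3)[1, 1], mean(m[2:3, 1]))
  m4 <- m; m4[, 1] <- 1  # fully heterozygous SNP dropped at max_het = 0.5
  expect_equal(ncol(clean_markers(m4)), 2)
})

test_that("VanRaden kinship matches the hand example and its invariants", {
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  K <- kinship_vanraden(m)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2, 2))
  # identical genotype rows: off-diagonal equals both diagonals
  m2 <- sim_markers(6, 80, seed = 3)
  m2[2, ] <- m2[1, ]
  K2 <- kinship_vanraden(m2)
  expect_equal(K2[1, 2], K2[1, 1])
  expect_equal(K2[1, 2], K2[2, 2])
  # symmetric PSD for generated markers; mean diagonal ~ 1 under HW
  m3 <- sim_markers(150, 600, seed = 4)
  K3 <- kinship_vanraden(m3)
  expect_equal(K3, t(K3))
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(mean(diag(K3)), 1, tolerance = 0.05)
  expect_warning(kinship_vanraden(cbind(m, c(0, 0))), "monomorphic")
})

test_that("constant phenotypes collapse the GBLUP to zero genetic variance", {
  K <- kinship_vanraden(sim_markers(5, 50, seed = 5))
  y <- setNames(rep(2.5, 5), rownames(K))
  fit <- fit_gblup(y, K)
  expect_equal(fit$sigma2_u, 0)
  expect_equal(unname(fit$blup), rep(0, 5))
  expect_equal(unname(predict_gblup(fit, rownames(K)[1], K)), 2.5)
})

test_that("BLUPs equal a direct mixed-model-equation solve at the fitted ratio", {
  K <- kinship_vanraden(sim_markers(10, 200, seed = 6))
  y <- withr::with_seed(7, setNames(drop(chol(K + diag(1e-6, 10)) %*%
                                           rnorm(10)) + rnorm(10, 0, 0.5) + 5,
                                    rownames(K)))
  fit <- fit_gblup(y, K)
  # oracle: dense GLS/BLUP solve at the same delta, independent code path
  V <- K + fit$delta * diag(10)
  Vi <- solve(V)
  one <- rep(1, 10)
  mu <- drop((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  u <- drop(K %*% Vi %*% (y - mu))
  expect_equal(fit$mu, mu, tolerance = 1e-6)
  expect_equal(unname(fit$blup), unname(u), tolerance = 1e-6)
  # out-of-sample prediction equals the dense conditional-mean oracle
  train <- rownames(K)[1:7]; targets <- rownames(K)[8:10]
  fit2 <- fit_gblup(y[train], K)
  Vt <- K[train, train] + fit2$delta * diag(7)
  o1 <- rep(1, 7); Vti <- solve(Vt)
  mu2 <- drop((t(o1) %*% Vti %*% y[train]) / (t(o1) %*% Vti %*% o1))
  oracle <- mu2 + drop(K[targets, train] %*% Vti %*% (y[train] - mu2))
  expect_equal(unname(predict_gblup(fit2, targets, K)), unname(oracle),
               tolerance = 1e-6)
})

test_that("an identity kinship gives mean-only out-of-sample predictions", {
  K <- diag(8); dimnames(K) <- list(letters[1:8], letters[1:8])
  y <- withr::with_seed(8, setNames(rnorm(5, 10), letters[1:5]))
  fit <- fit_gblup(y, K)
  pred <- predict_gblup(fit, c("f", "g"), K)
  expect_equal(as.numeric(pred), rep(fit$mu, 2))
  expect_equal(attr(pred, "uninformed"), c("f", "g"))
})

test_that("GBLUP predictions shift with a constant added to the phenotype", {
  K <- kinship_vanraden(sim_markers(12, 150, seed = 9))
  y <- withr::with_seed(9, setNames(rnorm(12, 4), rownames(K)))
  p1 <- predict_gblup(fit_gblup(y, K), rownames(K)[1:3], K)
  p2 <- predict_gblup(fit_gblup(y + 10, K), rownames(K)[1:3], K)
  expect_equal(unname(p2 - p1), rep(10, 3), tolerance = 1e-5)
})

test_that("station BLUPs shrink but preserve balanced-design ordering", {
  model <- true_model(
    log_worth_base = setNames(seq(-1, 1, length.out = 30),
                              sprintf("G%03d", 1:30)),
    log_worth_shift = setNames(rep(0, 30), sprintf("G%03d", 1:30)),
    noise_sd = 0.3)
  des <- sim_station_design(sprintf("G%03d", 1:30), 2, 1, 2)
  trial <- sim_station_trial(des, model, seed = 10)
  sb <- station_blup(trial$plots, "gy")
  means <- tapply(trial$plots$gy, trial$plots$genotype, mean)[names(sb$blup)]
  expect_gte(cor(sb$blup, means, method = "spearman"), 0.999)
  # shrinkage: BLUPs are smaller in magnitude than centered genotype means
  expect_lte(max(abs(sb$blup)), max(abs(means - mean(means))) + 1e-8)
  # no true genotype variance: BLUPs collapse towards zero
  flat <- true_model(log_worth_base = setNames(rep(0, 30), names(model$log_worth_base)),
                     log_worth_shift = setNames(rep(0, 30), names(model$log_worth_base)),
                     noise_sd = 0.3)
  sb0 <- station_blup(sim_station_trial(des, flat, seed = 11)$plots, "gy")
  expect_lte(sd(sb0$blup), 0.5 * sd(sb$blup))
})

test_that("heritability follows the trial-mean formula", {
  expect_equal(heritability(0, 1, n_reps = 2)$H2, 0)
  expect_equal(heritability(1, 1, n_reps = 2, n_locs = 1)$H2, 2 / 3)
  h <- vapply(1:5, function(r) heritability(1, 1, n_reps = r)$H2, 0)
  expect_true(all(diff(h) > 0))
  expect_equal(heritability(1, 1, n_reps = 2, sigma2_a = 0.5)$h2,
               0.5 / (0.5 + 0.5))
  expect_error(heritability(0, 0), "zero total variance")
})
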