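lin_dataset <- function(n, seed, noise = 0) {
  X <- withr::with_seed(seed, cbind(
    HR = runif(n, 55, 90), CSBP = runif(n, 90, 160),
    CDBP = runif(n, 60, 100), SaO2 = runif(n, 90, 100)))
  y <- 0.5 * X[, "HR"] + 0.3 * X[, "CSBP"] - 0.2 * X[, "CDBP"] +
    1.5 * X[, "SaO2"] + withr::with_seed(seed + 1, rnorm(n, 0, noise))
  structure(list(X = X, y = y, target = "SV", role = "train"),
            class = "cr_dataset")
}

test_that("a noiseless smooth target is interpolated almost exactly", {
  tr <- lin_dataset(200, seed = 1)
  te <- lin_dataset(80, seed = 9)
  m <- fit_gpr(tr, gpr_config(n_iter = 25, seed = 2))
  mt <- evaluate_metrics(predict(m, te$X)$mean, te$y)
  expect_gte(mt$r2, 0.999)
})

test_that("a constant target yields a flagged constant model", {
  tr <- lin_dataset(40, seed = 1)
  tr$y <- rep(5, 40)
  m <- fit_gpr(tr)
  expect_true(m$constant)
  pr <- predict(m, tr$X[1:7, ])
  expect_equal(pr$mean, rep(5, 7))
})

test_that("fitting is deterministic under identical seeds", {
  tr <- lin_dataset(60, seed = 4, noise = 1)
  m1 <- fit_gpr(tr, gpr_config(n_iter = 10, seed = 5))
  m2 <- fit_gpr(tr, gpr_config(n_iter = 10, seed = 5))
  expect_identical(m1$hyper, m2$hyper)
  m3 <- fit_gpr(tr, gpr_config(n_iter = 10, seed = 6))
  expect_false(identical(m3$hyper, m1$hyper) &&
                 identical(m3$tuning$draws, m1$tuning$draws))
})

test_that("training points are reproduced within the noise level", {
  tr <- lin_dataset(100, seed = 2, noise = 0.5)
  m <- fit_gpr(tr, gpr_config(n_iter = 25, seed = 3))
  pr <- predict(m, tr$X)
  expect_lt(max(abs(pr$mean - tr$y)), 3 * (m$hyper$sigma_n + 0.5))
  # predictive SD at training points shrinks toward the noise level
  expect_lt(stats::median(pr$sd), 3 * (m$hyper$sigma_n + 1e-6) + 0.1)
})

test_that("predictive uncertainty grows outside the training hull", {
  tr <- lin_dataset(150, seed = 3)
  m <- fit_gpr(tr, gpr_config(n_iter = 25, seed = 4))
  inside <- predict(m, tr$X)$sd
  far <- tr$X[1:10, ]
  far[, "HR"] <- 300
  far[, "CSBP"] <- 400
  outside <- predict(m, far)$sd
  expect_gt(min(outside), stats::median(inside))
})

test_that("prediction is order-preserving and schema-checked", {
  tr <- lin_dataset(50, seed = 6)
  m <- fit_gpr(tr, gpr_config(n_iter = 5, seed = 7))
  X <- tr$X[c(3, 1, 2), ]
  pr <- predict(m, X)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$mean[2], predict(m, tr$X[1, , drop = FALSE])$mean)
  bad <- tr$X[1:2, ]
  colnames(bad) <- c("a", "b", "c", "d")
  expect_error(predict(m, bad), "feature columns")
  expect_error(predict(m, as.data.frame(tr$X[, 1:3])), "missing feature")
})

test_that("z-scoring statistics come from training data only", {
  tr <- lin_dataset(60, seed = 8)
  m <- fit_gpr(tr, gpr_config(n_iter = 5, seed = 9))
  ctr <- m$center
  invisible(predict(m, tr$X + 50))
  expect_identical(m$center, ctr)
  expect_equal(unname(m$center), unname(colMeans(tr$X)))
})

test_that("error metrics match their closed forms", {
  y <- c(100, 50)
  expect_equal(evaluate_metrics(c(90, 50), y)$max_re, 10)
  expect_equal(evaluate_metrics(c(90, 50), y)$mre, 5)
  perfect <- evaluate_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$max_re, 0)
  expect_equal(perfect$mre, 0)
  ybar <- evaluate_metrics(rep(mean(y), 2), y)
  expect_equal(ybar$r2, 0)
  expect_error(evaluate_metrics(1:3, 1:2), "length mismatch")
  # zero-denominator guard
  g <- evaluate_metrics(c(1, 2), c(0, 2))
  expect_equal(g$n_guarded, 1)
  expect_true(is.na(g$re[1]))
  expect_equal(g$abs_err[1], 1)
})

test_that("metric aggregates keep their ordering invariants", {
  for (s in 1:5) {
    yp <- withr::with_seed(s, rnorm(30, 100, 10))
    yt <- withr::with_seed(s + 50, rnorm(30, 100, 10))
    mt <- evaluate_metrics(yp, yt)
    expect_gte(mt$max_re, mt$mre)
    expect_gte(mt$mre, 0)
    expect_lte(mt$r2, 1)
  }
})

test_that("learning curve improves with size and hits the identity case", {
  tr <- lin_dataset(220, seed = 10, noise = 0.2)
  m <- fit_gpr(tr, gpr_config(n_iter = 15, seed = 11))
  lc <- learning_curve_gpr(tr, c(60, 198), m$hyper, gpr_config(seed = 11))
  expect_equal(lc$size, c(60, 198))
  expect_lte(lc$cv_max_error[2], lc$cv_max_error[1])
  expect_error(learning_curve_gpr(tr, 500, m$hyper), "exceeds")
  expect_error(learning_curve_gpr(tr, 210, m$hyper), "exceeds")
})

test_that("exact GP agrees with an independent kernel-machine fit", {
  skip_if_not_installed("kernlab")
  tr <- lin_dataset(150, seed = 12)
  te <- lin_dataset(60, seed = 13)
  m <- fit_gpr(tr, gpr_config(n_iter = 25, seed = 14))
  ours <- predict(m, te$X)$mean
  ref <- kernlab::gausspr(x = tr$X, y = tr$y, kernel = "rbfdot",
                          kpar = list(sigma = 0.25), var = 0.01,
                          variance.model = FALSE)
  theirs <- as.numeric(kernlab::predict(ref, te$X))
  expect_gte(evaluate_metrics(ours, te$y)$r2, 0.999)
  expect_gte(evaluate_metrics(theirs, te$y)$r2, 0.98)
  expect_gt(stats::cor(ours, theirs), 0.99)
})
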