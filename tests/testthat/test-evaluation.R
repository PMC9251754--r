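test_that("mse and bias match hand arithmetic and a brute-force loop", {
  mb <- mse_bias(c(1, 2), c(1, 4))
  expect_equal(unname(mb$overall[c("mse", "bias")]), c(2, -1))
  expect_equal(unname(mse_bias(1:5, 1:5)$overall[c("mse", "bias")]), c(0, 0))

  set.seed(1)
  for (r in 1:20) {
    n <- sample(3:50, 1)
    pred <- rnorm(n); obs <- rnorm(n)
    arms <- sample(c("a", "b"), n, replace = TRUE)
    mb <- mse_bias(pred, obs, arms)
    # independent loop oracle
    se <- 0; bi <- 0
    for (i in seq_len(n)) {
      se <- se + (pred[i] - obs[i])^2
      bi <- bi + (pred[i] - obs[i])
    }
    expect_equal(unname(mb$overall[["mse"]]), se / n, tolerance = 1e-12)
    expect_equal(unname(mb$overall[["bias"]]), bi / n, tolerance = 1e-12)
    expect_equal(sum(mb$per_arm$n), n)
  }
})

test_that("r_squared follows its definition including the negative range", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_lt(r_squared(-obs, obs), 0)  # worse than the mean is negative
  expect_error(r_squared(1:3, rep(2, 3)), "constant")
  set.seed(2)
  for (r in 1:20) {
    pred <- rnorm(30); obs <- rnorm(30)
    expect_equal(r_squared(pred, obs),
                 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
  }
})

test_that("outcome calibration recovers known affine miscalibration", {
  set.seed(3)
  y <- rnorm(200, 5, 2)
  arms <- sample(c("a", "b"), 200, replace = TRUE)
  cal <- calibration_outcome(y, y, arms)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(cal$slopes), c(1, 1), tolerance = 1e-10)

  # pred = y + 1: regressing y on pred gives slope 1, intercept -1
  cal2 <- calibration_outcome(y + 1, y, arms)
  expect_equal(cal2$intercept, -1, tolerance = 1e-10)
  expect_equal(unname(cal2$slopes), c(1, 1), tolerance = 1e-10)

  # K = 1 reduces to simple linear regression
  pred <- rnorm(200)
  cal3 <- calibration_outcome(pred, y, rep("a", 200))
  lm0 <- lm(y ~ pred)
  expect_equal(cal3$intercept, unname(coef(lm0)[1]), tolerance = 1e-10)
  expect_equal(unname(cal3$slopes), unname(coef(lm0)[2]), tolerance = 1e-10)
})

test_that("calibration lines match a brute-force least-squares oracle", {
  set.seed(4)
  for (r in 1:10) {
    n <- 100
    pred <- rnorm(n); obs <- rnorm(n)
    arms <- sample(c("a", "b", "c"), n, replace = TRUE)
    cal <- calibration_outcome(pred, obs, arms)
    X <- cbind(1, pred * (arms == "a"), pred * (arms == "b"),
               pred * (arms == "c"))
    beta <- solve(crossprod(X), crossprod(X, obs))
    expect_equal(c(cal$intercept, unname(cal$slopes)), as.numeric(beta),
                 tolerance = 1e-10)
  }
})

test_that("benefit calibration is 0/1 for a well-specified model and scales", {
  set.seed(5)
  n <- 20000
  model <- fake_model(alpha = 4, beta = c(0.4, -0.3),
                      gamma = matrix(c(0.5, -0.2), 2, 1), delta = -0.9,
                      treatments = c("a", "w"), covariates = c("x1", "x2"))
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  arms <- sample(c("a", "w"), n, replace = TRUE)
  mu_a <- predict(model, X, "a", interval = "none")$fit
  mu_w <- predict(model, X, "w", interval = "none")$fit
  y <- ifelse(arms == "w", mu_w, mu_a) + rnorm(n)
  preds <- cbind(a = mu_a, w = mu_w)
  cb <- calibration_benefit(preds, y, arms)
  expect_equal(cb$intercept, 0, tolerance = 0.05)
  expect_equal(cb$prognostic_slope, 1, tolerance = 0.05)
  expect_equal(unname(cb$benefit_slopes), 1, tolerance = 0.05)

  # a model whose relative-effect block is halved predicts half the benefit,
  # so its benefit slope doubles
  half <- cbind(a = mu_a, w = mu_a + (mu_w - mu_a) / 2)
  cbh <- calibration_benefit(half, y, arms)
  expect_equal(unname(cbh$benefit_slopes), 2, tolerance = 0.1)

  # permuted benefits carry no individual-level information; with a
  # mean-zero benefit (pure effect modification) the slope collapses to 0
  model0 <- fake_model(alpha = 4, beta = c(0.4, -0.3),
                       gamma = matrix(c(0.5, -0.2), 2, 1), delta = 0,
                       treatments = c("a", "w"), covariates = c("x1", "x2"))
  mu_w0 <- predict(model0, X, "w", interval = "none")$fit
  y0 <- ifelse(arms == "w", mu_w0, mu_a) + rnorm(n)
  perm <- cbind(a = mu_a, w = mu_a + sample(mu_w0 - mu_a))
  cbp <- calibration_benefit(perm, y0, arms)
  expect_equal(unname(cbp$benefit_slopes), 0, tolerance = 0.05)
})

test_that("benefit calibration matches its design-matrix oracle", {
  set.seed(6)
  n <- 150
  preds <- cbind(a = rnorm(n), w = rnorm(n), v = rnorm(n))
  obs <- rnorm(n)
  arms <- sample(c("a", "w", "v"), n, replace = TRUE)
  cb <- calibration_benefit(preds, obs, arms)
  X <- cbind(1, preds[, "a"],
             (preds[, "w"] - preds[, "a"]) * (arms == "w"),
             (preds[, "v"] - preds[, "a"]) * (arms == "v"))
  beta <- solve(crossprod(X), crossprod(X, obs))
  expect_equal(c(cb$intercept, cb$prognostic_slope,
                 unname(cb$benefit_slopes)),
               as.numeric(beta), tolerance = 1e-10)
})
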