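make_index <- function(covariates, contrasts) {
  rbind(
    data.frame(role = "intercept", covariate = NA_character_,
               contrast = NA_character_, stringsAsFactors = FALSE),
    data.frame(role = "main", covariate = covariates,
               contrast = NA_character_, stringsAsFactors = FALSE),
    data.frame(role = "trt", covariate = NA_character_, contrast = contrasts,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(contrasts, function(w)
      data.frame(role = "interaction", covariate = covariates, contrast = w,
                 stringsAsFactors = FALSE))))
}

lp_eval <- function(theta, index, x, trt) {
  out <- theta[index$role == "intercept"]
  out <- out + sum(theta[index$role == "main"] * x)
  if (trt != "ref") {
    out <- out + theta[index$role == "trt" & index$contrast == trt]
    ii <- index$role == "interaction" & index$contrast == trt
    out <- out + sum(theta[ii] * x)
  }
  out
}

test_that("standardization centers and scales continuous covariates only", {
  df <- data.frame(patient = 1:4, treatment = c("a", "a", "b", "b"),
                   y = 1:4, xc = c(2, 4, 6, 8), xb = c(0, 1, 0, 1))
  std <- standardize_study(df, c("xc", "xb"), "s")
  expect_equal(mean(std$study$xc), 0, tolerance = 1e-12)
  expect_equal(sd(std$study$xc), 1, tolerance = 1e-12)
  expect_identical(std$study$xb, df$xb)   # binary untouched
  expect_identical(std$study$y, df$y)     # outcome untouched
  expect_true(std$scaling$scaled[1])
  expect_false(std$scaling$scaled[2])

  # two-point case: {2, 4} with sample sd
  df2 <- data.frame(xc = c(2, 4))
  std2 <- standardize_study(df2, "xc", "s")
  expect_equal(std2$scaling$mean[1], 3)
  expect_equal(std2$scaling$sd[1], sd(c(2, 4)))
  expect_equal(std2$study$xc, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # idempotence up to scaling: already-standardized column
  z <- as.numeric(scale(rnorm(20)))
  df3 <- data.frame(xc = z)
  std3 <- standardize_study(df3, "xc", "s")
  expect_equal(std3$study$xc, z, tolerance = 1e-10)

  expect_error(standardize_study(data.frame(xc = rep(2, 5)), "xc", "stud"),
               "constant in study 'stud'")
})

test_that("destandardization follows the closed-form map and preserves the predictor", {
  # single covariate, mu=2, s=2, a=1, b=1, c=0.5, d=0
  index <- make_index("x1", "w")
  theta <- c(1, 1, 0, 0.5)  # a, b, d, c
  scaling <- data.frame(covariate = "x1", mean = 2, sd = 2, scaled = TRUE,
                        stringsAsFactors = FALSE)
  est <- fake_estimate(theta, diag(4) * 0.01, index, c("ref", "w"), "ref",
                       covariates = "x1")
  est$draws <- matrix(rep(theta, each = 3), 3)
  nat <- destandardize_estimate(est, scaling)
  expect_equal(nat$theta[index$role == "intercept"], 0)
  expect_equal(nat$theta[index$role == "main"], 0.5)
  expect_equal(nat$theta[index$role == "interaction"], 0.25)
  expect_equal(nat$theta[index$role == "trt"], -0.5)

  # predictor equivalence on 5 random patients
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(1, 2, 2)
    z <- (x - 2) / 2
    trt <- sample(c("ref", "w"), 1)
    expect_equal(lp_eval(theta, index, z, trt),
                 lp_eval(nat$theta, index, x, trt), tolerance = 1e-10)
  }
})

test_that("random fits: predictor equivalence, bijection, PSD preservation", {
  set.seed(21)
  covs <- c("x1", "x2", "x3")
  index <- make_index(covs, c("w", "v"))
  q <- nrow(index)
  for (rep in 1:10) {
    theta <- rnorm(q)
    A <- matrix(rnorm(q * q), q)
    S <- crossprod(A) / q
    scaling <- data.frame(covariate = covs, mean = rnorm(3, 0, 2),
                          sd = runif(3, 0.5, 3), scaled = TRUE,
                          stringsAsFactors = FALSE)
    est <- fake_estimate(theta, S, index, c("ref", "w", "v"), "ref",
                         covariates = covs)
    set.seed(100 + rep)
    est$draws <- matrix(rnorm(50 * q), 50) %*% chol(S) +
      matrix(rep(theta, each = 50), 50)
    nat <- destandardize_estimate(est, scaling)

    # predictor equivalence over 100 random (x, t) at the posterior mean
    th_std <- colMeans(est$draws); th_nat <- nat$theta
    dmax <- 0
    for (i in 1:100) {
      x <- rnorm(3, 1, 2)
      z <- (x - scaling$mean) / scaling$sd
      trt <- sample(c("ref", "w", "v"), 1)
      dmax <- max(dmax, abs(lp_eval(th_std, index, z, trt) -
                              lp_eval(th_nat, index, x, trt)))
    }
    expect_lt(dmax, 1e-10)

    # covariance transform keeps symmetry and positive semi-definiteness
    expect_equal(nat$S, t(nat$S), tolerance = 1e-10)
    expect_true(all(eigen(nat$S, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))

    # bijection: the inverse scaling recovers standardized coefficients
    J <- rwenma:::destandardize_jacobian(index, scaling)
    back <- solve(J, th_nat)
    expect_equal(as.numeric(back), as.numeric(th_std), tolerance = 1e-12)
  }
})

test_that("identity scaling is a no-op", {
  covs <- c("x1", "x2")
  index <- make_index(covs, "w")
  theta <- rnorm(nrow(index))
  S <- diag(nrow(index))
  scaling <- data.frame(covariate = covs, mean = 0, sd = 1, scaled = FALSE,
                        stringsAsFactors = FALSE)
  est <- fake_estimate(theta, S, index, c("ref", "w"), "ref",
                       covariates = covs)
  est$draws <- matrix(rep(theta, each = 4), 4)
  nat <- destandardize_estimate(est, scaling)
  expect_equal(nat$theta, theta, tolerance = 1e-12)
})
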