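# OLS with treatment dummies and interactions: the frequentist oracle the
# vague-prior Bayesian fit must agree with at moderate n
ols_oracle <- function(df, covariates, reference) {
  arms <- sort(unique(df$treatment))
  nonref <- setdiff(arms, reference)
  X <- as.matrix(df[covariates])
  Xd <- cbind(1, X)
  for (w in nonref) Xd <- cbind(Xd, as.numeric(df$treatment == w))
  for (w in nonref) Xd <- cbind(Xd, X * (df$treatment == w))
  fit <- lm.fit(Xd, df$y)
  list(coef = fit$coefficients,
       vcov = chol2inv(chol(crossprod(Xd))) *
         sum(fit$residuals^2) / (nrow(Xd) - ncol(Xd)))
}

two_arm_study <- function(n = 500, p = 3, seed = 1, gamma_size = 0.3) {
  studies <- data.frame(study = "s1", design = "rct", n = as.integer(n),
                        stringsAsFactors = FALSE)
  studies$arms <- list(c("dmards", "rtx"))
  g <- matrix(gamma_size * c(1, rep(-0.5, p - 1)), p, 1,
              dimnames = list(paste0("x", 1:p), "rtx"))
  cfg <- sim_config(treatments = c("dmards", "rtx"), studies = studies,
                    n_cov = p, gamma = g, delta_rct = c(rtx = -0.8))
  simulate_ipd(cfg, seed = seed)
}

test_that("vague-prior posterior agrees with the least-squares oracle", {
  ipd <- two_arm_study(500, 3, seed = 4)
  df <- ipd$studies$s1
  est <- fit_study(df, ipd$covariates, reference = "dmards",
                   mcmc = quick_mcmc(iter = 1500), study_id = "s1")
  oracle <- ols_oracle(df, ipd$covariates, "dmards")
  post_sd <- sqrt(diag(est$S))
  expect_true(all(abs(est$theta - oracle$coef) < 2 * post_sd))
  # posterior spread matches the sampling covariance scale
  expect_equal(post_sd, sqrt(diag(oracle$vcov)), tolerance = 0.25)
})

test_that("an overwhelming Laplace rate pins interactions at zero", {
  ipd <- two_arm_study(300, 3, seed = 6)
  est <- fit_study(ipd$studies$s1, ipd$covariates, reference = "dmards",
                   shrink = TRUE, mcmc = quick_mcmc(),
                   priors = prior_settings(lambda = 1e6), study_id = "s1")
  cc <- est$theta[est$index$role == "interaction"]
  expect_true(all(abs(cc) < 1e-2))
})

test_that("three-arm studies carry two contrast blocks with cross-correlation", {
  studies <- data.frame(study = "r1", design = "nrs", n = 400L,
                        stringsAsFactors = FALSE)
  studies$arms <- list(c("dmards", "rtx", "tcz"))
  cfg <- sim_config(studies = studies, n_cov = 2)
  ipd <- simulate_ipd(cfg, seed = 7)
  est <- suppressWarnings(  # marginal Gelman-Rubin on short test chains
    fit_study(ipd$studies$r1, ipd$covariates, reference = "dmards",
              mcmc = quick_mcmc(), study_id = "r1"))
  expect_setequal(unique(na.omit(est$index$contrast)), c("rtx", "tcz"))
  expect_equal(sum(est$index$role == "trt"), 2)
  expect_equal(sum(est$index$role == "interaction"), 4)
  i1 <- which(est$index$role == "trt" & est$index$contrast == "rtx")
  i2 <- which(est$index$role == "trt" & est$index$contrast == "tcz")
  # joint fit: the two treatment effects share a_j, b_j, so their posterior
  # covariance is not forced to zero
  expect_gt(abs(est$S[i1, i2]), 1e-6)
})

test_that("a study lacking the reference gets its largest arm as local reference", {
  studies <- data.frame(study = "s1", design = "rct", n = 300L,
                        stringsAsFactors = FALSE)
  studies$arms <- list(c("rtx", "tcz"))
  cfg <- sim_config(treatments = c("dmards", "rtx", "tcz"), studies = studies,
                    n_cov = 2)
  ipd <- simulate_ipd(cfg, seed = 8)
  est <- fit_study(ipd$studies$s1, ipd$covariates, reference = "dmards",
                   mcmc = quick_mcmc(), study_id = "s1")
  expect_true(est$local_reference %in% c("rtx", "tcz"))
  cnt <- table(ipd$studies$s1$treatment)
  expect_equal(est$local_reference, names(cnt)[which.max(cnt)])
})

test_that("shrinkage reduces interaction magnitude under null interactions", {
  # repeated-run property at small n: average |c| with the Bayesian LASSO
  # never exceeds the unpenalized average
  reps <- 5
  mean_abs <- function(shrink, seed) {
    ipd <- two_arm_study(150, 3, seed = seed, gamma_size = 0)
    est <- fit_study(ipd$studies$s1, ipd$covariates, reference = "dmards",
                     shrink = shrink, mcmc = quick_mcmc(iter = 600),
                     study_id = "s1")
    mean(abs(est$theta[est$index$role == "interaction"]))
  }
  # short chains: convergence warnings on the shrinkage rate are expected
  shrunk <- suppressWarnings(vapply(1:reps, function(s)
    mean_abs(TRUE, 100 + s), 0))
  plain <- suppressWarnings(vapply(1:reps, function(s)
    mean_abs(FALSE, 100 + s), 0))
  expect_lt(mean(shrunk), mean(plain))
})

test_that("degenerate designs are flagged", {
  ipd <- two_arm_study(40, 3, seed = 9)
  df <- ipd$studies$s1
  df <- df[c(which(df$treatment == "dmards"),
             which(df$treatment == "rtx")[1:4]), ]
  expect_warning(fit_study(df, ipd$covariates, reference = "dmards",
                           mcmc = quick_mcmc(iter = 300), study_id = "s1"),
                 "fewer than n_cov")
})
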