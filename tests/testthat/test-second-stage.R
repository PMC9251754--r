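scalar_est <- function(theta, var, id, design = "rct") {
  idx <- data.frame(role = "intercept", covariate = NA_character_,
                    contrast = NA_character_, stringsAsFactors = FALSE)
  est <- fake_estimate(theta, matrix(var), idx, arms = "a", local_ref = "a",
                       design = design, study_id = id)
  est
}

int_trt_est <- function(a, d, va, vd, id, design) {
  idx <- data.frame(role = c("intercept", "trt"),
                    covariate = NA_character_,
                    contrast = c(NA, "b"), stringsAsFactors = FALSE)
  fake_estimate(c(a, d), diag(c(va, vd)), idx, arms = c("a", "b"),
                local_ref = "a", design = design, study_id = id)
}

test_that("common-effect pooling matches the precision-weighted closed form", {
  ests <- list(scalar_est(1, 1, "s1"), scalar_est(3, 1, "s2"))
  mp <- pool_common(ests, reference = "a", mcmc = pool_mcmc())
  mcse <- mp$sd[["alpha"]] / sqrt(coda::effectiveSize(mp$draws[, "alpha"]))
  expect_equal(unname(mp$mean[["alpha"]]), 2.0, tolerance = 3 * mcse + 1e-6)
  expect_equal(unname(mp$sd[["alpha"]]), 1 / sqrt(2), tolerance = 0.05)
})

test_that("single-study pooling is a passthrough", {
  ests <- list(scalar_est(1.7, 0.25, "s1"))
  mp <- pool_common(ests, reference = "a", mcmc = pool_mcmc())
  expect_equal(unname(mp$mean[["alpha"]]), 1.7, tolerance = 0.03)
  expect_equal(unname(mp$sd[["alpha"]]), 0.5, tolerance = 0.05)
})

test_that("selection matrices route studies onto only the contrasts they estimate", {
  # two 2-arm studies on different contrasts: B vs A and C vs A
  mk <- function(contrast, id) {
    idx <- data.frame(role = c("intercept", "trt"),
                      covariate = NA_character_,
                      contrast = c(NA, contrast), stringsAsFactors = FALSE)
    fake_estimate(c(4, -1), diag(2), idx, arms = c("a", contrast),
                  local_ref = "a", design = "rct", study_id = id)
  }
  ests <- list(mk("b", "s1"), mk("c", "s2"))
  lay <- rwenma:::prepare_ests(ests, "a")
  M1 <- rwenma:::mapping_matrix(ests[[1]], lay$bindex, "a")
  M2 <- rwenma:::mapping_matrix(ests[[2]], lay$bindex, "a")
  db <- which(lay$bindex$role == "delta" & lay$bindex$contrast == "b")
  dc <- which(lay$bindex$role == "delta" & lay$bindex$contrast == "c")
  al <- which(lay$bindex$role == "alpha")
  expect_equal(colSums(abs(M1))[c(al, db, dc)] > 0, c(TRUE, TRUE, FALSE),
               ignore_attr = TRUE)
  expect_equal(colSums(abs(M2))[c(al, db, dc)] > 0, c(TRUE, FALSE, TRUE),
               ignore_attr = TRUE)
})

test_that("consistency mapping re-expresses non-reference-based studies", {
  # study against local reference b containing arms (b, a, c):
  # d_{a,b} estimates -delta_b, d_{c,b} estimates delta_c - delta_b
  idx <- data.frame(role = c("intercept", "trt", "trt"),
                    covariate = NA_character_,
                    contrast = c(NA, "a", "c"), stringsAsFactors = FALSE)
  est <- fake_estimate(c(3, 0.8, -0.2), diag(3), idx,
                       arms = c("a", "b", "c"), local_ref = "b",
                       design = "nrs", study_id = "s1")
  bindex <- rwenma:::basic_index(c("a", "b", "c"), character(0),
                                 interactions = FALSE)
  M <- rwenma:::mapping_matrix(est, bindex, "a")
  phi <- c(alpha = 4, delta_b = -0.8, delta_c = -1.1)
  expected <- c(4 - 0.8,          # E[a_j] = alpha + delta_b
                0.8,              # E[d_ab] = -delta_b
                -1.1 + 0.8)       # E[d_cb] = delta_c - delta_b
  expect_equal(as.numeric(M %*% phi), expected)
})

test_that("an uninformed pooled parameter is an error naming the parameter", {
  ests <- list(int_trt_est(4, -1, 1, 1, "s1", "rct"))
  ests[[1]]$arms <- c("a", "b", "c")  # claims arm c but estimates no contrast
  expect_error(pool_common(ests, "a", mcmc = pool_mcmc()), "delta.c")
})

test_that("design-adjusted pooling reproduces the weighted closed form", {
  # RCT d=1 (var 1), NRS d=0 (var 1), w=0.25: pooled delta = 0.8
  ests <- list(int_trt_est(4, 1, 1, 1, "t1", "rct"),
               int_trt_est(4, 0, 1, 1, "r1", "nrs"))
  mp <- pool_design_adjusted(ests, "a", weights = 0.25, mcmc = pool_mcmc())
  d <- mp$draws[, "delta.b"]
  mcse <- sd(d) / sqrt(coda::effectiveSize(d))
  expect_equal(unname(mp$mean[["delta.b"]]), 0.8, tolerance = 3 * mcse + 0.01)
  # alpha pooled from the NRS only
  expect_equal(unname(mp$mean[["alpha"]]), 4, tolerance = 0.05)

  expect_error(pool_design_adjusted(list(int_trt_est(4, 1, 1, 1, "t1",
                                                     "rct")),
                                    "a", mcmc = pool_mcmc()),
               "at least one NRS")
})

test_that("degenerate weight limits recover the unweighted and RCT-only fits", {
  set.seed(3)
  ests <- list(int_trt_est(4.0, 1.0, 0.04, 0.04, "t1", "rct"),
               int_trt_est(3.6, 0.2, 0.04, 0.04, "r1", "nrs"),
               int_trt_est(3.5, 0.3, 0.04, 0.04, "r2", "nrs"))
  mp1 <- pool_design_adjusted(ests, "a", weights = 1, mcmc = pool_mcmc())
  # w=1: delta as in common pooling of all studies
  mp_all <- pool_common(ests, "a", mcmc = pool_mcmc())
  expect_equal(unname(mp1$mean[["delta.b"]]),
               unname(mp_all$mean[["delta.b"]]), tolerance = 0.03)
  # w -> 0: delta from the RCT alone
  mp0 <- pool_design_adjusted(ests, "a", weights = 1e-6, mcmc = pool_mcmc())
  expect_equal(unname(mp0$mean[["delta.b"]]), 1.0, tolerance = 0.05)
})

test_that("random-effects pooling: fixed tau = 0 reduces to common effect", {
  ests <- list(scalar_est(1, 1, "s1"), scalar_est(3, 1, "s2"))
  # a scalar intercept-only layout has no delta entries; use trt estimates
  ests <- list(int_trt_est(4, 1, 1, 1, "s1", "rct"),
               int_trt_est(4, 3, 1, 1, "s2", "rct"))
  mp0 <- pool_random_tau(ests, "a", tau_prior = 0, mcmc = pool_mcmc())
  mpc <- pool_common(ests, "a", mcmc = pool_mcmc())
  expect_equal(unname(mp0$mean[["delta.b"]]),
               unname(mpc$mean[["delta.b"]]), tolerance = 0.05)
})

test_that("random-effects pooling recovers a known between-study sd", {
  set.seed(10)
  tau <- 0.3
  ests <- lapply(1:20, function(j)
    int_trt_est(4, rnorm(1, -1, sqrt(tau^2 + 0.01)), 0.05, 0.01,
                paste0("s", j), "rct"))
  expect_warning(
    mp <- pool_random_tau(ests, "a", mcmc = pool_mcmc()),
    NA)
  expect_true(median(mp$tau_draws) > 0.15 && median(mp$tau_draws) < 0.45)
})

test_that("full multivariate pooling guards its dimension and zero-Sigma limit", {
  ests <- list(int_trt_est(4, 1, 1, 1, "s1", "rct"),
               int_trt_est(4, 3, 1, 1, "s2", "rct"))
  expect_error(pool_full_mv(ests, "a", form = "full", mcmc = pool_mcmc()),
               "more studies")
  mp <- pool_full_mv(ests, "a", Sigma = matrix(0, 2, 2), mcmc = pool_mcmc())
  mpc <- pool_common(ests, "a", mcmc = pool_mcmc())
  expect_equal(unname(mp$mean[["delta.b"]]),
               unname(mpc$mean[["delta.b"]]), tolerance = 0.05)
})

test_that("no-interaction pooling rejects estimates with interaction terms", {
  covs <- "x1"
  idx <- rbind(data.frame(role = c("intercept", "main", "trt"),
                          covariate = c(NA, "x1", NA),
                          contrast = c(NA, NA, "b"),
                          stringsAsFactors = FALSE),
               data.frame(role = "interaction", covariate = "x1",
                          contrast = "b", stringsAsFactors = FALSE))
  est <- fake_estimate(c(4, 0.5, -1, 0.2), diag(4), idx, c("a", "b"), "a",
                       covariates = covs, study_id = "s1")
  expect_error(pool_no_interactions(list(est), "a", mcmc = pool_mcmc()),
               "refit")
})
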