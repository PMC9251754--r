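#' Fit the first-stage Bayesian regression for one study
#'
#' Fits, to each completed data set of one study, the linear model
#' `y ~ Normal(a + b'x + c_{tA}'x + d_{tA}, sigma^2)` with the interaction
#' and treatment-effect terms set to zero for the study's (local) reference
#' arm.  Covariates are standardized study-wise before fitting and the
#' posterior draws are mapped back to the natural scale exactly; draws are
#' then concatenated across the `m` imputations (mixing the posteriors) and
#' summarized into a posterior-mean vector and covariance matrix.
#'
#' When `shrink = TRUE` the interaction coefficients receive a Laplace prior
#' (Bayesian LASSO when its rate is given a hyperprior); all other
#' coefficients always keep vague normal priors.
#'
#' The Gaussian likelihood is supplied to the sampler through its exact
#' sufficient-statistic factorization (the least-squares estimate is normal
#' around the coefficients with covariance `sigma^2 (X'X)^{-1}`, and the
#' residual sum of squares is `sigma^2` times a chi-squared), which leaves
#' the posterior unchanged while making the fit cost independent of the
#' study's sample size.
#'
#' @param imputed an `imputed_set` from [impute_study()], or a single
#'   completed data.frame.
#' @param covariates ordered covariate names (taken from `imputed` if
#'   available).
#' @param reference the global reference treatment; if absent from the study
#'   the study's largest arm becomes the local reference, and its contrasts
#'   are re-expressed against the global reference at the pooling stage.
#' @param design `"rct"` or `"nrs"` (recorded in the estimate).
#' @param shrink logical: Laplace-shrink the interaction coefficients?
#' @param include_interactions logical: include treatment-covariate
#'   interaction terms at all?  (`FALSE` gives the no-effect-modifier model.)
#' @param mcmc an [mcmc_settings()].
#' @param priors a [prior_settings()].
#' @param study_id label for messages.
#' @return An object of class `study_estimate`: posterior mean `theta`,
#'   covariance `S`, natural-scale `draws`, `sigma` summary, an `index`
#'   data.frame mapping each entry to (role, covariate, contrast), the local
#'   reference, arm set, design, and per-parameter Gelman-Rubin statistics.
#' @export
fit_study <- function(imputed, covariates = NULL, reference,
                      design = "rct", shrink = FALSE,
                      include_interactions = TRUE,
                      mcmc = mcmc_settings(profile = "study"),
                      priors = prior_settings(),
                      study_id = NULL) {
  if (is.data.frame(imputed)) {
    imputed <- structure(list(completed = list(imputed), m = 1L,
                              study_id = if (is.null(study_id)) "study"
                                         else study_id,
                              covariates = covariates),
                         class = "imputed_set")
  }
  stopifnot(inherits(imputed, "imputed_set"))
  if (is.null(covariates)) covariates <- imputed$covariates
  if (is.null(study_id)) study_id <- imputed$study_id
  p <- length(covariates)
  first <- imputed$completed[[1]]
  arms <- sort(unique(first$treatment))
  if (length(arms) < 2L)
    stop("study '", study_id, "' has fewer than 2 arms")
  reference <- tolower(reference)
  local_ref <- if (reference %in% arms) reference else {
    cnt <- table(first$treatment)
    names(cnt)[which.max(cnt)]
  }
  nonref <- setdiff(arms, local_ref)

  arm_n <- table(first$treatment)
  small <- names(arm_n)[arm_n < p + 2]
  if (length(small))
    warning("study '", study_id, "': arm(s) ",
            paste(small, collapse = ", "),
            " have fewer than n_cov + 2 patients; estimates may be unstable")

  # identical completed sets (no missingness): one fit suffices
  sets <- imputed$completed
  if (length(sets) > 1L && identical(sets[[1]], sets[[2]]))
    sets <- sets[1L]

  index <- rbind(
    data.frame(role = "intercept", covariate = NA_character_,
               contrast = NA_character_, stringsAsFactors = FALSE),
    data.frame(role = "main", covariate = covariates,
               contrast = NA_character_, stringsAsFactors = FALSE),
    if (length(nonref))
      data.frame(role = "trt", covariate = NA_character_, contrast = nonref,
                 stringsAsFactors = FALSE),
    if (include_interactions && length(nonref))
      do.call(rbind, lapply(nonref, function(w)
        data.frame(role = "interaction", covariate = covariates,
                   contrast = w, stringsAsFactors = FALSE))))
  rownames(index) <- NULL
  q <- nrow(index)
  n_em <- sum(index$role == "interaction")
  q_vague <- q - if (shrink) n_em else 0L

  all_draws <- vector("list", length(sets))
  sigma_draws <- vector("list", length(sets))
  gr_max <- NULL
  for (si in seq_along(sets)) {
    dat <- sets[[si]]
    dat <- dat[!is.na(dat$y), , drop = FALSE]
    std <- standardize_study(dat, covariates, study_id)
    ds <- std$study
    X <- as.matrix(ds[covariates])
    Xd <- cbind(1, X)
    for (w in nonref) Xd <- cbind(Xd, as.numeric(ds$treatment == w))
    if (include_interactions)
      for (w in nonref) Xd <- cbind(Xd, X * (ds$treatment == w))
    n <- nrow(Xd)
    if (n <= q)
      stop("study '", study_id, "': fewer observed outcomes (", n,
           ") than parameters (", q, ")")
    qrX <- qr(Xd)
    if (qrX$rank < q)
      stop("study '", study_id, "': design matrix is rank deficient")
    ols <- qr.coef(qrX, ds$y)
    SSE <- max(sum((ds$y - Xd %*% ols)^2), 1e-12)

    jd <- list(theta_ols = as.numeric(ols), XtX = crossprod(Xd),
               SSE = SSE, df2 = (n - q) / 2, q = q,
               prior_prec = 1 / priors$coef_sd^2,
               sigma_upper = priors$sigma_upper)
    monitor <- c("theta", "sigma")
    lines <- c(
      "model{",
      "theta_ols[1:q] ~ dmnorm(theta[1:q], XtX[1:q,1:q] / sigma2)",
      "SSE ~ dgamma(df2, 0.5 / sigma2)",
      sprintf("for(k in 1:%d){ theta[k] ~ dnorm(0, prior_prec) }", q_vague))
    if (shrink && n_em > 0) {
      # Laplace(lambda) via its normal-scale-mixture representation
      # (c ~ N(0, s^2), s^2 ~ Exp(lambda^2/2)): identical marginal prior,
      # but keeps every coefficient update conjugate
      lines <- c(lines,
        sprintf(paste0("for(k in %d:%d){ theta[k] ~ dnorm(0, 1/ss[k])\n",
                       "  ss[k] ~ dexp(l2h) }"), q_vague + 1L, q),
        "l2h <- 0.5 * lambda * lambda")
      if (identical(priors$lambda, "random")) {
        lines <- c(lines, sprintf("lambda ~ dgamma(%g, %g)",
                                  priors$lambda_shape, priors$lambda_rate))
        monitor <- c(monitor, "lambda")
      } else jd$lambda <- priors$lambda
    }
    lines <- c(lines,
               "sigma ~ dunif(0, sigma_upper)",
               "sigma2 <- sigma * sigma", "}")
    fit <- run_jags(paste(lines, collapse = "\n"), jd, monitor, mcmc)
    check_convergence(fit$gr, mcmc,
                      paste0("first-stage fit of study '", study_id, "'"))
    if (!is.null(fit$gr))
      gr_max <- if (is.null(gr_max)) fit$gr else pmax(gr_max, fit$gr)

    th_cols <- paste0("theta[", seq_len(q), "]")
    if (q == 1L) th_cols <- "theta"
    draws_std <- fit$draws[, th_cols, drop = FALSE]
    J <- destandardize_jacobian(index, std$scaling)
    all_draws[[si]] <- draws_std %*% t(J)
    sigma_draws[[si]] <- fit$draws[, "sigma"]
  }
  draws <- do.call(rbind, all_draws)
  sig <- unlist(sigma_draws)
  structure(list(study_id = study_id, design = tolower(design),
                 theta = as.numeric(colMeans(draws)),
                 S = stats::cov(draws), draws = draws,
                 sigma = c(mean = mean(sig), sd = stats::sd(sig)),
                 index = index, n = nrow(first),
                 local_reference = local_ref, arms = arms,
                 covariates = covariates, gr = gr_max,
                 shrink = shrink,
                 has_interactions = include_interactions && length(nonref) > 0,
                 scale = "natural"),
            class = "study_estimate")
}

#' @export
print.study_estimate <- function(x, digits = 3, ...) {
  cat("First-stage estimate: study '", x$study_id, "' (",
      toupper(x$design), ", n = ", x$n, ")\n", sep = "")
  cat("  local reference:", x$local_reference,
      "| arms:", paste(x$arms, collapse = ", "),
      if (x$shrink) "| Laplace shrinkage on interactions" else "", "\n")
  lab <- param_labels(x$index)
  est <- data.frame(estimate = round(x$theta, digits),
                    sd = round(sqrt(diag(x$S)), digits))
  rownames(est) <- lab
  print(est)
  cat("  residual sd:", round(x$sigma[["mean"]], digits), "\n")
  invisible(x)
}

param_labels <- function(index) {
  vapply(seq_len(nrow(index)), function(r) {
    switch(index$role[r],
           intercept = "(Intercept)",
           main = index$covariate[r],
           trt = paste0("trt:", index$contrast[r]),
           interaction = paste0(index$covariate[r], ":", index$contrast[r]),
           alpha = "alpha",
           beta = paste0("beta.", index$covariate[r]),
           gamma = paste0("gamma.", index$covariate[r], ":",
                          index$contrast[r]),
           delta = paste0("delta.", index$contrast[r]))
  }, "")
}
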