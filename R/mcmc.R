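#' MCMC sampler settings
#'
#' @param chains number of parallel chains (>= 2 when convergence is
#'   checked).
#' @param iter post-burn-in iterations per chain.
#' @param burnin burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param adapt adaptation steps for the sampler.
#' @param gr_threshold upper bound on the Gelman-Rubin potential scale
#'   reduction factor; monitored parameters exceeding it trigger a warning
#'   (or an error, see `on_nonconvergence`).
#' @param on_nonconvergence `"warn"` or `"error"`.
#' @param profile shortcut overriding `iter`/`burnin`: `"study"` (3 chains of
#'   10000, 1000 burn-in, the full analysis profile for per-study fits),
#'   `"pool"` (3 chains of 200000, 20000 burn-in, for pooling), or `"test"`
#'   (3 chains of 2000, 500 burn-in, for quick checks).
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3L, iter = 10000L, burnin = 1000L,
                          thin = 1L, adapt = 500L, gr_threshold = 1.05,
                          on_nonconvergence = c("warn", "error"),
                          profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("study", "pool", "test"))
    if (profile == "study") { iter <- 10000L; burnin <- 1000L }
    if (profile == "pool") { iter <- 200000L; burnin <- 20000L }
    if (profile == "test") { iter <- 2000L; burnin <- 500L }
  }
  stopifnot(iter > 0, burnin >= 0, chains >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 adapt = as.integer(adapt), gr_threshold = gr_threshold,
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "mcmc_settings")
}

#' Prior settings for the Bayesian regressions
#'
#' Vague priors: Normal(0, `coef_sd`^2) on intercepts, main effects,
#' unpenalized interactions and treatment effects; Uniform(0, `sigma_upper`)
#' on residual and between-study standard deviations.  When interaction
#' shrinkage is enabled the interaction coefficients get a Laplace (double
#' exponential) prior with rate `lambda`; `lambda = "random"` places a
#' Gamma(`lambda_shape`, `lambda_rate`) hyperprior on it (the Bayesian
#' LASSO), a fixed positive number uses that rate directly.
#'
#' @param coef_sd prior standard deviation of regression coefficients.
#' @param sigma_upper upper bound of the uniform prior on standard
#'   deviations.
#' @param lambda `"random"` or a fixed positive rate for the Laplace prior.
#' @param lambda_shape,lambda_rate Gamma hyperprior parameters for a random
#'   `lambda`.
#' @return list of class `prior_settings`.
#' @export
prior_settings <- function(coef_sd = 100, sigma_upper = 100,
                           lambda = "random", lambda_shape = 0.1,
                           lambda_rate = 0.1) {
  if (!identical(lambda, "random")) {
    stopifnot(is.numeric(lambda), lambda > 0)
  }
  structure(list(coef_sd = coef_sd, sigma_upper = sigma_upper,
                 lambda = lambda, lambda_shape = lambda_shape,
                 lambda_rate = lambda_rate),
            class = "prior_settings")
}

# Run a JAGS model and return list(draws = matrix of stacked chains,
# gr = named psrf vector or NULL). `monitor` are node names.
run_jags <- function(model_string, data, monitor, mcmc, inits = NULL) {
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = TRUE)
  if (mcmc$burnin > 0) stats::update(jm, mcmc$burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor, n.iter = mcmc$iter,
                              thin = mcmc$thin, progress.bar = "none")
  gr <- NULL
  if (mcmc$chains >= 2) {
    gr <- tryCatch({
      g <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
      stats::setNames(g$psrf[, 1], rownames(g$psrf))
    }, error = function(e) NULL)
  }
  draws <- do.call(rbind, lapply(samp, as.matrix))
  list(draws = draws, gr = gr)
}

check_convergence <- function(gr, mcmc, context) {
  if (is.null(gr)) return(invisible(NULL))
  bad <- gr[!is.na(gr) & gr > mcmc$gr_threshold]
  if (length(bad)) {
    msg <- paste0("Gelman-Rubin statistic above ", mcmc$gr_threshold,
                  " in ", context, " for: ",
                  paste(names(bad), round(bad, 3), collapse = ", "))
    if (mcmc$on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  invisible(NULL)
}
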