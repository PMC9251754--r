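# Shared fixtures and reduced MCMC profiles for the test suite.
# Expensive fits are cached in an environment so test files can reuse them.

quick_mcmc <- function(chains = 2L, iter = 800L, burnin = 200L)
  mcmc_settings(chains = chains, iter = iter, burnin = burnin, adapt = 200L)

test_mcmc <- function() mcmc_settings(profile = "test")

pool_mcmc <- function(iter = 5000L, burnin = 1000L)
  mcmc_settings(chains = 3L, iter = iter, burnin = burnin, adapt = 300L)

# small connected network: 2 two-arm RCTs + 2 three-arm NRS
small_net_config <- function(n = c(200, 250, 300, 250), n_cov = 3,
                             gap = 0, tau = 0, alpha = c(rct = 4, nrs = 4),
                             ...) {
  studies <- data.frame(study = c("t1", "t2", "r1", "r2"),
                        design = c("rct", "rct", "nrs", "nrs"),
                        n = n, stringsAsFactors = FALSE)
  studies$arms <- list(c("dmards", "rtx"), c("dmards", "tcz"),
                       c("dmards", "rtx", "tcz"),
                       c("dmards", "rtx", "tcz"))
  sim_config(studies = studies, n_cov = n_cov, gap = gap, tau = tau,
             alpha = alpha, ...)
}

# a hand-built study estimate for second-stage unit tests (pooling only
# consumes theta, S, index, arms, local_reference, design, covariates)
fake_estimate <- function(theta, S, index, arms, local_ref, design = "rct",
                          covariates = character(0), study_id = "fake") {
  structure(list(study_id = study_id, design = design,
                 theta = theta, S = S,
                 draws = matrix(rep(theta, each = 2), 2),
                 sigma = c(mean = 1, sd = 0.1), index = index, n = 100L,
                 local_reference = local_ref, arms = arms,
                 covariates = covariates, gr = NULL, shrink = FALSE,
                 has_interactions = any(index$role == "interaction"),
                 scale = "natural"),
            class = "study_estimate")
}

# a hand-built prediction model with point-mass posteriors at given
# coefficient values (ndraw identical draws)
fake_model <- function(alpha, beta, gamma, delta, treatments, covariates,
                       ndraw = 4L, approach = "IIa") {
  ab <- matrix(rep(c(alpha, beta), each = ndraw), ndraw,
               dimnames = list(NULL, c("alpha", paste0("beta.", covariates))))
  nonref <- treatments[-1]
  gcols <- unlist(lapply(nonref, function(w)
    paste0("gamma.", covariates, ":", w)))
  dcols <- paste0("delta.", nonref)
  gd <- matrix(rep(c(as.numeric(gamma), delta), each = ndraw), ndraw,
               dimnames = list(NULL, c(gcols, dcols)))
  structure(list(approach = approach, reference = treatments[1],
                 treatments = treatments, covariates = covariates,
                 interactions = TRUE, ab = ab, gd = gd),
            class = "rwe_model")
}

fixture_env <- new.env()

with_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}
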