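# ---- basic-parameter layout and consistency mapping --------------------

# Layout of the pooled ("basic") parameter vector: alpha, beta (per
# covariate), gamma blocks (per non-reference treatment x covariate, when
# interactions are modelled), then delta (per non-reference treatment).
basic_index <- function(treatments, covariates, interactions = TRUE) {
  nonref <- treatments[-1]
  idx <- rbind(
    data.frame(role = "alpha", covariate = NA_character_,
               contrast = NA_character_, stringsAsFactors = FALSE),
    if (length(covariates))
      data.frame(role = "beta", covariate = covariates,
                 contrast = NA_character_, stringsAsFactors = FALSE),
    if (interactions && length(covariates))
      do.call(rbind, lapply(nonref, function(w)
        data.frame(role = "gamma", covariate = covariates, contrast = w,
                   stringsAsFactors = FALSE))),
    if (length(nonref))
      data.frame(role = "delta", covariate = NA_character_,
                 contrast = nonref, stringsAsFactors = FALSE))
  rownames(idx) <- NULL
  idx
}

# Selection/consistency matrix M mapping the basic vector phi to the
# expectation of a study's parameter vector.  For a study whose local
# reference is B != A (the global reference):
#   E[a_j]      = alpha + delta_BA
#   E[b_jk]     = beta_k + gamma_k,BA
#   E[c_jk,WB]  = gamma_k,WA - gamma_k,BA
#   E[d_j,WB]   = delta_WA - delta_BA
# so that every posterior draw satisfies the consistency relations exactly.
mapping_matrix <- function(est, bindex, reference) {
  q <- nrow(est$index); Q <- nrow(bindex)
  M <- matrix(0, q, Q)
  B <- est$local_reference
  bcol <- function(role, covariate = NA, contrast = NA) {
    hit <- bindex$role == role &
      (is.na(covariate) | bindex$covariate %in% covariate) &
      (is.na(contrast) | bindex$contrast %in% contrast)
    w <- which(hit)
    if (!length(w))
      stop("no basic parameter for role=", role, " covariate=", covariate,
           " contrast=", contrast,
           " (did you pool interaction estimates with pool_no_interactions?)")
    w
  }
  for (r in seq_len(q)) {
    role <- est$index$role[r]
    if (role == "intercept") {
      M[r, bcol("alpha")] <- 1
      if (B != reference) M[r, bcol("delta", contrast = B)] <- 1
    } else if (role == "main") {
      k <- est$index$covariate[r]
      M[r, bcol("beta", covariate = k)] <- 1
      if (B != reference && any(bindex$role == "gamma"))
        M[r, bcol("gamma", covariate = k, contrast = B)] <- 1
    } else if (role == "trt") {
      w <- est$index$contrast[r]
      if (B == reference) {
        M[r, bcol("delta", contrast = w)] <- 1
      } else if (w == reference) {
        M[r, bcol("delta", contrast = B)] <- -1
      } else {
        M[r, bcol("delta", contrast = w)] <- 1
        M[r, bcol("delta", contrast = B)] <- -1
      }
    } else if (role == "interaction") {
      w <- est$index$contrast[r]; k <- est$index$covariate[r]
      if (B == reference) {
        M[r, bcol("gamma", covariate = k, contrast = w)] <- 1
      } else if (w == reference) {
        M[r, bcol("gamma", covariate = k, contrast = B)] <- -1
      } else {
        M[r, bcol("gamma", covariate = k, contrast = w)] <- 1
        M[r, bcol("gamma", covariate = k, contrast = B)] <- -1
      }
    }
  }
  M
}

# ---- generic ragged pooling sampler ------------------------------------

# contribs: list of list(theta, S, M, study_id); model one of
# "common", "tau", "full", "diag".  For "tau", is_delta marks the basic
# entries that get study-level random effects.
run_pool <- function(contribs, bindex, model = "common",
                     priors = prior_settings(),
                     mcmc = mcmc_settings(profile = "pool"),
                     tau_prior = list(upper = 100), context = "pooling") {
  Q <- nrow(bindex)
  J <- length(contribs)
  # pad one-dimensional contributions with an inert standard-normal
  # component (zero mapping row) so every block is a valid dmnorm node
  contribs <- lapply(contribs, function(cb) {
    if (length(cb$theta) == 1L) {
      cb$theta <- c(cb$theta, 0)
      cb$S <- diag(c(cb$S[1, 1], 1))
      cb$M <- rbind(cb$M, 0)
    }
    cb
  })
  Ps <- vapply(contribs, function(cb) length(cb$theta), 0L)
  maxP <- max(Ps)
  informed <- Reduce(`+`, lapply(contribs, function(cb)
    colSums(abs(cb$M)) > 0))
  if (any(informed == 0))
    stop("pooled parameter(s) informed by no study: ",
         paste(param_labels(bindex)[informed == 0], collapse = ", "))

  theta <- matrix(0, J, maxP)
  Omega <- array(0, c(J, maxP, maxP))
  M <- array(0, c(J, maxP, Q))
  for (j in seq_len(J)) {
    cb <- contribs[[j]]
    pj <- Ps[j]
    theta[j, 1:pj] <- cb$theta
    Omega[j, 1:pj, 1:pj] <- solve(cb$S)
    M[j, 1:pj, 1:Q] <- cb$M
  }
  jd <- list(theta = theta, Omega = Omega, M = M, J = J, P = Ps, Q = Q,
             prior_prec = 1 / priors$coef_sd^2)
  monitor <- "phi"
  lik <- c(
    "for(j in 1:J){",
    "  theta[j,1:P[j]] ~ dmnorm(mu[j,1:P[j]], Omega[j,1:P[j],1:P[j]])",
    "}")
  if (model == "tau" && is.numeric(tau_prior) && tau_prior == 0)
    model <- "common"  # degenerate prior: no between-study variation
  if (model == "common") {
    body <- c("for(j in 1:J){",
              "  for(r in 1:P[j]){ mu[j,r] <- inprod(M[j,r,1:Q], phi[1:Q]) }",
              "}")
  } else if (model == "tau") {
    jd$isdelta <- as.numeric(bindex$role == "delta")
    if (is.numeric(tau_prior)) {  # fixed tau
      jd$tau <- tau_prior
      tau_lines <- character(0)
    } else {
      jd$tau_upper <- tau_prior$upper
      tau_lines <- "tau ~ dunif(0, tau_upper)"
      monitor <- c(monitor, "tau")
    }
    body <- c("for(j in 1:J){",
              "  for(k in 1:Q){",
              "    re[j,k] ~ dnorm(phi[k], prec_tau)",
              "    phis[j,k] <- (1-isdelta[k])*phi[k] + isdelta[k]*re[j,k]",
              "  }",
              "  for(r in 1:P[j]){ mu[j,r] <- inprod(M[j,r,1:Q], phis[j,1:Q]) }", "}",
              tau_lines,
              "prec_tau <- pow(tau + 1.0E-10, -2)")
  } else if (model == "full") {
    jd$Rmat <- diag(0.1, Q)
    jd$wdf <- Q + 1
    monitor <- c(monitor, "SigmaB")
    body <- c("for(j in 1:J){",
              "  xi[j,1:Q] ~ dmnorm(phi[1:Q], OmegaB[1:Q,1:Q])",
              "  for(r in 1:P[j]){ mu[j,r] <- inprod(M[j,r,1:Q], xi[j,1:Q]) }", "}",
              "OmegaB[1:Q,1:Q] ~ dwish(Rmat[1:Q,1:Q], wdf)",
              "SigmaB[1:Q,1:Q] <- inverse(OmegaB[1:Q,1:Q])")
  } else if (model == "diag") {
    jd$sd_upper <- if (is.list(tau_prior)) tau_prior$upper else 100
    monitor <- c(monitor, "sd_b")
    body <- c("for(j in 1:J){",
              "  for(k in 1:Q){ xi[j,k] ~ dnorm(phi[k], pow(sd_b[k],-2)) }",
              "  for(r in 1:P[j]){ mu[j,r] <- inprod(M[j,r,1:Q], xi[j,1:Q]) }", "}",
              "for(k in 1:Q){ sd_b[k] ~ dunif(0, sd_upper) }")
  } else stop("unknown pooling model: ", model)
  lines <- c("model{", lik, body,
             "for(k in 1:Q){ phi[k] ~ dnorm(0, prior_prec) }", "}")
  fit <- run_jags(paste(lines, collapse = "\n"), jd, monitor, mcmc)
  check_convergence(fit$gr[grep("^phi", names(fit$gr))], mcmc, context)

  phi_cols <- if (Q == 1L) grep("^phi", colnames(fit$draws), value = TRUE)
              else paste0("phi[", seq_len(Q), "]")
  draws <- fit$draws[, phi_cols, drop = FALSE]
  colnames(draws) <- param_labels(bindex)
  tau_draws <- if ("tau" %in% colnames(fit$draws)) fit$draws[, "tau"] else NULL
  list(draws = draws, tau_draws = tau_draws, gr = fit$gr, raw = fit$draws)
}

new_meta_params <- function(pool, bindex, treatments, reference, covariates,
                            model, studies, weights = NULL) {
  structure(list(draws = pool$draws,
                 mean = colMeans(pool$draws),
                 sd = apply(pool$draws, 2, stats::sd),
                 index = bindex, treatments = treatments,
                 reference = reference, covariates = covariates,
                 model = model, tau_draws = pool$tau_draws, gr = pool$gr,
                 studies = studies, weights = weights),
            class = "meta_params")
}

#' @export
print.meta_params <- function(x, digits = 3, ...) {
  cat("Pooled second-stage parameters (", x$model, " model, ",
      length(x$studies), " studies)\n", sep = "")
  est <- data.frame(mean = round(x$mean, digits), sd = round(x$sd, digits))
  print(est)
  if (!is.null(x$tau_draws))
    cat("between-study sd tau: median",
        round(stats::median(x$tau_draws), digits), "\n")
  invisible(x)
}

prepare_ests <- function(ests, reference, interactions = NULL) {
  stopifnot(length(ests) >= 1)
  for (e in ests) stopifnot(inherits(e, "study_estimate"))
  covariates <- ests[[1]]$covariates
  for (e in ests)
    if (!identical(e$covariates, covariates))
      stop("studies have different covariate lists")
  has_int <- vapply(ests, function(e) any(e$index$role == "interaction"), TRUE)
  if (is.null(interactions)) {
    if (any(has_int) && !all(has_int))
      stop("mix of estimates with and without interaction terms")
    interactions <- all(has_int)
  }
  trts <- sort(unique(unlist(lapply(ests, function(e) e$arms))))
  reference <- tolower(reference)
  if (!reference %in% trts) stop("reference '", reference,
                                 "' not among estimated treatments")
  treatments <- c(reference, setdiff(trts, reference))
  list(treatments = treatments, covariates = covariates,
       interactions = interactions,
       bindex = basic_index(treatments, covariates, interactions))
}

# ---- the pooling models -------------------------------------------------

#' Common-effect multivariate pooling of study estimates
#'
#' Pools first-stage estimates assuming every study shares the same
#' intercept, main effects, effect modifiers and relative effects: each
#' study's estimate is normal around a selection/consistency mapping of the
#' pooled vector, with its own first-stage covariance.  Studies inform only
#' the parameters they estimate.
#'
#' @param ests list of `study_estimate`s on the natural scale.
#' @param reference the global reference treatment.
#' @param priors a [prior_settings()].
#' @param mcmc an [mcmc_settings()].
#' @return A `meta_params` object holding posterior draws and summaries of
#'   alpha, beta, gamma and delta.
#' @export
pool_common <- function(ests, reference,
                        priors = prior_settings(),
                        mcmc = mcmc_settings(profile = "pool")) {
  lay <- prepare_ests(ests, reference)
  contribs <- lapply(ests, function(e)
    list(theta = e$theta, S = e$S,
         M = mapping_matrix(e, lay$bindex, lay$treatments[1]),
         study_id = e$study_id))
  pool <- run_pool(contribs, lay$bindex, "common", priors, mcmc,
                   context = "common-effect pooling")
  new_meta_params(pool, lay$bindex, lay$treatments, lay$treatments[1],
                  lay$covariates, "common",
                  vapply(ests, function(e) e$study_id, ""))
}

#' Random-effects pooling with a common between-study variance
#'
#' As [pool_common()], but the relative treatment effects are study-specific,
#' normally distributed around the pooled effects with a single between-study
#' standard deviation `tau` shared across treatment contrasts; intercept,
#' main effects and effect modifiers remain common.
#'
#' @inheritParams pool_common
#' @param tau_prior either `list(upper = )` for a Uniform(0, upper) prior on
#'   `tau`, or a fixed numeric value (0 recovers the common-effect model).
#' @return A `meta_params` with `tau_draws` when `tau` is random.
#' @export
pool_random_tau <- function(ests, reference,
                            tau_prior = list(upper = 100),
                            priors = prior_settings(),
                            mcmc = mcmc_settings(profile = "pool")) {
  lay <- prepare_ests(ests, reference)
  contribs <- lapply(ests, function(e)
    list(theta = e$theta, S = e$S,
         M = mapping_matrix(e, lay$bindex, lay$treatments[1]),
         study_id = e$study_id))
  ninform <- Reduce(`+`, lapply(contribs, function(cb)
    as.numeric(colSums(abs(cb$M)) > 0)))
  if (any(ninform[lay$bindex$role == "delta"] < 2))
    warning("some treatment contrasts are informed by fewer than 2 studies;",
            " tau is weakly identified")
  pool <- run_pool(contribs, lay$bindex, "tau", priors, mcmc,
                   tau_prior = tau_prior,
                   context = "random-effects pooling")
  new_meta_params(pool, lay$bindex, lay$treatments, lay$treatments[1],
                  lay$covariates, "random-tau",
                  vapply(ests, function(e) e$study_id, ""))
}

#' Full multivariate random-effects pooling
#'
#' Every study has its own latent parameter vector, normal around the pooled
#' vector with between-study covariance `Sigma` (inverse-Wishart prior), or a
#' diagonal `Sigma` with independent uniform priors on the standard
#' deviations.  Estimating a full `Sigma` needs more studies than parameters;
#' with few studies prefer the common-`tau` or common-effect simplifications.
#'
#' @inheritParams pool_common
#' @param form `"full"` or `"diagonal"`.
#' @param Sigma optionally a fixed between-study covariance; the zero matrix
#'   recovers the common-effect model.
#' @export
pool_full_mv <- function(ests, reference, form = c("full", "diagonal"),
                         Sigma = NULL,
                         priors = prior_settings(),
                         mcmc = mcmc_settings(profile = "pool")) {
  form <- match.arg(form)
  lay <- prepare_ests(ests, reference)
  Q <- nrow(lay$bindex)
  if (!is.null(Sigma) && all(Sigma == 0))
    return(pool_common(ests, reference, priors, mcmc))
  J <- length(ests)
  if (form == "full" && J < Q + 1)
    stop("full between-study covariance needs more studies (", J,
         ") than parameters (", Q, "); use the common-tau or common-effect",
         " simplification")
  if (form == "diagonal" && J < 3)
    stop("diagonal between-study covariance needs at least 3 studies")
  contribs <- lapply(ests, function(e)
    list(theta = e$theta, S = e$S,
         M = mapping_matrix(e, lay$bindex, lay$treatments[1]),
         study_id = e$study_id))
  pool <- run_pool(contribs, lay$bindex,
                   if (form == "full") "full" else "diag",
                   priors, mcmc, context = "multivariate RE pooling")
  new_meta_params(pool, lay$bindex, lay$treatments, lay$treatments[1],
                  lay$covariates, paste0("mv-", form),
                  vapply(ests, function(e) e$study_id, ""))
}

#' Design-adjusted pooling with variance inflation of non-randomized evidence
#'
#' Pools relative treatment effects and effect modifiers from all studies,
#' inflating the covariance of each non-randomized study's interaction and
#' treatment-effect block by `1/w` (0 < w <= 1), so that NRS evidence on
#' relative effects is down-weighted while randomized evidence enters at face
#' value; the intercept and covariate main effects are pooled from the NRS
#' only, un-inflated, since they describe the real-world population.
#'
#' @inheritParams pool_common
#' @param weights a single weight applied to every NRS, or a named vector
#'   keyed by study id (RCTs implicitly 1).
#' @export
pool_design_adjusted <- function(ests, reference, weights = 0.25,
                                 priors = prior_settings(),
                                 mcmc = mcmc_settings(profile = "pool")) {
  lay <- prepare_ests(ests, reference)
  designs <- vapply(ests, function(e) e$design, "")
  if (!any(designs == "nrs"))
    stop("design-adjusted pooling needs at least one NRS: the intercept and",
         " main effects are estimated from NRS only")
  ids <- vapply(ests, function(e) e$study_id, "")
  if (is.null(names(weights)))
    weights <- stats::setNames(rep(weights[1], sum(designs == "nrs")),
                               ids[designs == "nrs"])
  stopifnot(all(weights > 0), all(weights <= 1))

  cd <- function(e) which(e$index$role %in% c("trt", "interaction"))
  ab <- function(e) which(e$index$role %in% c("intercept", "main"))
  contribs <- list()
  for (e in ests) {
    M <- mapping_matrix(e, lay$bindex, lay$treatments[1])
    r <- cd(e)
    if (length(r)) {
      S <- e$S[r, r, drop = FALSE]
      if (e$design == "nrs") S <- S / weights[[e$study_id]]
      contribs[[length(contribs) + 1L]] <-
        list(theta = e$theta[r], S = S, M = M[r, , drop = FALSE],
             study_id = e$study_id)
    }
    if (e$design == "nrs") {
      r <- ab(e)
      contribs[[length(contribs) + 1L]] <-
        list(theta = e$theta[r], S = e$S[r, r, drop = FALSE],
             M = M[r, , drop = FALSE], study_id = e$study_id)
    }
  }
  pool <- run_pool(contribs, lay$bindex, "common", priors, mcmc,
                   context = "design-adjusted pooling")
  new_meta_params(pool, lay$bindex, lay$treatments, lay$treatments[1],
                  lay$covariates, "design-adjusted", ids, weights = weights)
}

#' Pooling of no-effect-modifier estimates
#'
#' Common-effect pooling of intercept, main effects and relative effects for
#' first-stage fits made without treatment-covariate interactions.  Supplying
#' estimates that contain interaction terms is an error: the simplified model
#' must be refitted at the first stage, not zeroed out after the fact.
#'
#' @inheritParams pool_common
#' @export
pool_no_interactions <- function(ests, reference,
                                 priors = prior_settings(),
                                 mcmc = mcmc_settings(profile = "pool")) {
  for (e in ests)
    if (any(e$index$role == "interaction"))
      stop("estimates contain interaction terms; refit the first stage with",
           " include_interactions = FALSE")
  lay <- prepare_ests(ests, reference, interactions = FALSE)
  contribs <- lapply(ests, function(e)
    list(theta = e$theta, S = e$S,
         M = mapping_matrix(e, lay$bindex, lay$treatments[1]),
         study_id = e$study_id))
  pool <- run_pool(contribs, lay$bindex, "common", priors, mcmc,
                   context = "no-interaction pooling")
  new_meta_params(pool, lay$bindex, lay$treatments, lay$treatments[1],
                  lay$covariates, "no-interactions",
                  vapply(ests, function(e) e$study_id, ""))
}
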