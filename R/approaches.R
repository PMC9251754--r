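# ---- workspace: shared imputations and cached first-stage fits ---------

# A workspace bundles the imputed data and lazily caches first-stage fits in
# the three variants the approaches need: "plain" (no shrinkage),
# "shrunk" (Laplace prior on interactions), "noint" (no interaction terms).
rwe_workspace <- function(ipd, reference = NULL, m = 20L, pmm_k = 5L,
                          pmm_cycles = 10L,
                          mcmc_study = mcmc_settings(profile = "study"),
                          mcmc_pool = mcmc_settings(profile = "pool"),
                          priors = prior_settings(), seed = 1L) {
  stopifnot(inherits(ipd, "ipd_set"))
  net <- summarize_network(ipd, reference)
  ids <- names(ipd$studies)
  has_na <- vapply(ipd$studies, function(df)
    anyNA(df[ipd$covariates]), TRUE)
  imputed <- lapply(seq_along(ids), function(i) {
    impute_study(ipd$studies[[ids[i]]], ipd$covariates,
                 m = if (has_na[i]) m else 1L, k = pmm_k,
                 cycles = pmm_cycles,
                 seed = as.integer(seed) + 7L * i, study_id = ids[i])
  })
  names(imputed) <- ids
  env <- new.env(parent = emptyenv())
  structure(list(ipd = ipd, net = net, reference = net$reference,
                 imputed = imputed, cache = env,
                 mcmc_study = mcmc_study, mcmc_pool = mcmc_pool,
                 priors = priors, seed = as.integer(seed)),
            class = "rwe_workspace")
}

ws_fit <- function(ws, id, variant) {
  key <- paste(id, variant, sep = "::")
  if (!is.null(ws$cache[[key]])) return(ws$cache[[key]])
  i <- match(id, names(ws$imputed))
  est <- fit_study(ws$imputed[[id]],
                   covariates = ws$ipd$covariates,
                   reference = ws$reference,
                   design = ws$ipd$design[[id]],
                   shrink = variant == "shrunk",
                   include_interactions = variant != "noint",
                   mcmc = ws$mcmc_study, priors = ws$priors,
                   study_id = id)
  ws$cache[[key]] <- est
  est
}

ws_fits <- function(ws, variant, ids = names(ws$imputed)) {
  stats::setNames(lapply(ids, ws_fit, ws = ws, variant = variant), ids)
}

# draws of (alpha, beta) / (gamma, delta) blocks from a pooled meta_params
meta_blocks <- function(mp) {
  ab <- mp$draws[, mp$index$role %in% c("alpha", "beta"), drop = FALSE]
  gd <- mp$draws[, mp$index$role %in% c("gamma", "delta"), drop = FALSE]
  list(ab = ab, gd = gd,
       ab_index = mp$index[mp$index$role %in% c("alpha", "beta"), ],
       gd_index = mp$index[mp$index$role %in% c("gamma", "delta"), ])
}

# draws of a single study's estimate re-expressed in the basic layout; the
# study must use the global reference as its local reference and contain
# every treatment whose parameters are requested.
estimate_blocks <- function(est, treatments, reference) {
  if (est$local_reference != reference)
    stop("study '", est$study_id, "' does not include the reference",
         " treatment '", reference, "'; cannot serve as a calibration source")
  missing_t <- setdiff(treatments, est$arms)
  bindex <- basic_index(treatments, est$covariates,
                        interactions = any(est$index$role == "interaction"))
  Q <- nrow(bindex)
  draws <- matrix(0, nrow(est$draws), Q,
                  dimnames = list(NULL, param_labels(bindex)))
  for (r in seq_len(Q)) {
    role <- bindex$role[r]
    src_role <- c(alpha = "intercept", beta = "main",
                  gamma = "interaction", delta = "trt")[[role]]
    hit <- est$index$role == src_role &
      (is.na(bindex$covariate[r]) |
         est$index$covariate %in% bindex$covariate[r]) &
      (is.na(bindex$contrast[r]) |
         est$index$contrast %in% bindex$contrast[r])
    if (any(hit)) draws[, r] <- est$draws[, which(hit)[1]]
    else if (!is.na(bindex$contrast[r]) && bindex$contrast[r] %in% missing_t)
      stop("study '", est$study_id, "' lacks arm '", bindex$contrast[r],
           "' needed for its parameters")
  }
  mp <- list(draws = draws, index = bindex)
  meta_blocks(mp)
}

#' Wire pooled and study-specific sources into a prediction model
#'
#' Builds the final prediction model for an approach by pairing the source of
#' the intercept and covariate main effects with the source of the effect
#' modifiers and relative treatment effects, per the approach taxonomy:
#' approach I takes everything from a single NRS; IIa/IIb/IV take everything
#' from the pooled analysis; IIc/IIIb take the intercept and main effects
#' from a single target NRS and the relative-effect block from the pooled
#' (IIc) or design-adjusted (IIIb) analysis; IIIa takes the relative-effect
#' block design-adjusted and the intercept/main effects from the NRS-only
#' pooling.
#'
#' @param approach one of `"I"`, `"IIa"`, `"IIb"`, `"IIc"`, `"IIIa"`,
#'   `"IIIb"`, `"IV"`.
#' @param pooled a `meta_params` (required except for approach I).
#' @param target_est a `study_estimate` of the target NRS (required for I,
#'   IIc, IIIb).
#' @param ab_source optionally a precomputed `(alpha, beta)` source (a
#'   `meta_params` over NRS), used by cross-validation rules.
#' @return An object of class `rwe_model`.
#' @export
assemble_approach <- function(approach, pooled = NULL, target_est = NULL,
                              ab_source = NULL) {
  approach <- match.arg(approach,
                        c("I", "IIa", "IIb", "IIc", "IIIa", "IIIb", "IV"))
  need_target <- approach %in% c("I", "IIc", "IIIb") && is.null(ab_source)
  if (need_target && is.null(target_est))
    stop("approach ", approach, " requires a target NRS estimate")
  if (approach != "I" && is.null(pooled))
    stop("approach ", approach, " requires pooled second-stage parameters")

  if (approach == "I") {
    treatments <- c(target_est$local_reference,
                    setdiff(target_est$arms, target_est$local_reference))
    src <- estimate_blocks(target_est, treatments,
                           target_est$local_reference)
    ab <- src$ab; gd <- src$gd
    gd_index <- src$gd_index
    reference <- target_est$local_reference
    covariates <- target_est$covariates
    interactions <- any(target_est$index$role == "interaction")
  } else {
    treatments <- pooled$treatments
    reference <- pooled$reference
    covariates <- pooled$covariates
    interactions <- any(pooled$index$role == "gamma")
    pb <- meta_blocks(pooled)
    gd <- pb$gd; gd_index <- pb$gd_index
    if (!is.null(ab_source)) {
      ab <- meta_blocks(ab_source)$ab
    } else if (approach %in% c("IIc", "IIIb")) {
      ab <- estimate_blocks(target_est, treatments, reference)$ab
    } else {
      ab <- pb$ab
    }
  }
  structure(list(approach = approach, reference = reference,
                 treatments = treatments, covariates = covariates,
                 interactions = interactions,
                 ab = ab, gd = gd, gd_index = gd_index,
                 pooled = pooled, target_est = target_est),
            class = "rwe_model")
}

# ---- top-level fitting --------------------------------------------------

#' Fit a real-world outcome prediction model from multi-study IPD
#'
#' Runs the full two-stage pipeline for one modelling approach: multiple
#' imputation of missing covariates per study, per-study Bayesian regression
#' (standardized covariates, optional Laplace shrinkage of interactions,
#' posterior draws mixed across imputations and returned on the natural
#' scale), second-stage multivariate pooling, and assembly of the prediction
#' model `y(x, t) = alpha + beta'x + gamma_t'x + delta_t`.
#'
#' The approaches differ in what feeds the model: `"I"` uses a single NRS
#' with shrinkage; `"IIa"` pools all studies design-naively without
#' shrinkage; `"IIb"` adds shrinkage; `"IIc"` is IIb with the intercept and
#' main effects re-estimated from the target NRS; `"IIIa"` down-weights NRS
#' relative effects by inflating their variances by `1/weight` and estimates
#' intercept/main effects from NRS only; `"IIIb"` is IIIa with a target-NRS
#' intercept source; `"IV"` is IIa without effect modifiers.
#'
#' @param ipd an `ipd_set`.
#' @param approach one of `"I"`, `"IIa"`, `"IIb"`, `"IIc"`, `"IIIa"`,
#'   `"IIIb"`, `"IV"`.
#' @param reference global reference treatment; default: the arm with most
#'   patients.
#' @param target_nrs study id of the target NRS (required for I, IIc, IIIb).
#' @param weight NRS down-weighting factor in (0, 1] for IIIa/IIIb.
#' @param second_stage pooling model for IIa/IIb/IIc: `"common"`,
#'   `"tau"` (random treatment effects, shared between-study sd), `"full"`
#'   or `"diagonal"` multivariate random effects.
#' @param m number of imputations for studies with missing covariate cells.
#' @param mcmc_study,mcmc_pool [mcmc_settings()] for the two stages.
#' @param priors a [prior_settings()].
#' @param seed integer seed controlling imputation and MCMC reproducibility.
#' @param workspace internal: reuse a prepared workspace (used by the
#'   cross-validation drivers).
#' @return An `rwe_model`; see [predict.rwe_model()].
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cov = 3, studies = data.frame(
#'   study = c("t1", "r1"), design = c("rct", "nrs"), n = c(150, 150),
#'   arms = I(list(c("dmards", "rtx"), c("dmards", "rtx")))))
#' ipd <- simulate_ipd(cfg, seed = 7)
#' fit <- rwe_fit(ipd, "IIa", m = 1,
#'                mcmc_study = mcmc_settings(profile = "test"),
#'                mcmc_pool = mcmc_settings(chains = 3, iter = 5000,
#'                                          burnin = 1000))
#' coef(fit)
#' }
#' @export
rwe_fit <- function(ipd, approach = "IIb", reference = NULL,
                    target_nrs = NULL, weight = 0.25,
                    second_stage = c("common", "tau", "full", "diagonal"),
                    m = 20L,
                    mcmc_study = mcmc_settings(profile = "study"),
                    mcmc_pool = mcmc_settings(profile = "pool"),
                    priors = prior_settings(), seed = 1L,
                    workspace = NULL) {
  approach <- match.arg(approach,
                        c("I", "IIa", "IIb", "IIc", "IIIa", "IIIb", "IV"))
  second_stage <- match.arg(second_stage)
  ws <- if (is.null(workspace))
    rwe_workspace(ipd, reference, m = m, mcmc_study = mcmc_study,
                  mcmc_pool = mcmc_pool, priors = priors, seed = seed)
  else workspace

  if (approach %in% c("I", "IIc", "IIIb")) {
    if (is.null(target_nrs))
      stop("approach ", approach, " requires target_nrs")
    if (!target_nrs %in% names(ws$ipd$studies))
      stop("target_nrs '", target_nrs, "' not among the studies")
    if (ws$ipd$design[[target_nrs]] != "nrs")
      stop("target study '", target_nrs, "' is not an NRS")
  }

  model <- switch(approach,
    "I" = {
      target <- ws_fit(ws, target_nrs, "shrunk")
      assemble_approach("I", target_est = target)
    },
    "IIa" = ,
    "IIb" = {
      variant <- if (approach == "IIb") "shrunk" else "plain"
      ests <- ws_fits(ws, variant)
      pooled <- pool_stage2(ests, ws, second_stage)
      assemble_approach(approach, pooled = pooled)
    },
    "IIc" = {
      ests <- ws_fits(ws, "shrunk")
      pooled <- pool_stage2(ests, ws, second_stage)
      assemble_approach("IIc", pooled = pooled,
                        target_est = ests[[target_nrs]])
    },
    "IIIa" = {
      ests <- ws_fits(ws, "shrunk")
      pooled <- pool_design_adjusted(ests, ws$reference, weights = weight,
                                     priors = ws$priors,
                                     mcmc = ws$mcmc_pool)
      assemble_approach("IIIa", pooled = pooled)
    },
    "IIIb" = {
      ests <- ws_fits(ws, "shrunk")
      pooled <- pool_design_adjusted(ests, ws$reference, weights = weight,
                                     priors = ws$priors,
                                     mcmc = ws$mcmc_pool)
      assemble_approach("IIIb", pooled = pooled,
                        target_est = ests[[target_nrs]])
    },
    "IV" = {
      ests <- ws_fits(ws, "noint")
      pooled <- pool_no_interactions(ests, ws$reference,
                                     priors = ws$priors,
                                     mcmc = ws$mcmc_pool)
      assemble_approach("IV", pooled = pooled)
    })
  model$network <- ws$net
  model$workspace <- ws
  model
}

pool_stage2 <- function(ests, ws, second_stage) {
  switch(second_stage,
         common = pool_common(ests, ws$reference, priors = ws$priors,
                              mcmc = ws$mcmc_pool),
         tau = pool_random_tau(ests, ws$reference, priors = ws$priors,
                               mcmc = ws$mcmc_pool),
         full = pool_full_mv(ests, ws$reference, form = "full",
                             priors = ws$priors, mcmc = ws$mcmc_pool),
         diagonal = pool_full_mv(ests, ws$reference, form = "diagonal",
                                 priors = ws$priors, mcmc = ws$mcmc_pool))
}

# ---- rwe_model methods --------------------------------------------------

#' @export
print.rwe_model <- function(x, ...) {
  cat("Real-world outcome prediction model (approach ", x$approach, ")\n",
      sep = "")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      "(reference:", paste0(x$reference, ")"), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (!x$interactions) cat("  no effect modifiers (gamma = 0)\n")
  cat("  posterior draws:", nrow(x$ab), "(intercept/main block),",
      nrow(x$gd), "(relative-effect block)\n")
  invisible(x)
}

#' @export
coef.rwe_model <- function(object, ...) {
  c(colMeans(object$ab), colMeans(object$gd))
}

#' @export
summary.rwe_model <- function(object, level = 0.95, ...) {
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draws <- cbind(object$ab, object$gd)
  tab <- data.frame(mean = colMeans(draws),
                    sd = apply(draws, 2, stats::sd),
                    lower = apply(draws, 2, stats::quantile, qs[1]),
                    upper = apply(draws, 2, stats::quantile, qs[2]))
  structure(list(approach = object$approach, table = tab, level = level),
            class = "summary.rwe_model")
}

#' @export
print.summary.rwe_model <- function(x, digits = 3, ...) {
  cat("Approach", x$approach, "posterior summary (",
      100 * x$level, "% credible intervals)\n")
  print(round(x$table, digits))
  invisible(x)
}

# point (posterior-mean) linear predictor; exact because the predictor is
# linear in the parameters
lp_point <- function(object, X, t) {
  ab <- colMeans(object$ab)
  out <- as.numeric(cbind(1, X) %*% ab)
  if (t != object$reference) {
    gd <- colMeans(object$gd)
    lab_d <- paste0("delta.", t)
    if (!lab_d %in% names(gd)) stop("unknown treatment: ", t)
    out <- out + gd[[lab_d]]
    if (object$interactions) {
      gcols <- paste0("gamma.", object$covariates, ":", t)
      out <- out + as.numeric(X %*% gd[gcols])
    }
  }
  out
}

# draws of the linear predictor for each row of X under treatment t:
# returns (ndraws x n) matrix
lp_draws <- function(object, X, t, nd) {
  Xt <- rbind(1, t(X))
  out <- object$ab[seq_len(nd), , drop = FALSE] %*% Xt
  if (t != object$reference) {
    lab_d <- paste0("delta.", t)
    if (!lab_d %in% colnames(object$gd))
      stop("unknown treatment: ", t)
    gdd <- object$gd[seq_len(nd), , drop = FALSE]
    out <- out + gdd[, lab_d]
    if (object$interactions) {
      gcols <- paste0("gamma.", object$covariates, ":", t)
      out <- out + gdd[, gcols, drop = FALSE] %*% t(X)
    }
  }
  out
}

check_newdata <- function(object, newdata) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$covariates, names(newdata))
    if (length(miss))
      stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
    newdata <- as.matrix(newdata[object$covariates])
  }
  if (ncol(newdata) != length(object$covariates))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$covariates), " covariates")
  if (anyNA(newdata))
    stop("newdata contains missing covariate values; impute first")
  newdata
}

#' Predict outcomes or treatment benefits for new patients
#'
#' Evaluates the prediction model drawwise over the posterior, returning the
#' posterior-mean prediction and a central credible interval.  For
#' `type = "benefit"` the predicted difference between outcomes under
#' `treatment` and `comparator` is returned; the intercept and main-effect
#' contributions cancel exactly in every draw.
#'
#' @param object an `rwe_model`.
#' @param newdata data.frame (or matrix) of covariate values on the natural
#'   scale, one row per patient; no missing entries.
#' @param treatment a treatment label, `"all"` (outcome under every
#'   treatment), or for benefits the first treatment of the difference.
#' @param type `"outcome"` or `"benefit"`.
#' @param comparator second treatment of the benefit difference (default:
#'   the reference).
#' @param level credible level of the interval.
#' @param interval `"credible"` or `"none"` (point predictions only; exact,
#'   since the predictor is linear in the parameters).
#' @param ndraws cap on the number of posterior draws used drawwise.
#' @param draws if `TRUE`, also return the draw matrices (patients in
#'   columns).
#' @param ... unused.
#' @return A data.frame with columns `patient`, `treatment` (or
#'   `treatment`/`comparator`), `fit`, and `lwr`/`upr` unless
#'   `interval = "none"`; with `draws = TRUE`, a list with the data.frame
#'   and the draw matrices.
#' @export
predict.rwe_model <- function(object, newdata, treatment = "all",
                              type = c("outcome", "benefit"),
                              comparator = NULL, level = 0.95,
                              interval = c("credible", "none"),
                              ndraws = 4000L, draws = FALSE, ...) {
  type <- match.arg(type)
  interval <- match.arg(interval)
  X <- check_newdata(object, newdata)
  n <- nrow(X)
  nd <- min(nrow(object$ab), nrow(object$gd), ndraws)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pat <- if (is.data.frame(newdata) && !is.null(rownames(newdata)))
    rownames(newdata) else as.character(seq_len(n))

  if (type == "outcome") {
    trts <- if (identical(treatment, "all")) object$treatments
            else tolower(treatment)
    bad <- setdiff(trts, object$treatments)
    if (length(bad)) stop("unknown treatment(s): ", paste(bad, collapse = ", "))
    res <- list(); dmat <- list()
    for (t in trts) {
      if (interval == "none" && !draws) {
        df <- data.frame(patient = pat, treatment = t,
                         fit = lp_point(object, X, t),
                         stringsAsFactors = FALSE)
      } else {
        lp <- lp_draws(object, X, t, nd)
        df <- data.frame(patient = pat, treatment = t,
                         fit = colMeans(lp), stringsAsFactors = FALSE)
        if (interval == "credible") {
          qq <- apply(lp, 2, stats::quantile, qs)
          df$lwr <- qq[1, ]; df$upr <- qq[2, ]
        }
        if (draws) dmat[[t]] <- lp
      }
      res[[t]] <- df
    }
    out <- do.call(rbind, res); rownames(out) <- NULL
  } else {
    t1 <- tolower(if (identical(treatment, "all")) object$treatments[2]
                  else treatment)
    t2 <- tolower(if (is.null(comparator)) object$reference else comparator)
    for (t in c(t1, t2))
      if (!t %in% object$treatments) stop("unknown treatment: ", t)
    if (interval == "none" && !draws) {
      out <- data.frame(patient = pat, treatment = t1, comparator = t2,
                        fit = lp_point(object, X, t1) -
                          lp_point(object, X, t2),
                        stringsAsFactors = FALSE)
    } else {
      lp <- lp_draws(object, X, t1, nd) - lp_draws(object, X, t2, nd)
      out <- data.frame(patient = pat, treatment = t1, comparator = t2,
                        fit = colMeans(lp), stringsAsFactors = FALSE)
      if (interval == "credible") {
        qq <- apply(lp, 2, stats::quantile, qs)
        out$lwr <- qq[1, ]; out$upr <- qq[2, ]
      }
      if (draws) dmat <- list(benefit = lp)
    }
  }
  if (draws) list(prediction = out, draws = dmat) else out
}
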