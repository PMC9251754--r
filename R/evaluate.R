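# ---- performance metrics ------------------------------------------------

#' Mean squared error and bias, overall and per treatment arm
#'
#' `MSE = mean((pred - obs)^2)`, `bias = mean(pred - obs)`; values close to
#' zero indicate good performance.  With `arms` given, the same quantities
#' are reported within each treatment arm.
#'
#' @param pred,obs numeric vectors of equal length.
#' @param arms optional treatment labels per observation.
#' @return list with `overall` (named vector `mse`, `bias`, `n`) and, when
#'   `arms` is given, `per_arm` (data.frame with one row per arm).
#' @export
mse_bias <- function(pred, obs, arms = NULL) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]
  out <- list(overall = c(mse = mean((pred - obs)^2),
                          bias = mean(pred - obs), n = length(pred)))
  if (!is.null(arms)) {
    arms <- arms[ok]
    per <- lapply(sort(unique(arms)), function(a) {
      i <- arms == a
      if (!any(i)) {
        warning("empty arm subset: ", a)
        return(NULL)
      }
      data.frame(arm = a, mse = mean((pred[i] - obs[i])^2),
                 bias = mean(pred[i] - obs[i]), n = sum(i),
                 stringsAsFactors = FALSE)
    })
    out$per_arm <- do.call(rbind, per)
  }
  out
}

#' Coefficient of determination of predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean.  Negative values (predictions worse than the observed
#' mean) are permitted.
#'
#' @param pred,obs numeric vectors of equal length, `length >= 2`.
#' @return a single numeric value.
#' @export
r_squared <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]
  stopifnot(length(obs) >= 2)
  if (stats::var(obs) == 0)
    stop("observed outcomes are constant; R-squared is undefined")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Calibration line for predicted outcomes
#'
#' Least-squares fit of the observed outcome on the predicted outcome with a
#' shared intercept and one slope per treatment arm:
#' `y = eta_0 + sum_k eta_k * pred * I(arm = k)`.  An intercept near 0 and
#' slopes near 1 indicate good calibration.
#'
#' @param pred,obs numeric vectors.
#' @param arms treatment label per observation.
#' @return list with `intercept`, `slopes` (named by arm), `unstable`
#'   (arms with fewer than 2 patients, whose slope is flagged), and the
#'   underlying `lm` fit.
#' @export
calibration_outcome <- function(pred, obs, arms) {
  stopifnot(length(pred) == length(obs), length(obs) == length(arms))
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]; arms <- as.character(arms[ok])
  labs <- sort(unique(arms))
  Xc <- sapply(labs, function(a) pred * (arms == a))
  if (is.null(dim(Xc))) Xc <- matrix(Xc, nrow = 1)
  colnames(Xc) <- labs
  fit <- stats::lm(obs ~ Xc)
  coefs <- stats::coef(fit)
  unstable <- labs[table(factor(arms, levels = labs)) < 2]
  list(intercept = unname(coefs[1]),
       slopes = stats::setNames(unname(coefs[-1]), labs),
       unstable = unstable, fit = fit)
}

#' Calibration line for predicted treatment benefit
#'
#' Regresses the observed outcome on the predicted outcome under the
#' reference treatment (the prognostic component) and on the predicted
#' benefit of the received treatment over the reference:
#' `y = kappa_0 + kappa_1 pred_ref + sum_{k>1} kappa_k (pred_k - pred_ref)
#' I(arm = k)`.  Slopes near 1 mean predicted benefits are realized on
#' average.
#'
#' @param pred_matrix matrix of predicted outcomes, one row per patient, one
#'   column per treatment, columns named by treatment with the reference
#'   first (as produced from [predict.rwe_model()] point predictions).
#' @param obs observed outcomes.
#' @param arms treatment received.
#' @return list with `intercept`, `prognostic_slope` (on the
#'   reference-treatment prediction) and `benefit_slopes` per non-reference
#'   treatment, plus the `lm` fit.
#' @export
calibration_benefit <- function(pred_matrix, obs, arms) {
  pred_matrix <- as.matrix(pred_matrix)
  trts <- colnames(pred_matrix)
  stopifnot(!is.null(trts), nrow(pred_matrix) == length(obs),
            length(obs) == length(arms))
  ok <- !is.na(obs) & stats::complete.cases(pred_matrix)
  pred_matrix <- pred_matrix[ok, , drop = FALSE]
  obs <- obs[ok]; arms <- as.character(arms[ok])
  ref <- trts[1]
  Xb <- cbind(pred_matrix[, ref])
  colnames(Xb) <- ref
  for (t in trts[-1]) {
    Xb <- cbind(Xb, (pred_matrix[, t] - pred_matrix[, ref]) * (arms == t))
    colnames(Xb)[ncol(Xb)] <- t
  }
  fit <- stats::lm(obs ~ Xb)
  coefs <- stats::coef(fit)
  list(intercept = unname(coefs[1]),
       prognostic_slope = unname(coefs[2]),
       benefit_slopes = stats::setNames(unname(coefs[-(1:2)]), trts[-1]),
       fit = fit)
}

# all metrics for one model on one evaluation study; rows that cannot be
# scored (missing outcome or missing covariate values) are excluded from
# the metrics and counted in the report
evaluate_model <- function(model, study_df, covariates) {
  ok_y <- !is.na(study_df$y)
  ok_x <- stats::complete.cases(study_df[covariates])
  n_missing_y <- sum(!ok_y)
  n_missing_x <- sum(ok_y & !ok_x)
  ok <- ok_y & ok_x
  df <- study_df[ok, , drop = FALSE]
  X <- df[covariates]
  preds <- sapply(model$treatments, function(t)
    lp_point(model, check_newdata(model, X), t))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1,
                                           dimnames = list(NULL,
                                                           model$treatments))
  received <- match(df$treatment, model$treatments)
  if (anyNA(received))
    stop("evaluation study contains treatment(s) unknown to the model: ",
         paste(setdiff(df$treatment, model$treatments), collapse = ", "))
  pred_received <- preds[cbind(seq_len(nrow(preds)), received)]
  mb <- mse_bias(pred_received, df$y, df$treatment)
  co <- calibration_outcome(pred_received, df$y, df$treatment)
  cb <- calibration_benefit(preds, df$y, df$treatment)
  list(mse = mb$overall[["mse"]], bias = mb$overall[["bias"]],
       per_arm = mb$per_arm,
       r2 = r_squared(pred_received, df$y),
       calibration = co, calibration_benefit = cb,
       n = nrow(df), n_missing_outcome = n_missing_y,
       n_missing_covariates = n_missing_x,
       scatter = data.frame(pred = pred_received, obs = df$y,
                            arm = df$treatment, stringsAsFactors = FALSE))
}

flat_metrics <- function(ev) {
  c(mse = ev$mse, bias = ev$bias, r2 = ev$r2,
    cal_intercept = ev$calibration$intercept,
    stats::setNames(ev$calibration$slopes,
                    paste0("cal_slope.", names(ev$calibration$slopes))),
    benefit_intercept = ev$calibration_benefit$intercept,
    benefit_prognostic = ev$calibration_benefit$prognostic_slope,
    stats::setNames(ev$calibration_benefit$benefit_slopes,
                    paste0("benefit_slope.",
                           names(ev$calibration_benefit$benefit_slopes))))
}

# ---- internal validation with bootstrap optimism correction ------------

resample_ipd <- function(ipd, seed) {
  set.seed(as.integer(seed))
  for (s in names(ipd$studies)) {
    df <- ipd$studies[[s]]
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$treatment),
                         function(i) sample(i, length(i), replace = TRUE)))
    ipd$studies[[s]] <- df[sort(idx), , drop = FALSE]
  }
  ipd
}

#' Internal validation of the modelling approaches
#'
#' Trains each approach on all available data and scores it on each NRS
#' separately (prediction of real-world outcomes is the goal, so metrics are
#' always computed on NRS patients), overall and per treatment arm.  With
#' `B > 0`, optimism-corrected performance is estimated by bootstrap:
#' patients are resampled within study and arm, every approach is refitted
#' on the bootstrap data, and the mean difference between its performance on
#' the bootstrap NRS and on the original NRS is subtracted from the apparent
#' performance.  For the approaches anchored to a target NRS (I, IIc, IIIb)
#' the target is the NRS being evaluated.
#'
#' @param ipd an `ipd_set` with at least one NRS.
#' @param approaches character vector of approach labels.
#' @param B number of bootstrap resamples (0 = apparent metrics only).
#' @param seed integer seed.
#' @param ... further arguments to [rwe_fit()] (`reference`, `weight`, `m`,
#'   `mcmc_study`, `mcmc_pool`, `priors`, `second_stage`).
#' @param boot_mcmc optional reduced [mcmc_settings()] used for the
#'   bootstrap refits (recorded in the report); refitting a long-chain model
#'   hundreds of times is rarely warranted.
#' @return An object of class `rwe_validation`: per-NRS, per-approach
#'   apparent metrics (and `optimism` / `corrected` when `B > 0`).
#' @export
internal_validation <- function(ipd, approaches = c("IIa", "IV"), B = 0L,
                                seed = 1L, boot_mcmc = NULL, ...) {
  stopifnot(inherits(ipd, "ipd_set"))
  nrs_ids <- names(ipd$design)[ipd$design == "nrs"]
  if (!length(nrs_ids)) stop("internal validation needs at least one NRS")
  dots <- list(...)

  fit_all <- function(data, mcmc_override = NULL, seed_off = 0L) {
    args <- dots
    if (!is.null(mcmc_override)) {
      args$mcmc_study <- mcmc_override
      args$mcmc_pool <- mcmc_override
    }
    args$seed <- as.integer(seed) + seed_off
    ws <- do.call(rwe_workspace, c(list(ipd = data), args[
      intersect(names(args), c("reference", "m", "mcmc_study", "mcmc_pool",
                               "priors", "seed"))]))
    models <- list()
    for (ap in approaches) {
      if (ap %in% c("I", "IIc", "IIIb")) {
        for (tn in nrs_ids)
          models[[paste0(ap, "@", tn)]] <-
            do.call(rwe_fit, c(list(ipd = data, approach = ap,
                                    target_nrs = tn, workspace = ws),
                               args[intersect(names(args),
                                              c("weight", "second_stage"))]))
      } else {
        models[[ap]] <-
          do.call(rwe_fit, c(list(ipd = data, approach = ap,
                                  workspace = ws),
                             args[intersect(names(args),
                                            c("weight", "second_stage"))]))
      }
    }
    models
  }
  model_for <- function(models, ap, nrs) {
    if (ap %in% c("I", "IIc", "IIIb")) models[[paste0(ap, "@", nrs)]]
    else models[[ap]]
  }

  models <- fit_all(ipd)
  report <- list()
  for (nrs in nrs_ids) {
    report[[nrs]] <- list()
    for (ap in approaches) {
      ev <- evaluate_model(model_for(models, ap, nrs),
                           ipd$studies[[nrs]], ipd$covariates)
      report[[nrs]][[ap]] <- list(apparent = ev)
    }
  }

  if (B > 0) {
    opt_acc <- list()
    for (b in seq_len(B)) {
      boot <- resample_ipd(ipd, seed = as.integer(seed) + 1000L + b)
      bmodels <- fit_all(boot, mcmc_override = boot_mcmc, seed_off = b)
      for (nrs in nrs_ids) for (ap in approaches) {
        mb <- model_for(bmodels, ap, nrs)
        perf_boot <- flat_metrics(evaluate_model(mb, boot$studies[[nrs]],
                                                 ipd$covariates))
        perf_orig <- flat_metrics(evaluate_model(mb, ipd$studies[[nrs]],
                                                 ipd$covariates))
        key <- paste(nrs, ap, sep = "::")
        opt_acc[[key]] <- rbind(opt_acc[[key]], perf_boot - perf_orig)
      }
    }
    for (nrs in nrs_ids) for (ap in approaches) {
      key <- paste(nrs, ap, sep = "::")
      optimism <- colMeans(opt_acc[[key]])
      apparent <- flat_metrics(report[[nrs]][[ap]]$apparent)
      report[[nrs]][[ap]]$optimism <- optimism
      report[[nrs]][[ap]]$corrected <- apparent - optimism
    }
  }
  structure(list(report = report, approaches = approaches, B = B,
                 nrs = nrs_ids,
                 reduced_boot_mcmc = !is.null(boot_mcmc)),
            class = "rwe_validation")
}

#' @export
print.rwe_validation <- function(x, digits = 3, ...) {
  cat("Internal validation (", x$B, " bootstrap resamples",
      if (x$reduced_boot_mcmc) ", reduced-chain refits", ")\n", sep = "")
  for (nrs in names(x$report)) {
    cat("\n== evaluation NRS:", nrs, "==\n")
    tab <- t(sapply(x$report[[nrs]], function(r) flat_metrics(r$apparent)))
    print(round(tab, digits))
  }
  invisible(x)
}

# ---- internal-external (leave-one-NRS-out) cross-validation ------------

drop_study <- function(ipd, id) {
  ipd$studies[[id]] <- NULL
  ipd$design <- ipd$design[names(ipd$design) != id]
  ipd
}

keep_studies <- function(ipd, ids) {
  ipd$studies <- ipd$studies[ids]
  ipd$design <- ipd$design[ids]
  ipd
}

#' Internal-external (leave-one-NRS-out) cross-validation
#'
#' Cycles over the non-randomized studies: each in turn is excluded, the
#' models are trained on the remaining studies, and performance is measured
#' on the left-out NRS.  Approach-specific rules apply: approach I trains on
#' the remaining NRS only (pooled when more than one remains); approaches
#' IIc and IIIb estimate the intercept and covariate main effects from the
#' remaining NRS (never from RCTs) while their relative-effect block comes
#' from all remaining studies.  The overall row pools patients across folds.
#'
#' @param ipd an `ipd_set` with at least 2 NRS.
#' @param approaches character vector of approach labels.
#' @param seed integer seed.
#' @param ... further arguments to [rwe_fit()].
#' @return An object of class `rwe_cv`: per-fold and overall metrics.
#' @export
internal_external_cv <- function(ipd, approaches = c("IIa", "IV"),
                                 seed = 1L, ...) {
  stopifnot(inherits(ipd, "ipd_set"))
  nrs_ids <- names(ipd$design)[ipd$design == "nrs"]
  if (length(nrs_ids) < 2)
    stop("internal-external cross-validation needs at least 2 NRS; with a",
         " single NRS split it by a clustering variable into pseudo-studies")
  dots <- list(...)
  ws_args <- intersect(names(dots), c("reference", "m", "mcmc_study",
                                      "mcmc_pool", "priors"))
  fit_args <- intersect(names(dots), c("weight", "second_stage"))

  folds <- list()
  for (heldout in nrs_ids) {
    train <- drop_study(ipd, heldout)
    net <- tryCatch(summarize_network(train),
                    error = function(e)
                      stop("training network for fold '", heldout,
                           "' is invalid: ", conditionMessage(e)))
    ws <- do.call(rwe_workspace,
                  c(list(ipd = train, seed = as.integer(seed)), dots[ws_args]))
    other_nrs <- setdiff(nrs_ids, heldout)
    fold <- list()
    for (ap in approaches) {
      model <- if (ap == "I") {
        nest <- ws_fits(ws, "shrunk", ids = other_nrs)
        if (length(nest) == 1L) assemble_approach("I", target_est = nest[[1]])
        else {
          pooled <- pool_common(nest, ws$reference, priors = ws$priors,
                                mcmc = ws$mcmc_pool)
          mI <- assemble_approach("IIb", pooled = pooled)
          mI$approach <- "I"  # CV rule: approach I trains on the other NRS
          mI
        }
      } else if (ap %in% c("IIc", "IIIb")) {
        ests <- ws_fits(ws, "shrunk")
        pooled <- if (ap == "IIc")
          pool_stage2(ests, ws, dots$second_stage %||% "common")
        else pool_design_adjusted(ests, ws$reference,
                                  weights = dots$weight %||% 0.25,
                                  priors = ws$priors, mcmc = ws$mcmc_pool)
        ab_pool <- pool_common(lapply(ests[other_nrs], strip_to_ab),
                               ws$reference, priors = ws$priors,
                               mcmc = ws$mcmc_pool)
        assemble_approach(ap, pooled = pooled, ab_source = ab_pool)
      } else {
        do.call(rwe_fit, c(list(ipd = train, approach = ap, workspace = ws),
                           dots[fit_args]))
      }
      fold[[ap]] <- evaluate_model(model, ipd$studies[[heldout]],
                                   ipd$covariates)
    }
    folds[[heldout]] <- fold
  }
  overall <- list()
  for (ap in approaches) {
    sc <- do.call(rbind, lapply(folds, function(f) f[[ap]]$scatter))
    mb <- mse_bias(sc$pred, sc$obs, sc$arm)
    overall[[ap]] <- list(mse = mb$overall[["mse"]],
                          bias = mb$overall[["bias"]],
                          per_arm = mb$per_arm,
                          r2 = r_squared(sc$pred, sc$obs),
                          n = nrow(sc))
  }
  structure(list(folds = folds, overall = overall,
                 approaches = approaches, nrs = nrs_ids),
            class = "rwe_cv")
}

# reduce a study estimate to its intercept/main-effect block (used when the
# calibration source is a pooled set of NRS)
strip_to_ab <- function(est) {
  keep <- est$index$role %in% c("intercept", "main")
  est$index <- est$index[keep, , drop = FALSE]
  est$theta <- est$theta[keep]
  est$S <- est$S[keep, keep, drop = FALSE]
  est$draws <- est$draws[, keep, drop = FALSE]
  est$has_interactions <- FALSE
  est$arms <- est$local_reference  # only alpha/beta are pooled
  est
}

#' @export
print.rwe_cv <- function(x, digits = 3, ...) {
  cat("Internal-external cross-validation over",
      length(x$folds), "NRS folds\n")
  for (f in names(x$folds)) {
    cat("\n== left-out NRS:", f, "==\n")
    tab <- t(sapply(x$folds[[f]], flat_metrics))
    print(round(tab, digits))
  }
  cat("\n== overall (pooled patients across folds) ==\n")
  tab <- t(sapply(x$overall, function(o)
    c(mse = o$mse, bias = o$bias, r2 = o$r2, n = o$n)))
  print(round(tab, digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
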