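#' Multiple imputation of missing covariates by predictive mean matching
#'
#' Fills missing covariate cells within a single study using chained
#' equations with predictive mean matching (PMM): each incomplete covariate
#' is regressed, over its observed rows, on the other covariates, treatment
#' indicators, treatment-covariate interactions, and the outcome; missing
#' entries receive the observed value of a donor drawn at random from the
#' `k` candidates whose predicted means are closest.  Imputation is done in
#' each study separately, and outcomes are never imputed.
#'
#' @param study a per-study data.frame (element of an `ipd_set`).
#' @param covariates ordered covariate names.
#' @param m number of completed data sets.
#' @param k number of PMM donor candidates.
#' @param cycles number of chained-equation sweeps per imputation.
#' @param seed integer seed.
#' @param study_id label for error messages.
#' @return An object of class `imputed_set`: list with `completed` (list of
#'   `m` data.frames), `m`, `study_id`, `covariates`.  Observed cells are
#'   identical across the `m` copies; imputed values are always observed
#'   donor values of the same column.
#' @details A covariate missing for every patient in the study
#'   (systematically missing) is an error: multilevel imputation of
#'   systematically missing predictors is out of scope.  Rows with a missing
#'   outcome participate in the imputation models through a mean-filled
#'   outcome predictor but their outcome is left missing.
#' @export
impute_study <- function(study, covariates, m = 20L, k = 5L, cycles = 10L,
                         seed = 1L, study_id = "study") {
  stopifnot(m >= 1L, k >= 1L, cycles >= 1L)
  for (cv in covariates)
    if (all(is.na(study[[cv]])))
      stop("covariate '", cv, "' is systematically missing in study '",
           study_id, "'; multilevel imputation is not supported")
  incomplete <- covariates[vapply(covariates,
                                  function(cv) anyNA(study[[cv]]), TRUE)]
  if (!length(incomplete)) {
    return(structure(list(completed = rep(list(study), m), m = as.integer(m),
                          study_id = study_id, covariates = covariates),
                     class = "imputed_set"))
  }
  if (!any(!is.na(study$y)))
    stop("study '", study_id, "' has no observed outcomes")
  set.seed(as.integer(seed))

  arms <- sort(unique(study$treatment))
  n <- nrow(study)
  trt_dummies <- sapply(arms[-1], function(a) as.numeric(study$treatment == a))
  if (is.null(dim(trt_dummies))) trt_dummies <- matrix(trt_dummies, n)
  y_fill <- study$y
  y_fill[is.na(y_fill)] <- mean(study$y, na.rm = TRUE)

  completed <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- study
    # initialize missing cells with random observed draws of the same column
    for (cv in incomplete) {
      mis <- is.na(cur[[cv]])
      obs <- study[[cv]][!mis]
      cur[[cv]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (cv in incomplete) {
        mis <- is.na(study[[cv]])
        others <- setdiff(covariates, cv)
        Xo <- as.matrix(cur[others])
        inter <- do.call(cbind, lapply(seq_len(ncol(trt_dummies)), function(a)
          Xo * trt_dummies[, a]))
        Z <- cbind(1, Xo, trt_dummies, inter, y_fill)
        zo <- Z[!mis, , drop = FALSE]
        target <- study[[cv]][!mis]
        # ridge-stabilized least squares for the imputation model
        ZtZ <- crossprod(zo) + diag(1e-8 * max(1, diag(crossprod(zo))),
                                    ncol(zo))
        bhat <- solve(ZtZ, crossprod(zo, target))
        pred_obs <- as.numeric(zo %*% bhat)
        pred_mis <- as.numeric(Z[mis, , drop = FALSE] %*% bhat)
        # k-nearest-donor search on the sorted predictions: a 2k-wide
        # window around the insertion point contains the k closest donors
        o <- order(pred_obs)
        po <- pred_obs[o]; to <- target[o]
        n_obs <- length(po)
        pos <- findInterval(pred_mis, po)
        kk <- min(k, n_obs)
        don <- vapply(seq_along(pred_mis), function(i) {
          lo <- max(1L, pos[i] - kk + 1L)
          hi <- min(n_obs, pos[i] + kk)
          w <- lo:hi
          cand <- w[order(abs(po[w] - pred_mis[i]))[seq_len(kk)]]
          to[cand[sample.int(kk, 1L)]]
        }, 0)
        cur[[cv]][mis] <- don
      }
    }
    completed[[im]] <- cur
  }
  structure(list(completed = completed, m = as.integer(m),
                 study_id = study_id, covariates = covariates),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Imputed set for study '", x$study_id, "': m = ", x$m,
      " completed data sets, n = ", nrow(x$completed[[1]]), "\n", sep = "")
  invisible(x)
}
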