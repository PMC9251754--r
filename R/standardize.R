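#' Study-specific covariate standardization
#'
#' Centers and scales every continuous covariate by its study-specific mean
#' and sample (n-1) standard deviation, so that a penalty on
#' treatment-covariate interactions acts on a common scale.  Binary
#' covariates (observed values within \{0, 1\}) are left untouched, as is the
#' outcome.
#'
#' @param study a per-study data.frame (a `studies` element of an `ipd_set`).
#' @param covariates ordered covariate names.
#' @param study_id label used in error messages.
#' @return list with elements `study` (standardized copy) and `scaling`, a
#'   data.frame with columns `covariate`, `mean`, `sd`, `scaled`;
#'   unscaled covariates carry `mean = 0`, `sd = 1`.
#' @export
standardize_study <- function(study, covariates, study_id = "study") {
  scaling <- data.frame(covariate = covariates, mean = 0, sd = 1,
                        scaled = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    cv <- covariates[i]
    x <- study[[cv]]
    obs <- x[!is.na(x)]
    if (all(obs %in% c(0, 1))) next  # binary: not standardized
    if (length(unique(obs)) < 2L)
      stop("covariate '", cv, "' is constant in study '", study_id,
           "': cannot standardize")
    m <- mean(obs); s <- stats::sd(obs)
    study[[cv]] <- (x - m) / s
    scaling$mean[i] <- m; scaling$sd[i] <- s; scaling$scaled[i] <- TRUE
  }
  list(study = study, scaling = scaling)
}

# Jacobian of the linear map from standardized-scale to natural-scale
# coefficients, for a parameter vector laid out by `index` (see fit_study):
#   a'      = a - sum_k b_k mu_k / s_k
#   b'_k    = b_k / s_k
#   c'_k,W  = c_k,W / s_k
#   d'_W    = d_W - sum_k c_k,W mu_k / s_k
destandardize_jacobian <- function(index, scaling) {
  q <- nrow(index)
  J <- diag(q)
  ratio <- stats::setNames(scaling$mean / scaling$sd, scaling$covariate)
  inv_s <- stats::setNames(1 / scaling$sd, scaling$covariate)
  for (r in seq_len(q)) {
    role <- index$role[r]
    if (role == "intercept") {
      kk <- which(index$role == "main")
      for (k in kk) J[r, k] <- -ratio[[index$covariate[k]]]
    } else if (role == "main") {
      J[r, r] <- inv_s[[index$covariate[r]]]
    } else if (role == "interaction") {
      J[r, r] <- inv_s[[index$covariate[r]]]
    } else if (role == "trt") {
      kk <- which(index$role == "interaction" &
                    index$contrast == index$contrast[r])
      for (k in kk) J[r, k] <- -ratio[[index$covariate[k]]]
    }
  }
  J
}

#' Map a fitted study estimate back to the natural covariate scale
#'
#' Applies the exact linear back-transformation implied by study-specific
#' standardization to the posterior draws (each draw is transformed, then
#' summaries recomputed), so that the linear predictor of any patient is
#' identical on the standardized and natural scales and the covariance
#' transform `S' = J S J'` is exact, preserving positive semi-definiteness.
#'
#' @param est a `study_estimate` fitted on standardized covariates (see
#'   [fit_study()]).
#' @param scaling the `scaling` data.frame returned by [standardize_study()].
#' @return The `study_estimate` on the natural scale.
#' @export
destandardize_estimate <- function(est, scaling) {
  stopifnot(inherits(est, "study_estimate"))
  if (!setequal(scaling$covariate, unique(stats::na.omit(est$index$covariate))) &&
      any(est$index$role %in% c("main", "interaction")))
    stop("scaling covariates do not match the estimate's covariates")
  J <- destandardize_jacobian(est$index, scaling)
  est$draws <- est$draws %*% t(J)
  est$theta <- as.numeric(colMeans(est$draws))
  est$S <- stats::cov(est$draws)
  est$scale <- "natural"
  est
}
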