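#' Configuration for the multi-study IPD simulator
#'
#' Describes a network of randomized trials (RCTs) and non-randomized studies
#' (NRS) generating a continuous outcome from the linear model
#' `y = alpha_j + beta'x + gamma_t'x + delta_jt + e`.  The defaults emulate a
#' rheumatoid-arthritis-like layout: three two-arm RCTs, two three-arm
#' registries covering all three treatments, nine baseline covariates, a
#' DAS28-like outcome on a 0-10 scale, registry treatment assignment that
#' depends on covariates (confounding), a lower registry intercept and
#' registry relative effects attenuated relative to the RCTs (the
#' efficacy-effectiveness gap).
#'
#' @param treatments treatment labels, reference first.
#' @param studies a data.frame with columns `study`, `design` (`"rct"`/
#'   `"nrs"`), `n`, and `arms` (list column of arm subsets).  Default: the
#'   RA-like five-study layout.
#' @param n_cov number of covariates (used only when `covariate_spec` is
#'   `NULL`).
#' @param covariate_spec data.frame with columns `name`, `type`
#'   (`"continuous"`/`"binary"`), `mean`, `sd` (continuous) and `prob`
#'   (binary).
#' @param cov_cor exchangeable correlation among continuous covariates.
#' @param alpha named vector of per-design intercepts `c(rct=, nrs=)`, or a
#'   per-study named vector.
#' @param beta main-effect (prognostic) coefficients, length `n_cov`.
#' @param gamma matrix of effect-modifier coefficients, `n_cov` rows, one
#'   column per non-reference treatment (zero matrix if no effect
#'   modification).
#' @param delta_rct named vector of relative effects versus the reference in
#'   RCTs, one entry per non-reference treatment.
#' @param gap additive shift applied to NRS relative effects:
#'   `delta_nrs = delta_rct + gap`.  A positive gap with negative
#'   `delta_rct` attenuates effects in routine care.
#' @param tau between-study standard deviation of the study-level relative
#'   effects around their design-specific mean.
#' @param sigma residual standard deviation.
#' @param confounding matrix (`n_cov` rows, one column per non-reference
#'   treatment) of multinomial-logit coefficients linking covariates to NRS
#'   treatment assignment; `NULL` disables confounding.
#' @param outcome_bounds length-2 numeric to clamp outcomes (e.g. `c(0,10)`),
#'   or `NULL` (default) for no clamping.  Clamping breaks linear-model truth
#'   and is off in all recovery checks.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_ipd()]
#' @export
sim_config <- function(treatments = c("dmards", "rtx", "tcz"),
                       studies = NULL,
                       n_cov = 9L,
                       covariate_spec = NULL,
                       cov_cor = 0.2,
                       alpha = c(rct = 4.0, nrs = 3.5),
                       beta = NULL,
                       gamma = NULL,
                       delta_rct = NULL,
                       gap = 0.3,
                       tau = 0,
                       sigma = 1.2,
                       confounding = NULL,
                       outcome_bounds = NULL) {
  if (is.null(studies)) {
    studies <- data.frame(
      study = c("rct1", "rct2", "rct3", "reg1", "reg2"),
      design = c("rct", "rct", "rct", "nrs", "nrs"),
      n = c(500L, 1200L, 800L, 2000L, 1000L),
      stringsAsFactors = FALSE)
    studies$arms <- list(treatments[c(1, 2)], treatments[c(1, 3)],
                         treatments[c(1, 3)], treatments, treatments)
  }
  if (is.null(covariate_spec)) {
    n_bin <- min(3L, n_cov)
    n_con <- n_cov - n_bin
    covariate_spec <- data.frame(
      name = paste0("x", seq_len(n_cov)),
      type = c(rep("continuous", n_con), rep("binary", n_bin)),
      mean = c(rep(0, n_con), rep(NA, n_bin)),
      sd = c(rep(1, n_con), rep(NA, n_bin)),
      prob = c(rep(NA, n_con), rep(0.5, n_bin)),
      stringsAsFactors = FALSE)
  }
  n_cov <- nrow(covariate_spec)
  K <- length(treatments)
  nonref <- treatments[-1]
  if (is.null(beta))
    beta <- round(seq(-0.3, 0.3, length.out = n_cov), 3)
  if (is.null(gamma))
    gamma <- matrix(0, n_cov, K - 1, dimnames = list(covariate_spec$name, nonref))
  if (is.null(dim(gamma)))
    gamma <- matrix(gamma, n_cov, K - 1, dimnames = list(covariate_spec$name, nonref))
  if (is.null(delta_rct))
    delta_rct <- stats::setNames(seq(-0.8, -1.1, length.out = K - 1), nonref)
  if (length(gap) == 1L) gap <- stats::setNames(rep(gap, K - 1), nonref)
  if (is.null(confounding)) {
    confounding <- matrix(0, n_cov, K - 1,
                          dimnames = list(covariate_spec$name, nonref))
    confounding[c(1, n_cov), ] <- 0.5  # sicker patients drawn to biologics
  }
  stopifnot(sigma > 0, tau >= 0, length(beta) == n_cov,
            nrow(gamma) == n_cov, ncol(gamma) == K - 1,
            length(delta_rct) == K - 1)
  for (a in studies$arms)
    if (!all(a %in% treatments))
      stop("study arm set not a subset of treatments: ",
           paste(a, collapse = ","))
  structure(list(treatments = treatments, studies = studies,
                 covariate_spec = covariate_spec, cov_cor = cov_cor,
                 alpha = alpha, beta = beta, gamma = gamma,
                 delta_rct = delta_rct, gap = gap, tau = tau, sigma = sigma,
                 confounding = confounding, outcome_bounds = outcome_bounds),
            class = "sim_config")
}

#' Simulate a multi-study IPD network
#'
#' Draws covariates per study, assigns treatment uniformly over the study's
#' arms in RCTs and by a covariate-dependent multinomial logit in NRS,
#' generates study-level relative effects around the design-specific mean
#' (RCT truth versus gap-shifted NRS truth) with between-study standard
#' deviation `tau`, and produces outcomes from the linear model with residual
#' standard deviation `sigma`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical config + seed gives identical tables.
#' @return An `ipd_set` with attribute `"truth"`: a list holding all
#'   generating parameters and the realized study-level effects
#'   (`delta_study`), for parameter-recovery checks.
#' @export
simulate_ipd <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cs <- config$covariate_spec
  p <- nrow(cs)
  trts <- config$treatments
  nonref <- trts[-1]
  K <- length(trts)
  is_con <- cs$type == "continuous"

  # correlated standard normals -> scaled continuous; thresholded binaries
  R <- matrix(config$cov_cor, p, p); diag(R) <- 1
  Rchol <- chol(R)

  delta_nrs <- config$delta_rct + config$gap[nonref]
  studies <- list(); design <- character(0)
  delta_study <- matrix(NA_real_, nrow(config$studies), K - 1,
                        dimnames = list(config$studies$study, nonref))
  for (j in seq_len(nrow(config$studies))) {
    srow <- config$studies[j, ]
    n <- srow$n
    arms <- srow$arms[[1]]
    des <- srow$design
    Z <- matrix(stats::rnorm(n * p), n, p) %*% Rchol
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, cs$name))
    for (k in seq_len(p)) {
      if (is_con[k]) X[, k] <- cs$mean[k] + cs$sd[k] * Z[, k]
      else X[, k] <- as.numeric(Z[, k] < stats::qnorm(cs$prob[k]))
    }

    if (des == "rct") {
      trt <- sample(arms, n, replace = TRUE)
    } else {
      # multinomial logit over this study's arms; reference has linear score 0
      eta <- matrix(0, n, length(arms))
      for (ai in seq_along(arms)) {
        a <- arms[ai]
        if (a != trts[1]) eta[, ai] <- X %*% config$confounding[, a]
      }
      pr <- exp(eta - apply(eta, 1, max))
      pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      cp <- t(apply(pr, 1, cumsum))
      trt <- arms[max.col(u < cp, ties.method = "first")]
    }

    d_mean <- if (des == "rct") config$delta_rct else delta_nrs
    d_j <- stats::rnorm(K - 1, d_mean, config$tau)
    names(d_j) <- nonref
    delta_study[j, ] <- d_j

    a_j <- if (!is.null(names(config$alpha)) &&
               srow$study %in% names(config$alpha))
      config$alpha[[srow$study]] else config$alpha[[des]]
    lp <- a_j + as.numeric(X %*% config$beta)
    for (w in nonref) {
      iw <- trt == w
      if (any(iw))
        lp[iw] <- lp[iw] + as.numeric(X[iw, , drop = FALSE] %*%
                                        config$gamma[, w]) + d_j[[w]]
    }
    y <- lp + stats::rnorm(n, 0, config$sigma)
    if (!is.null(config$outcome_bounds))
      y <- pmin(pmax(y, config$outcome_bounds[1]), config$outcome_bounds[2])

    df <- data.frame(patient = paste0(srow$study, "_", seq_len(n)),
                     treatment = trt, y = y, stringsAsFactors = FALSE)
    for (k in seq_len(p)) df[[cs$name[k]]] <- X[, k]
    studies[[srow$study]] <- df
    design[srow$study] <- des
  }
  ipd <- structure(list(studies = studies, design = design,
                        covariates = cs$name, treatments = sort(trts)),
                   class = "ipd_set")
  attr(ipd, "truth") <- list(alpha = config$alpha, beta = config$beta,
                             gamma = config$gamma,
                             delta_rct = config$delta_rct,
                             delta_nrs = delta_nrs,
                             delta_study = delta_study,
                             tau = config$tau, sigma = config$sigma,
                             config = config, seed = as.integer(seed))
  ipd
}

#' Set covariate cells missing, completely at random or at random
#'
#' Under `"mcar"` every covariate cell is masked independently with the given
#' rate.  Under `"mar"` the per-row masking probability of the target columns
#' depends on fully observed information only: the outcome and one designated
#' conditioning covariate (which is never masked itself), via a logistic
#' model calibrated so the marginal rate is approximately `rate`.  Outcomes
#' are never made missing.
#'
#' @param ipd an `ipd_set`.
#' @param rate target missingness rate in `[0, 1)`.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param condition_on covariate name driving MAR missingness (default: the
#'   first covariate).
#' @param mar_strength log-odds increment per standard deviation of the
#'   conditioning score under MAR.
#' @param seed integer seed.
#' @return The `ipd_set` with masked covariate cells (truth attribute
#'   preserved).
#' @export
inject_missingness <- function(ipd, rate, mechanism = c("mcar", "mar"),
                               condition_on = NULL, mar_strength = 1,
                               seed = 1L) {
  stopifnot(inherits(ipd, "ipd_set"), rate >= 0, rate < 1)
  mechanism <- match.arg(mechanism)
  if (rate == 0) return(ipd)
  set.seed(as.integer(seed))
  covs <- ipd$covariates
  if (is.null(condition_on)) condition_on <- covs[1]
  if (mechanism == "mar") {
    for (s in names(ipd$studies))
      if (anyNA(ipd$studies[[s]][[condition_on]]))
        stop("MAR conditioning column '", condition_on,
             "' has missing values in study '", s, "'")
  }
  target <- if (mechanism == "mar") setdiff(covs, condition_on) else covs
  for (s in names(ipd$studies)) {
    df <- ipd$studies[[s]]
    n <- nrow(df)
    if (mechanism == "mcar") {
      for (cv in target) {
        mask <- stats::runif(n) < rate
        df[[cv]][mask] <- NA_real_
      }
    } else {
      score <- scale(df$y + df[[condition_on]])[, 1]
      score[is.na(score)] <- 0
      # intercept solved so that mean prob ~= rate
      f <- function(b0) mean(stats::plogis(b0 + mar_strength * score)) - rate
      b0 <- stats::uniroot(f, c(-20, 20))$root
      pr <- stats::plogis(b0 + mar_strength * score)
      for (cv in target) {
        mask <- stats::runif(n) < pr
        df[[cv]][mask] <- NA_real_
      }
    }
    ipd$studies[[s]] <- df
  }
  ipd
}
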