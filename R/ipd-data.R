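#' Assemble a multi-study IPD set from a long patient-level table
#'
#' Validates and splits a long-format table of individual patient data (one
#' row per patient) into per-study tables sharing a common, ordered covariate
#' list.  Treatment and design labels are case-normalized so that, e.g.,
#' `"RCT"` and `"rct"` denote the same design and `"TCZ"`/`"tcz"` the same
#' arm.
#'
#' @param data a data.frame with one row per patient.
#' @param study,design,patient,treatment,outcome names of the columns holding
#'   the study identifier, study design (`"rct"` or `"nrs"`), patient
#'   identifier, treatment label and continuous outcome.
#' @param covariates character vector of covariate column names (continuous or
#'   binary; cells may be `NA`).  If `NULL`, every remaining column is used,
#'   in its original order.
#' @return An object of class `ipd_set`: a list with elements
#'   \describe{
#'     \item{studies}{named list of per-study data.frames with columns
#'       `patient`, `treatment`, `y` and the covariates,}
#'     \item{design}{named character vector (`"rct"`/`"nrs"`) per study,}
#'     \item{covariates}{the shared ordered covariate names,}
#'     \item{treatments}{sorted treatment labels present in the data.}
#'   }
#' @details Studies with a single treatment arm are rejected: the framework
#'   pools within-study contrasts and needs comparative studies.  Rows with a
#'   missing outcome are retained (they contribute to imputation models but
#'   are excluded from the regression likelihood).
#' @seealso [read_ipd()], [summarize_network()], [simulate_ipd()]
#' @export
as_ipd <- function(data, study = "study", design = "design",
                   patient = "patient", treatment = "treatment",
                   outcome = "y", covariates = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c(study, design, patient, treatment, outcome)
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("column(s) not found in data: ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(data), needed)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))

  des <- tolower(trimws(as.character(data[[design]])))
  bad <- setdiff(unique(des), c("rct", "nrs"))
  if (length(bad))
    stop("unknown design label(s): ", paste(bad, collapse = ", "),
         " (expected 'rct' or 'nrs')")
  y <- data[[outcome]]
  if (!is.numeric(y)) {
    yc <- suppressWarnings(as.numeric(as.character(y)))
    if (any(!is.na(y) & is.na(yc) & as.character(y) != "NA"))
      stop("outcome column '", outcome, "' is not numeric")
    y <- yc
  }
  for (cv in covariates) {
    if (!is.numeric(data[[cv]])) {
      xc <- suppressWarnings(as.numeric(as.character(data[[cv]])))
      if (any(!is.na(data[[cv]]) & is.na(xc) &
              as.character(data[[cv]]) != "NA"))
        stop("covariate '", cv, "' is not numeric")
      data[[cv]] <- xc
    }
  }

  sid <- as.character(data[[study]])
  trt <- tolower(trimws(as.character(data[[treatment]])))
  studies <- list()
  design_vec <- character(0)
  for (s in unique(sid)) {
    idx <- sid == s
    arms <- unique(trt[idx])
    if (length(arms) < 2L)
      stop("study '", s, "' has a single treatment arm; ",
           "only comparative studies are supported")
    d <- unique(des[idx])
    if (length(d) != 1L)
      stop("study '", s, "' has inconsistent design labels")
    df <- data.frame(patient = as.character(data[[patient]][idx]),
                     treatment = trt[idx], y = y[idx],
                     stringsAsFactors = FALSE)
    for (cv in covariates) df[[cv]] <- data[[cv]][idx]
    rownames(df) <- NULL
    studies[[s]] <- df
    design_vec[s] <- d
  }
  structure(list(studies = studies, design = design_vec,
                 covariates = covariates,
                 treatments = sort(unique(trt))),
            class = "ipd_set")
}

#' Read a multi-study IPD table from a delimited text file
#'
#' @param path path to a CSV file.
#' @param ... column mapping passed to [as_ipd()] (`study`, `design`,
#'   `patient`, `treatment`, `outcome`, `covariates`).
#' @param sep field separator, default `","`.
#' @return An `ipd_set`; see [as_ipd()].
#' @export
read_ipd <- function(path, ..., sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_ipd(df, ...)
}

#' Write an IPD set back to a single long CSV
#'
#' Inverse of [read_ipd()] up to column order; missing cells are written as
#' empty fields.
#'
#' @param ipd an `ipd_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "ipd_set"))
  rows <- lapply(names(ipd$studies), function(s) {
    df <- ipd$studies[[s]]
    cbind(data.frame(study = s, design = ipd$design[[s]],
                     stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = ",", row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' @export
print.ipd_set <- function(x, ...) {
  cat("IPD set:", length(x$studies), "studies,",
      sum(vapply(x$studies, nrow, 0L)), "patients\n")
  for (s in names(x$studies)) {
    df <- x$studies[[s]]
    cat(sprintf("  %-12s %s  n=%-5d arms: %s\n", s, toupper(x$design[[s]]),
                nrow(df), paste(sort(unique(df$treatment)), collapse = ", ")))
  }
  cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize the treatment network of a multi-study IPD set
#'
#' Builds the network whose nodes are treatments and whose edges are
#' within-study arm pairs, checks connectedness, and counts patients per
#' treatment.  The result is invariant to the ordering of studies and of
#' patients within a study.
#'
#' @param ipd an `ipd_set`.
#' @param reference the reference treatment label; if `NULL`,
#'   [choose_reference()] picks the arm with the most patients overall.
#' @return An object of class `network_summary` with elements `treatments`
#'   (reference first), `reference`, `arms` (per-study arm sets), `counts`
#'   (patients per treatment) and `connected`.
#' @export
summarize_network <- function(ipd, reference = NULL) {
  stopifnot(inherits(ipd, "ipd_set"))
  if (!length(ipd$studies)) stop("empty IPD set")
  arms <- lapply(ipd$studies, function(df) sort(unique(df$treatment)))
  trts <- sort(unique(unlist(arms)))
  counts <- vapply(trts, function(t)
    sum(vapply(ipd$studies, function(df) sum(df$treatment == t), 0L)), 0L)
  names(counts) <- trts

  # union-find over within-study arm pairs
  comp <- stats::setNames(seq_along(trts), trts)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (a in arms) {
    ids <- match(a, trts)
    r <- find(ids[1])
    for (i in ids[-1]) comp[find(i)] <- r
  }
  roots <- vapply(seq_along(trts), find, 0L)
  components <- split(trts, roots)
  connected <- length(components) == 1L
  if (!connected)
    stop("treatment network is disconnected; components: ",
         paste(vapply(components, paste, "", collapse = "+"),
               collapse = " | "))

  if (is.null(reference)) reference <- choose_reference(ipd)
  reference <- tolower(reference)
  if (!reference %in% trts)
    stop("reference treatment '", reference, "' absent from all studies")
  structure(list(treatments = c(reference, setdiff(trts, reference)),
                 reference = reference, arms = arms,
                 counts = counts, connected = connected),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Treatment network:", length(x$treatments), "treatments,",
      if (x$connected) "connected" else "DISCONNECTED", "\n")
  cat("  reference:", x$reference, "\n")
  cat("  patients per arm:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pick the default reference treatment
#'
#' Returns the treatment given to most patients across all studies, the usual
#' choice for the reference arm in this framework since the pooled intercept
#' is only informed by studies containing the reference.  Ties are broken by
#' lexicographic label order.
#'
#' @param ipd an `ipd_set`.
#' @return a treatment label.
#' @export
choose_reference <- function(ipd) {
  stopifnot(inherits(ipd, "ipd_set"), length(ipd$studies) > 0)
  trt <- unlist(lapply(ipd$studies, function(df) df$treatment))
  counts <- table(trt)
  names(counts)[which.max(counts)]  # which.max takes first on ties; table sorts labels
}
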