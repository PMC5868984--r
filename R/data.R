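#' Longitudinal monitoring dataset
#'
#' Constructs a validated long-format longitudinal dataset: one row per
#' observation, indexed by subject, with a group label, time in hours since
#' the alignment event (e.g. sleep onset), a real-valued response on the
#' analysis scale (e.g. log diastolic blood pressure), and optionally named
#' numeric covariate columns (binary covariates coded 0/1).
#'
#' Validation enforces: no duplicated (subject, time) pair, exactly one group
#' per subject, finite times and responses, and numeric, complete covariates
#' (missing covariate values are rejected, not imputed). Rows are sorted by
#' (subject, time). Group levels are recorded in order of first appearance
#' unless `group_levels` is supplied.
#'
#' @param df data frame holding the columns named below.
#' @param subject,group,time,response names of the id, group, time and
#'   response columns in `df`.
#' @param covariates character vector of covariate column names (may be empty).
#' @param group_levels optional character vector fixing the group level order;
#'   the first level is the default reference level for model indicators.
#' @return An object of class `sp_data`: a list with elements `data` (the
#'   canonicalised data frame with columns subject, group, time, response and
#'   covariates), `covariates`, and `groups` (level order).
#' @export
sp_data <- function(df, subject = "subject", group = "group", time = "time",
                    response = "response", covariates = character(),
                    group_levels = NULL) {
  needed <- c(subject, group, time, response, covariates)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    subject = as.character(df[[subject]]),
    group = as.character(df[[group]]),
    time = .as_numeric_checked(df[[time]], "time"),
    response = .as_numeric_checked(df[[response]], "response"),
    stringsAsFactors = FALSE
  )
  for (cv in covariates) {
    v <- .as_numeric_checked(df[[cv]], cv)
    if (anyNA(v)) stop("covariate '", cv, "' has missing values; imputation is not supported")
    out[[cv]] <- v
  }
  if (!all(is.finite(out$time))) stop("non-finite time values present")
  if (!all(is.finite(out$response))) stop("non-finite response values present")
  if (any(out$time < 0)) stop("negative times: time is hours since the alignment event")

  dup <- duplicated(out[, c("subject", "time")])
  if (any(dup)) {
    offenders <- unique(out[dup, c("subject", "time")])
    stop("duplicated (subject, time) pairs: ",
         paste(sprintf("(%s, %s)", offenders$subject, format(offenders$time)),
               collapse = ", "))
  }
  gps <- tapply(out$group, out$subject, function(g) length(unique(g)))
  if (any(gps > 1L)) {
    stop("subject(s) mapped to more than one group: ",
         paste(names(gps)[gps > 1L], collapse = ", "))
  }
  lv <- if (is.null(group_levels)) unique(out$group) else group_levels
  if (!all(out$group %in% lv)) {
    stop("group label(s) outside supplied levels: ",
         paste(setdiff(unique(out$group), lv), collapse = ", "))
  }
  out <- out[order(out$subject, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(data = out, covariates = covariates, groups = lv),
            class = "sp_data")
}

.as_numeric_checked <- function(x, what) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0L) {
    stop("non-numeric ", what, " value at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  v
}

#' Read a long-format longitudinal CSV
#'
#' Reads a header-ed CSV and validates it into an [sp_data] object. Column
#' names are configurable so device exports with arbitrary headers can be
#' mapped without editing the file.
#'
#' @param path path to an existing CSV file.
#' @inheritParams sp_data
#' @return An [sp_data] object sorted by (subject, time).
#' @seealso [write_long_csv()] for the inverse operation.
#' @export
read_long_csv <- function(path, subject = "subject", group = "group",
                          time = "time", response = "response",
                          covariates = character(), group_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sp_data(df, subject = subject, group = group, time = time,
          response = response, covariates = covariates,
          group_levels = group_levels)
}

#' Write a longitudinal dataset to CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_long_csv(write_long_csv(x))` round-trips every double exactly.
#'
#' @param x an [sp_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(x, path) {
  stopifnot(inherits(x, "sp_data"))
  df <- x$data
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
summary.sp_data <- function(object, ...) {
  d <- object$data
  subj_group <- tapply(d$group, d$subject, `[`, 1L)
  per_group <- table(factor(subj_group, levels = object$groups))
  obs_per_subject <- as.integer(table(d$subject)[unique(d$subject)])
  names(obs_per_subject) <- unique(d$subject)
  structure(list(
    n_subjects = length(unique(d$subject)),
    n_obs = nrow(d),
    group_sizes = per_group,
    obs_per_subject = obs_per_subject,
    time_range = range(d$time),
    covariates = object$covariates
  ), class = "summary.sp_data")
}

#' @export
print.summary.sp_data <- function(x, ...) {
  cat("Longitudinal dataset:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat("Subjects per group:\n")
  print(x$group_sizes)
  cat(sprintf("Time range: [%g, %g] hours\n", x$time_range[1], x$time_range[2]))
  cat(sprintf("Observations per subject: %d to %d\n",
              min(x$obs_per_subject), max(x$obs_per_subject)))
  if (length(x$covariates)) cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sp_data <- function(x, ...) {
  s <- summary(x)
  print(s)
  invisible(x)
}
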