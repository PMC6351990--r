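# Plain-text interchange: item bank CSV, response CSV (one row per
# respondent, QC columns prefixed "qc_"), demographics CSV, ability output
# CSV and a calibration report JSON.

#' Read / write an item bank CSV
#'
#' Columns \code{item_id}, \code{discrimination}, \code{difficulty},
#' \code{guessing} and optional \code{category}; header required, UTF-8,
#' decimal point.
#'
#' @param path file path.
#' @return \code{readItemBank}: an \linkS4class{ItemBank}.
#' @export
readItemBank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  itemBank(df$item_id, df$discrimination, df$difficulty, df$guessing,
           category = if ("category" %in% names(df)) df$category else NULL)
}

#' @rdname readItemBank
#' @param bank an \linkS4class{ItemBank}.
#' @export
writeItemBank <- function(bank, path) {
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a response CSV
#'
#' One row per respondent: a \code{respondent_id} column followed by one
#' 0/1/blank column per item; QC item columns carry the \code{qc_} prefix.
#'
#' @param path file path.
#' @return \code{readResponses}: a respondents x items numeric matrix
#'   (NA for blanks) with respondent ids as rownames.
#' @export
readResponses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "respondent_id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$respondent_id
  m
}

#' @rdname readResponses
#' @param responses respondents x items matrix with dimnames.
#' @export
writeResponses <- function(responses, path) {
  df <- data.frame(respondent_id = rownames(responses), responses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a demographics CSV
#'
#' \code{respondent_id}, \code{arm}, the five demographic columns and, for
#' simulated cohorts, \code{latent_theta}.
#'
#' @param path file path.
#' @return \code{readDemographics}: a respondent-profile data.frame.
#' @export
readDemographics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readDemographics
#' @param profiles respondent-profile data.frame.
#' @export
writeDemographics <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Write per-respondent ability estimates to CSV
#'
#' @param abilities data.frame from \code{\link{estimateAbilities}}.
#' @param path file path.
#' @export
writeAbilities <- function(abilities, path) {
  utils::write.csv(abilities, path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration report (trace, flags, filter audit) as JSON
#'
#' @param calib a \linkS4class{CalibrationResult}.
#' @param path file path.
#' @param audit optional filter audit data.frame from
#'   \code{\link{filterItemBank}}.
#' @export
writeCalibrationReport <- function(calib, path, audit = NULL) {
  rep <- list(
    n_iterations = calib@nIterations,
    converged = emConverged(calib),
    log_likelihood_trace = logLikTrace(calib),
    degenerate_items = itemFlags(calib),
    items = as.data.frame(calibratedItems(calib))
  )
  if (!is.null(audit)) rep$filter_audit <- audit
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
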