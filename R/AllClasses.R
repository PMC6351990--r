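#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.DISEASE_CATEGORIES <- c(
  "heart failure", "hypertension", "diabetes",
  "COPD", "liver failure", "cancer"
)

#' ItemBank: 3PL parameters for a set of test items
#'
#' Container for the item side of a three-parameter logistic (3PL) item
#' response model: per item a positive discrimination (logit slope per unit
#' of latent ability), a difficulty on the ability scale (the ability at
#' which the logistic component of the response probability is 1/2) and a
#' guessing lower asymptote in [0, 1).  Items may optionally carry one of
#' the six disease categories the comprehension test spans.
#'
#' @slot items data.frame with columns \code{item_id}, \code{discrimination},
#'   \code{difficulty}, \code{guessing} and optionally \code{category}.
#' @export
setClass("ItemBank", representation(items = "data.frame"))

setValidity("ItemBank", function(object) {
  df <- object@items
  req <- c("item_id", "discrimination", "difficulty", "guessing")
  if (!all(req %in% names(df)))
    return(paste("missing columns:", paste(setdiff(req, names(df)), collapse = ", ")))
  if (nrow(df) == 0)
    return("item bank must contain at least one item")
  if (anyDuplicated(df$item_id))
    return("item_id values must be distinct")
  if (!all(is.finite(df$discrimination)) || any(df$discrimination <= 0))
    return("discrimination must be finite and > 0")
  if (!all(is.finite(df$difficulty)))
    return("difficulty must be finite")
  if (any(df$guessing < 0 | df$guessing >= 1))
    return("guessing must lie in [0, 1)")
  if ("category" %in% names(df)) {
    cat <- as.character(df$category)
    bad <- !is.na(cat) & !(cat %in% .DISEASE_CATEGORIES)
    if (any(bad))
      return(paste("unknown category:", paste(unique(cat[bad]), collapse = ", ")))
  }
  TRUE
})

#' Construct an ItemBank
#'
#' @param item_id character vector of distinct item identifiers.
#' @param discrimination positive numeric vector (a parameters).
#' @param difficulty numeric vector on the latent ability scale (b).
#' @param guessing numeric vector in [0, 1) (c); recycled if scalar.
#' @param category optional character vector of disease categories (or NA).
#' @return An \linkS4class{ItemBank}.
#' @examples
#' itemBank(c("q1", "q2"), c(1, 1.5), c(-1, 0.5), 0.25)
#' @export
itemBank <- function(item_id, discrimination, difficulty, guessing = 0.25,
                     category = NULL) {
  n <- length(item_id)
  df <- data.frame(
    item_id = as.character(item_id),
    discrimination = rep_len(as.numeric(discrimination), n),
    difficulty = rep_len(as.numeric(difficulty), n),
    guessing = rep_len(as.numeric(guessing), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(category)) df$category <- rep_len(as.character(category), n)
  new("ItemBank", items = df)
}

#' @describeIn ItemBank number of items in the bank
#' @param x,object an \code{ItemBank}
#' @export
setMethod("length", "ItemBank", function(x) nrow(x@items))

setMethod("show", "ItemBank", function(object) {
  df <- object@items
  cat(sprintf("ItemBank with %d item(s)\n", nrow(df)))
  cat(sprintf("  discrimination: [%.3g, %.3g]\n",
              min(df$discrimination), max(df$discrimination)))
  cat(sprintf("  difficulty:     [%.3g, %.3g]\n",
              min(df$difficulty), max(df$difficulty)))
  cat(sprintf("  guessing:       %s\n",
              paste(format(unique(df$guessing)), collapse = ", ")))
  if ("category" %in% names(df))
    cat(sprintf("  categories:     %d distinct\n",
                length(unique(stats::na.omit(df$category)))))
})

#' @export
setMethod("as.data.frame", "ItemBank", function(x, ...) x@items)

setMethod("[", "ItemBank", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@items$item_id)
  new("ItemBank", items = x@items[i, , drop = FALSE])
})

#' @rdname itemBank
#' @export
itemIds <- function(x) x@items$item_id

#' @rdname itemBank
#' @export
discrimination <- function(x) stats::setNames(x@items$discrimination, x@items$item_id)

#' @rdname itemBank
#' @export
difficulty <- function(x) stats::setNames(x@items$difficulty, x@items$item_id)

#' @rdname itemBank
#' @export
guessing <- function(x) stats::setNames(x@items$guessing, x@items$item_id)

#' @rdname itemBank
#' @export
itemCategories <- function(x) {
  if ("category" %in% names(x@items))
    stats::setNames(x@items$category, x@items$item_id)
  else stats::setNames(rep(NA_character_, nrow(x@items)), x@items$item_id)
}

#' ComprehensionStudy: responses plus item and respondent annotation
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one comprehension
#' study: a dichotomous response assay (items as rows, respondents as
#' columns, entries 0/1/NA), item annotation in \code{rowData} (a logical
#' \code{qc} column marking attention-check items, plus 3PL parameters for
#' scored items) and respondent annotation in \code{colData} (arm
#' assignment, demographics and, for simulated cohorts, the generating
#' latent ability).
#'
#' @export
setClass("ComprehensionStudy", contains = "SummarizedExperiment")

setValidity("ComprehensionStudy", function(object) {
  if (!"responses" %in% SummarizedExperiment::assayNames(object))
    return("assay 'responses' is required")
  v <- SummarizedExperiment::assay(object, "responses")
  if (!all(v %in% c(0, 1, NA)))
    return("responses must be 0, 1 or NA")
  if (!"qc" %in% names(rowData(object)))
    return("rowData must contain a logical 'qc' column")
  TRUE
})

#' Construct a ComprehensionStudy
#'
#' @param responses numeric matrix of 0/1/NA values, items x respondents,
#'   with dimnames.
#' @param itemData DataFrame/data.frame of per-item annotation; must contain
#'   a logical \code{qc} column (attention-check flag).
#' @param respondentData DataFrame/data.frame of per-respondent annotation.
#' @param metadata list of study-level metadata (e.g. the generating truth).
#' @return A \linkS4class{ComprehensionStudy}.
#' @export
comprehensionStudy <- function(responses, itemData, respondentData,
                               metadata = list()) {
  se <- SummarizedExperiment(
    assays = list(responses = responses),
    rowData = itemData, colData = respondentData, metadata = metadata
  )
  new("ComprehensionStudy", se)
}

#' @rdname comprehensionStudy
#' @param x a \code{ComprehensionStudy}
#' @export
responses <- function(x) SummarizedExperiment::assay(x, "responses")

#' @rdname comprehensionStudy
#' @export
qcItemIds <- function(x) rownames(x)[rowData(x)$qc]

#' @rdname comprehensionStudy
#' @export
scoredItemIds <- function(x) rownames(x)[!rowData(x)$qc]

#' Extract the scored-item bank carried in a study's rowData
#'
#' @param x a \code{ComprehensionStudy} whose rowData carries 3PL columns.
#' @return An \linkS4class{ItemBank} for the non-QC items.
#' @export
studyItemBank <- function(x) {
  rd <- as.data.frame(rowData(x))
  rd <- rd[!rd$qc, , drop = FALSE]
  itemBank(rownames(rd), rd$discrimination, rd$difficulty, rd$guessing,
           category = if ("category" %in% names(rd)) rd$category else NULL)
}

setMethod("show", "ComprehensionStudy", function(object) {
  cat(sprintf("ComprehensionStudy: %d items (%d QC) x %d respondents\n",
              nrow(object), sum(rowData(object)$qc), ncol(object)))
  if ("arm" %in% names(colData(object))) {
    tb <- table(colData(object)$arm)
    cat("  arms:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  callNextMethod()
})

#' CalibrationResult: fitted 3PL item parameters from MML-EM
#'
#' Result of marginal maximum-likelihood (EM) calibration of a fixed-guessing
#' 3PL model: the estimated item bank, the per-iteration marginal
#' log-likelihood trace (non-decreasing up to numerical slack), convergence
#' status and per-item degeneracy flags.
#'
#' @slot items estimated \linkS4class{ItemBank} (guessing fixed).
#' @slot logLikTrace numeric, marginal log likelihood per EM iteration.
#' @slot converged logical.
#' @slot nIterations integer.
#' @slot flags character, ids of items with degenerate response columns.
#' @slot nRespondents integer.
#' @export
setClass("CalibrationResult", representation(
  items = "ItemBank", logLikTrace = "numeric", converged = "logical",
  nIterations = "integer", flags = "character", nRespondents = "integer"
))

setValidity("CalibrationResult", function(object) {
  g <- guessing(object@items)
  if (length(unique(g)) != 1)
    return("guessing must be identical (fixed) across calibrated items")
  tr <- object@logLikTrace
  if (length(tr) > 1 && any(diff(tr) < -1e-8))
    return("marginal log-likelihood trace must be non-decreasing")
  TRUE
})

#' @rdname CalibrationResult-class
#' @param x,object a \code{CalibrationResult}
#' @export
calibratedItems <- function(x) x@items

#' @rdname CalibrationResult-class
#' @export
logLikTrace <- function(x) x@logLikTrace

#' @rdname CalibrationResult-class
#' @export
emConverged <- function(x) x@converged

#' @rdname CalibrationResult-class
#' @export
itemFlags <- function(x) x@flags

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %d items, %d respondents\n",
              length(object@items), object@nRespondents))
  cat(sprintf("  EM iterations: %d (converged: %s)\n",
              object@nIterations, object@converged))
  cat(sprintf("  marginal logLik: %.4f\n", utils::tail(object@logLikTrace, 1)))
  if (length(object@flags))
    cat("  degenerate items:", paste(object@flags, collapse = ", "), "\n")
})

#' ArmComparison: per-arm summaries with Welch tests against baseline
#'
#' @slot summary data.frame of per-arm descriptive statistics for raw scores
#'   and ability estimates (n, mean, quartiles, whisker extremes).
#' @slot tests data.frame of Welch two-sample comparisons of each treatment
#'   arm against baseline, for both metrics.
#' @slot alpha numeric significance level.
#' @slot baseline character, name of the reference arm.
#' @export
setClass("ArmComparison", representation(
  summary = "data.frame", tests = "data.frame",
  alpha = "numeric", baseline = "character"
))

setValidity("ArmComparison", function(object) {
  p <- object@tests$p_value
  if (length(p) && (any(p < 0) || any(p > 1))) return("p values must lie in [0,1]")
  s <- object@summary
  if (nrow(s) && any(s$q1 > s$median | s$median > s$q3))
    return("quartiles must be ordered")
  TRUE
})

#' @rdname ArmComparison-class
#' @param x,object an \code{ArmComparison}
#' @export
armSummary <- function(x) x@summary

#' @rdname ArmComparison-class
#' @export
armTests <- function(x) x@tests

setMethod("show", "ArmComparison", function(object) {
  cat("Arm comparison (Welch two-sample t tests vs", object@baseline,
      "at alpha =", object@alpha, ")\n")
  s <- object@summary
  for (m in unique(s$metric)) {
    cat(sprintf("\n  %s:\n", m))
    sm <- s[s$metric == m, ]
    for (i in seq_len(nrow(sm)))
      cat(sprintf("    %-10s n=%2d  mean=%7.3f  median=%7.3f\n",
                  sm$arm[i], sm$n[i], sm$mean[i], sm$median[i]))
  }
  t <- object@tests
  cat("\n  tests vs baseline:\n")
  for (i in seq_len(nrow(t)))
    cat(sprintf("    %-10s %-10s t=%7.3f df=%6.2f p=%.4f%s\n",
                t$arm[i], t$metric[i], t$t[i], t$df[i], t$p_value[i],
                ifelse(t$significant[i], " *", "")))
})

#' RegressionResult: OLS fit of scores on demographics and arm
#'
#' @slot coefficients data.frame with term, estimate, se, t and two-sided p.
#' @slot n integer, respondents used.
#' @slot residualDf integer.
#' @slot rSquared numeric.
#' @slot reference named character, reference level per categorical variable.
#' @slot notes character, e.g. variables dropped as constant in the cohort.
#' @export
setClass("RegressionResult", representation(
  coefficients = "data.frame", n = "integer", residualDf = "integer",
  rSquared = "numeric", reference = "character", notes = "character"
))

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: n=%d, residual df=%d, R^2=%.3f\n",
              object@n, object@residualDf, object@rSquared))
  cf <- object@coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-35s %8.4f (se %.4f)  t=%7.3f  p=%.4f\n",
                cf$term[i], cf$estimate[i], cf$se[i], cf$t[i], cf$p_value[i]))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @rdname RegressionResult-class
#' @param x a \code{RegressionResult}
#' @export
regressionCoefficients <- function(x) x@coefficients
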