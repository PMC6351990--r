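# End-to-end analysis of a (real or simulated) three-arm comprehension
# study: QC filtering, raw scoring, ability estimation, arm comparison with
# Welch tests, demographic tabulation, score regression and extreme-item
# reporting.

#' Remove respondents who failed any quality-control item
#'
#' A respondent is retained only if every designated QC (attention-check)
#' item was answered correctly; a missing QC response counts as a failure.
#' QC columns are dropped from the returned scored data.  Applying the
#' filter twice equals applying it once.
#'
#' @param x a \linkS4class{ComprehensionStudy}, or a respondents x items
#'   matrix whose QC columns are named with the \code{qc_} prefix.
#' @param qc_prefix prefix identifying QC columns in matrix input.
#' @return For a study: the filtered \code{ComprehensionStudy} (QC rows
#'   dropped; removal report in \code{metadata(x)$qc_report}).  For a
#'   matrix: \code{list(responses, report)}.  The report lists each removed
#'   respondent with its count of failed QC items.
#' @export
applyQCFilter <- function(x, qc_prefix = "qc_") {
  if (is(x, "ComprehensionStudy")) {
    qc_ids <- qcItemIds(x)
    if (length(qc_ids) == 0)
      stop("no QC items designated: cannot apply the quality-control filter")
    qc <- t(responses(x)[qc_ids, , drop = FALSE])
    fails <- rowSums(qc != 1 | is.na(qc))
    keep <- fails == 0
    out <- x[scoredItemIds(x), keep]
    report <- data.frame(respondent_id = colnames(x)[!keep],
                         n_qc_failed = unname(fails[!keep]),
                         stringsAsFactors = FALSE)
    md <- metadata(out)
    md$qc_report <- report
    metadata(out) <- md
    return(out)
  }
  qc_cols <- grep(paste0("^", qc_prefix), colnames(x), value = TRUE)
  if (length(qc_cols) == 0)
    stop("no QC items designated: cannot apply the quality-control filter")
  qc <- x[, qc_cols, drop = FALSE]
  fails <- rowSums(qc != 1 | is.na(qc))
  keep <- fails == 0
  list(responses = x[keep, setdiff(colnames(x), qc_cols), drop = FALSE],
       report = data.frame(respondent_id = rownames(x)[!keep],
                           n_qc_failed = unname(fails[!keep]),
                           stringsAsFactors = FALSE))
}

#' Raw test scores (proportion correct)
#'
#' Per-respondent proportion of scored, non-missing responses answered
#' correctly.
#'
#' @param x a \linkS4class{ComprehensionStudy} (QC items excluded) or a
#'   respondents x items 0/1/NA matrix.
#' @return Named numeric vector in [0, 1].
#' @export
rawScores <- function(x) {
  if (is(x, "ComprehensionStudy"))
    x <- t(responses(x)[scoredItemIds(x), , drop = FALSE])
  nobs <- rowSums(!is.na(x))
  if (any(nobs == 0))
    stop("respondent(s) with no scored responses: ",
         paste(rownames(x)[nobs == 0], collapse = ", "))
  rowSums(x, na.rm = TRUE) / nobs
}

#' Welch two-sample t test
#'
#' Mean-difference test without assuming equal variances, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param x,y numeric samples with at least 2 finite values each and
#'   positive pooled spread.
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{mean_x},
#'   \code{mean_y}.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 || !all(is.finite(c(x, y))))
    stop("each sample needs >= 2 finite values")
  if (stats::var(x) + stats::var(y) == 0)
    stop("degenerate samples: both have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

.box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lw <- min(v[v >= q[1] - 1.5 * iqr])  # Tukey lower whisker
  uw <- max(v[v <= q[3] + 1.5 * iqr])
  c(mean = mean(v), q1 = q[1], median = q[2], q3 = q[3],
    min = min(v), max = max(v), whisker_low = lw, whisker_high = uw)
}

#' Compare treatment arms against baseline
#'
#' Produces per-arm descriptive statistics (mean, quartiles, Tukey box
#' whiskers) for raw scores and ability estimates, plus Welch two-sample
#' tests of each treatment arm against the baseline arm on both metrics.
#' By default p values are reported per comparison, unadjusted; an optional
#' multiplicity correction is available.
#'
#' @param raw_scores named numeric vector of raw scores.
#' @param abilities named numeric vector of ability estimates, aligned with
#'   \code{raw_scores}.
#' @param arms factor/character of arm labels aligned with the scores.
#' @param alpha significance level (default 0.05).
#' @param baseline reference arm name (default \code{"baseline"}).
#' @param adjust p-value adjustment across the treatment-arm comparisons of
#'   each metric: \code{"none"} (default), \code{"bonferroni"} or
#'   \code{"holm"}.
#' @return An \linkS4class{ArmComparison}.
#' @export
compareArms <- function(raw_scores, abilities, arms, alpha = 0.05,
                        baseline = "baseline", adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  arms <- as.character(arms)
  if (!baseline %in% arms) stop("missing arm: ", baseline)
  stopifnot(length(raw_scores) == length(arms),
            length(abilities) == length(arms))
  lv <- unique(arms)
  if (any(table(arms) < 2)) stop("every arm needs >= 2 respondents")
  metrics <- list(raw_score = raw_scores, ability = abilities)
  summ <- do.call(rbind, lapply(names(metrics), function(m) {
    do.call(rbind, lapply(lv, function(g) {
      v <- metrics[[m]][arms == g]
      data.frame(metric = m, arm = g, n = length(v), t(.box_stats(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  treat <- setdiff(lv, baseline)
  # zero-spread arms (e.g. identical constant scores) have no Welch
  # statistic; equal means are reported as a null result, not an error
  welch_safe <- function(x, y) {
    if (stats::var(x) + stats::var(y) == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2,
                  p_value = if (eq) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    welchTest(x, y)
  }
  tests <- do.call(rbind, lapply(names(metrics), function(m) {
    rows <- lapply(treat, function(g) {
      wt <- welch_safe(metrics[[m]][arms == g], metrics[[m]][arms == baseline])
      data.frame(metric = m, arm = g, t = wt$t, df = wt$df,
                 p_value = wt$p_value, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_adjusted <- stats::p.adjust(df$p_value, method = adjust)
    df
  }))
  tests$significant <- tests$p_adjusted < alpha
  rownames(summ) <- rownames(tests) <- NULL
  new("ArmComparison", summary = summ, tests = tests, alpha = alpha,
      baseline = baseline)
}

.round_half_up <- function(x) floor(x + 0.5)

#' Demographic counts table with integer percentages
#'
#' Per demographic variable, category and arm: the count and the percentage
#' of the arm total (rounded half-up to an integer), formatted
#' \code{"n (p)"}, plus a totals column over all arms.  Categories present
#' in the factor levels but unobserved appear as \code{"0 (0)"}.
#'
#' @param profiles respondent data.frame with \code{arm} and categorical
#'   demographic columns.
#' @param variables demographic columns to tabulate (default: the five
#'   standard ones present).
#' @return data.frame with columns \code{variable}, \code{category}, one
#'   formatted column per arm and \code{Total}.
#' @export
demographicsTable <- function(profiles,
                              variables = intersect(
                                c("gender", "age_band", "ethnicity",
                                  "education", "occupation"),
                                names(profiles))) {
  if (nrow(profiles) == 0) stop("empty cohort")
  arms <- unique(as.character(profiles$arm))
  arm_n <- table(factor(profiles$arm, levels = arms))
  total_n <- nrow(profiles)
  fmt <- function(count, denom)
    sprintf("%d (%d)", count,
            if (denom > 0) .round_half_up(100 * count / denom) else 0)
  rows <- lapply(variables, function(v) {
    f <- profiles[[v]]
    cats <- if (is.factor(f)) levels(f) else unique(as.character(f))
    do.call(rbind, lapply(cats, function(cc) {
      row <- data.frame(variable = v, category = cc, stringsAsFactors = FALSE)
      for (g in arms) {
        cnt <- sum(profiles$arm == g & as.character(f) == cc)
        row[[g]] <- fmt(cnt, arm_n[[g]])
      }
      row$Total <- fmt(sum(as.character(f) == cc), total_n)
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' OLS regression of scores on demographics and arm
#'
#' Ordinary least squares with dummy-coded categorical predictors and
#' explicit reference levels (defaults: baseline arm and the largest
#' observed demographic categories).  Variables constant in the cohort are
#' dropped with a recorded note; genuine aliasing among remaining dummies
#' raises an error listing the aliased terms rather than silently dropping
#' them.
#'
#' @param scores numeric outcome per respondent.
#' @param profiles respondent data.frame (arm + demographics), rows aligned
#'   with \code{scores}.
#' @param reference named character vector of reference levels per
#'   variable.
#' @param variables predictor columns (default arm + the five demographics
#'   present).
#' @return A \linkS4class{RegressionResult}.
#' @export
fitScoreRegression <- function(scores, profiles,
                               reference = c(arm = "baseline", gender = "Male",
                                             age_band = "22-34",
                                             ethnicity = "White",
                                             education = "Bachelors",
                                             occupation = "Other profession"),
                               variables = intersect(
                                 c("arm", "gender", "age_band", "ethnicity",
                                   "education", "occupation"),
                                 names(profiles))) {
  stopifnot(length(scores) == nrow(profiles))
  df <- data.frame(.score = scores)
  notes <- character(0)
  used <- character(0)
  for (v in variables) {
    f <- droplevels(factor(profiles[[v]]))
    if (nlevels(f) < 2) {
      notes <- c(notes, paste0("dropped constant variable '", v, "'"))
      next
    }
    if (!is.na(reference[v]) && reference[v] %in% levels(f))
      f <- stats::relevel(f, ref = unname(reference[v]))
    df[[v]] <- f
    used <- c(used, v)
  }
  if (length(used) == 0) stop("no non-constant predictors available")
  fit <- stats::lm(stats::reformulate(used, response = ".score"), data = df)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p_value = cf[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  ref_used <- reference[intersect(names(reference), used)]
  new("RegressionResult", coefficients = out, n = nrow(df),
      residualDf = as.integer(fit$df.residual), rSquared = sm$r.squared,
      reference = ref_used, notes = notes)
}

#' Report the easiest and hardest items by observed percent correct
#'
#' Selects the k items most often and least often answered correctly
#' (column percent-correct over non-missing responses) and pairs each with
#' its calibrated difficulty parameter — items rarely answered correctly
#' should carry the higher difficulties.  Ties are broken by item-id order.
#'
#' @param x a \linkS4class{ComprehensionStudy} or respondents x items
#'   matrix (scored items only).
#' @param items \linkS4class{ItemBank} supplying difficulties (defaults to
#'   the study's bank).
#' @param k number of items per extreme (2k must not exceed the bank size).
#' @return list with data.frames \code{easiest} and \code{hardest}
#'   (item_id, percent_correct, difficulty), each sorted from more to less
#'   extreme.
#' @export
extremeItemsReport <- function(x, items = NULL, k = 2) {
  if (is(x, "ComprehensionStudy")) {
    if (is.null(items)) items <- studyItemBank(x)
    x <- t(responses(x)[scoredItemIds(x), , drop = FALSE])
  }
  if (is.null(items)) stop("'items' is required for matrix input")
  if (k < 1 || 2 * k > ncol(x))
    stop("'k' must satisfy 1 <= k and 2k <= number of items")
  pct <- 100 * colSums(x == 1, na.rm = TRUE) / colSums(!is.na(x))
  b <- difficulty(items)[colnames(x)]
  ord <- order(-pct, colnames(x))          # ties: item_id order
  mk <- function(idx) {
    d <- data.frame(item_id = colnames(x)[idx],
                    percent_correct = unname(pct[idx]),
                    difficulty = unname(b[idx]), stringsAsFactors = FALSE)
    rownames(d) <- NULL
    d
  }
  list(easiest = mk(utils::head(ord, k)), hardest = mk(rev(utils::tail(ord, k))))
}

#' Run the full study analysis
#'
#' QC filtering, raw scoring, ability estimation (MLE with EAP fallback),
#' arm comparison with Welch tests, demographic tabulation, score
#' regression and the extreme-item report, in one call.
#'
#' @param study a \linkS4class{ComprehensionStudy} with QC items and arm
#'   annotation.
#' @param items \linkS4class{ItemBank} (default: the study's own bank).
#' @param alpha significance level for arm comparisons.
#' @param k extreme items per tail.
#' @param ... passed to \code{\link{estimateAbilities}}.
#' @return list of class \code{studyAnalysis}: \code{qc_report},
#'   \code{raw_scores}, \code{abilities}, \code{arm_comparison},
#'   \code{demographics}, \code{regression}, \code{extreme_items},
#'   \code{n_retained}.
#' @export
runStudyAnalysis <- function(study, items = NULL, alpha = 0.05, k = 2, ...) {
  stopifnot(is(study, "ComprehensionStudy"))
  if (is.null(items)) items <- studyItemBank(study)
  filtered <- applyQCFilter(study)
  scores <- rawScores(filtered)
  abil <- estimateAbilities(filtered, items, ...)
  profiles <- as.data.frame(colData(filtered))
  profiles$respondent_id <- colnames(filtered)
  cmp <- compareArms(scores, stats::setNames(abil$theta, abil$respondent_id),
                     profiles$arm, alpha = alpha)
  reg <- fitScoreRegression(scores, profiles)
  structure(list(
    qc_report = metadata(filtered)$qc_report,
    raw_scores = scores,
    abilities = abil,
    arm_comparison = cmp,
    demographics = demographicsTable(profiles),
    regression = reg,
    extreme_items = extremeItemsReport(filtered, items, k = k),
    n_retained = ncol(filtered)
  ), class = "studyAnalysis")
}

#' @export
print.studyAnalysis <- function(x, ...) {
  cat(sprintf("Study analysis: %d respondents retained after QC (%d removed)\n",
              x$n_retained, nrow(x$qc_report)))
  show(x$arm_comparison)
  invisible(x)
}
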