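# Per-respondent ability (theta) estimation: maximum likelihood over a
# bounded search interval, with expected-a-posteriori (EAP) scoring as the
# finite fallback for boundary (all-correct / all-incorrect) patterns.

.ability_row <- function(id, theta, se, method, converged, boundary, ll) {
  data.frame(respondent_id = id, theta = theta, se = se, method = method,
             converged = converged, boundary_flag = boundary,
             log_likelihood = ll, stringsAsFactors = FALSE)
}

.pattern_se <- function(items, theta, idx) {
  info <- sum(itemInformation(items, theta)[idx])
  if (info > 0) 1 / sqrt(info) else NA_real_
}

#' Maximum-likelihood ability estimate
#'
#' Maximises the 3PL pattern log likelihood over a bounded interval.
#' Patterns with every scored response correct (or every one incorrect)
#' have no interior maximum; these are flagged and handled by the
#' configured fallback — EAP scoring under a standard-normal prior
#' (default), or clamping to the interval endpoint — never silently.
#'
#' @param responses 0/1/NA vector named by item id (see
#'   \code{\link{patternLogLik}}).
#' @param items an \linkS4class{ItemBank}.
#' @param interval length-2 numeric search interval (default \code{c(-4, 4)},
#'   covering ±4 SD of a standard-normal trait).
#' @param tol optimizer tolerance (default 1e-6).
#' @param boundary fallback for boundary patterns: \code{"eap"} or
#'   \code{"clamp"}.
#' @param respondent_id identifier recorded in the output row.
#' @return One-row data.frame: \code{respondent_id}, \code{theta}, \code{se}
#'   (from expected Fisher information at the estimate), \code{method},
#'   \code{converged}, \code{boundary_flag}, \code{log_likelihood}.
#' @examples
#' bank <- itemBank(c("q1", "q2"), 1, c(-1, 1), 0)
#' estimateAbilityMLE(c(q1 = 1, q2 = 0), bank)$theta  # 0 by symmetry
#' @export
estimateAbilityMLE <- function(responses, items, interval = c(-4, 4),
                               tol = 1e-6, boundary = c("eap", "clamp"),
                               respondent_id = NA_character_) {
  boundary <- match.arg(boundary)
  pr <- .bank_params(items)
  if (length(interval) != 2 || interval[1] >= interval[2])
    stop("'interval' must be an ordered pair")
  m <- .match_pattern(responses, pr)
  if (all(m$u == 1) || all(m$u == 0)) {
    if (boundary == "clamp") {
      theta <- if (all(m$u == 1)) interval[2] else interval[1]
      est <- .ability_row(respondent_id, theta,
                         .pattern_se(items, theta, m$idx), "MLE", TRUE, TRUE,
                         patternLogLik(responses, items, theta))
    } else {
      est <- estimateAbilityEAP(responses, items,
                                respondent_id = respondent_id)
      est$boundary_flag <- TRUE
    }
    return(est)
  }
  opt <- stats::optimize(function(th) patternLogLik(responses, items, th),
                         interval = interval, maximum = TRUE, tol = tol)
  theta <- opt$maximum
  .ability_row(respondent_id, theta, .pattern_se(items, theta, m$idx),
               "MLE", TRUE, FALSE, opt$objective)
}

#' Expected-a-posteriori ability estimate
#'
#' Posterior mean of ability under a normal prior, computed on a fixed
#' equally spaced quadrature grid with normal-density weights; finite for
#' every response pattern, including all-correct and all-incorrect ones.
#' The reported standard error is the posterior standard deviation.
#'
#' @inheritParams estimateAbilityMLE
#' @param prior_mean,prior_sd normal prior on ability (default standard
#'   normal, matching the latent scale of the calibration).
#' @param n_nodes number of quadrature nodes (>= 21; default 61) spanning
#'   \code{prior_mean} ± 4 \code{prior_sd}.
#' @return One-row data.frame as in \code{\link{estimateAbilityMLE}} with
#'   \code{method = "EAP"}.
#' @export
estimateAbilityEAP <- function(responses, items, prior_mean = 0,
                               prior_sd = 1, n_nodes = 61,
                               respondent_id = NA_character_) {
  if (n_nodes < 21) stop("'n_nodes' must be >= 21")
  if (!is.numeric(prior_sd) || prior_sd <= 0) stop("'prior_sd' must be > 0")
  pr <- .bank_params(items)
  m <- .match_pattern(responses, pr)
  grid <- seq(prior_mean - 4 * prior_sd, prior_mean + 4 * prior_sd,
              length.out = n_nodes)
  logw <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  ll <- vapply(grid, function(th) {
    p <- .p3pl(pr$a[m$idx], pr$b[m$idx], pr$c[m$idx], th)
    sum(m$u * log(p) + (1 - m$u) * log1p(-p))
  }, numeric(1))
  lp <- ll + logw
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  theta <- sum(w * grid)
  psd <- sqrt(sum(w * (grid - theta)^2))
  .ability_row(respondent_id, theta, psd, "EAP", TRUE,
               all(m$u == 1) || all(m$u == 0),
               patternLogLik(responses, items, theta))
}

#' Estimate abilities for a whole response matrix or study
#'
#' Applies \code{\link{estimateAbilityMLE}} (with its EAP fallback for
#' boundary patterns) or \code{\link{estimateAbilityEAP}} to every
#' respondent.  Quality-control items are never scored: for a
#' \linkS4class{ComprehensionStudy} they are dropped automatically; a plain
#' matrix must contain scored items only (respondents in rows).
#'
#' @param x a \code{ComprehensionStudy} or a respondents x items 0/1/NA
#'   matrix with dimnames.
#' @param items an \linkS4class{ItemBank}; defaults to the bank carried in
#'   the study's rowData.
#' @param method \code{"MLE"} (default, EAP fallback at boundaries) or
#'   \code{"EAP"}.
#' @param ... passed to the per-pattern estimator.
#' @return data.frame with one row per respondent (columns as in
#'   \code{\link{estimateAbilityMLE}}).
#' @export
estimateAbilities <- function(x, items = NULL, method = c("MLE", "EAP"), ...) {
  method <- match.arg(method)
  if (is(x, "ComprehensionStudy")) {
    if (is.null(items)) items <- studyItemBank(x)
    mat <- t(responses(x)[scoredItemIds(x), , drop = FALSE])
  } else {
    if (is.null(items)) stop("'items' is required for matrix input")
    mat <- x
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("response matrix must have respondent and item dimnames")
  est <- lapply(rownames(mat), function(rid) {
    u <- mat[rid, ]
    names(u) <- colnames(mat)
    if (method == "MLE")
      estimateAbilityMLE(u, items, respondent_id = rid, ...)
    else
      estimateAbilityEAP(u, items, respondent_id = rid, ...)
  })
  do.call(rbind, est)
}
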