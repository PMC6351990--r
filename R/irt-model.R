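# Core 3PL response model:
#   p_i(theta) = c_i + (1 - c_i) / (1 + exp(-a_i (theta - b_i)))
# with discrimination a > 0, difficulty b on the ability scale and guessing
# lower asymptote c in [0, 1).

.bank_params <- function(items) {
  if (is(items, "ItemBank")) {
    df <- items@items
    list(a = df$discrimination, b = df$difficulty, c = df$guessing,
         ids = df$item_id)
  } else if (is.data.frame(items)) {
    validObject(new("ItemBank", items = items))
    list(a = items$discrimination, b = items$difficulty, c = items$guessing,
         ids = items$item_id)
  } else stop("'items' must be an ItemBank or an item data.frame")
}

.p3pl <- function(a, b, c, theta) c + (1 - c) * stats::plogis(a * (theta - b))

#' 3PL probability of a correct response
#'
#' Probability that a respondent with latent ability \code{theta} answers an
#' item correctly under the three-parameter logistic model,
#' \eqn{p = c + (1-c) / (1 + e^{-a(\theta - b)})}.  Vectorised over items
#' (with scalar \code{theta}) or over \code{theta} (with a single item).
#'
#' @param items an \linkS4class{ItemBank} (or its data.frame).
#' @param theta finite numeric latent ability value(s).
#' @return Numeric probabilities, strictly between each item's guessing
#'   floor and 1, named by item when \code{theta} is scalar.
#' @examples
#' b <- itemBank("q1", 1, -1, 0)
#' probCorrect(b, -1)  # 0.5: ability equal to difficulty, no guessing
#' @export
probCorrect <- function(items, theta) {
  pr <- .bank_params(items)
  if (!is.numeric(theta) || !all(is.finite(theta)))
    stop("'theta' must be finite numeric")
  if (length(theta) > 1 && length(pr$a) > 1 && length(theta) != length(pr$a))
    stop("vector 'theta' requires a single item or equal lengths")
  p <- .p3pl(pr$a, pr$b, pr$c, theta)
  if (length(theta) == 1) names(p) <- pr$ids
  p
}

#' 3PL probability of an incorrect response
#'
#' The exact complement \code{1 - probCorrect(items, theta)}.
#'
#' @inheritParams probCorrect
#' @return Numeric probabilities in (0, 1 - c).
#' @export
probIncorrect <- function(items, theta) 1 - probCorrect(items, theta)

.match_pattern <- function(responses, pr) {
  ids <- names(responses)
  if (is.null(ids)) {
    if (length(responses) != length(pr$ids))
      stop("unnamed responses must align 1:1 with the item bank")
    ids <- pr$ids
  }
  if (anyDuplicated(ids)) stop("response item ids must be distinct")
  idx <- match(ids, pr$ids)
  if (anyNA(idx))
    stop("unknown item id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  u <- as.numeric(responses)
  if (!all(u %in% c(0, 1, NA)))
    stop("responses must be 0, 1 or NA")
  keep <- !is.na(u)
  if (!any(keep)) stop("pattern has no scored (non-missing) responses")
  list(u = u[keep], idx = idx[keep])
}

#' Log likelihood of a dichotomous response pattern
#'
#' Sum over scored items of \eqn{u \log p_i(\theta) + (1-u) \log q_i(\theta)},
#' the log of the 3PL pattern likelihood product.  Missing (NA) responses are
#' excluded from the product, never imputed.
#'
#' @param responses numeric vector of 0/1/NA, named by item id (or unnamed
#'   and aligned with the bank).
#' @param items an \linkS4class{ItemBank} containing every response's item.
#' @param theta finite numeric scalar ability.
#' @return The log likelihood (scalar).
#' @export
patternLogLik <- function(responses, items, theta) {
  pr <- .bank_params(items)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta))
    stop("'theta' must be a finite scalar")
  m <- .match_pattern(responses, pr)
  p <- .p3pl(pr$a[m$idx], pr$b[m$idx], pr$c[m$idx], theta)
  sum(m$u * log(p) + (1 - m$u) * log1p(-p))
}

#' Fisher information of a single 3PL item
#'
#' Expected information about ability contributed by one item,
#' \eqn{I(\theta) = a^2 (q/p) ((p - c) / (1 - c))^2}; reduces to
#' \eqn{a^2 p q} when the guessing floor is zero.
#'
#' @inheritParams probCorrect
#' @return Nonnegative numeric information value(s).
#' @export
itemInformation <- function(items, theta) {
  pr <- .bank_params(items)
  if (!is.numeric(theta) || !all(is.finite(theta)))
    stop("'theta' must be finite numeric")
  p <- .p3pl(pr$a, pr$b, pr$c, theta)
  q <- 1 - p
  info <- pr$a^2 * (q / p) * ((p - pr$c) / (1 - pr$c))^2
  if (length(theta) == 1) names(info) <- pr$ids
  info
}

#' Test information and standard error curve
#'
#' Sums item Fisher information over the bank on a grid of ability values;
#' the ability standard error is the inverse square root of the total.  For
#' a bank whose difficulties sit low on the ability scale (as in an
#' instrument targeted at low-literacy respondents) the SE minimum falls
#' below zero ability.
#'
#' @param items an \linkS4class{ItemBank}.
#' @param theta_grid strictly increasing numeric grid of ability values.
#' @return data.frame with columns \code{theta}, \code{information} and
#'   \code{se} (\code{NA} where information is zero).
#' @export
testInformation <- function(items, theta_grid) {
  pr <- .bank_params(items)
  if (length(theta_grid) == 0 || !all(is.finite(theta_grid)))
    stop("'theta_grid' must be nonempty finite numeric")
  if (is.unsorted(theta_grid, strictly = TRUE))
    stop("'theta_grid' must be strictly increasing")
  info <- vapply(theta_grid,
                 function(th) sum(itemInformation(items, th)), numeric(1))
  se <- ifelse(info > 0, 1 / sqrt(info), NA_real_)
  data.frame(theta = theta_grid, information = info, se = se)
}
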