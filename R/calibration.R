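# Marginal maximum-likelihood (Bock-Aitkin EM) calibration of a
# fixed-guessing 3PL model.  The latent trait is integrated over a fixed
# N(0,1) quadrature grid, which pins the scale and location of the
# recovered difficulties (no post-hoc rescaling needed).

.em_loglik_nodes <- function(U0, Umiss, logP, logQ) {
  # n x K matrix of per-respondent log likelihood at each quadrature node
  U0 %*% logP + Umiss %*% logQ
}

.P_EPS <- 1e-12  # keeps log p / log q finite when the logistic saturates

.mstep_item <- function(r_k, n_k, grid, c, a0, b0, a_bounds, b_bounds) {
  # maximize sum_k r_k log p(theta_k) + (n_k - r_k) log q(theta_k) over (a,b)
  negf <- function(par) {
    p <- pmin(pmax(.p3pl(par[1], par[2], c, grid), .P_EPS), 1 - .P_EPS)
    -sum(r_k * log(p) + (n_k - r_k) * log1p(-p))
  }
  neggr <- function(par) {
    a <- par[1]; b <- par[2]
    s <- stats::plogis(a * (grid - b))
    p <- pmin(pmax(c + (1 - c) * s, .P_EPS), 1 - .P_EPS)
    dpde <- (1 - c) * s * (1 - s)          # d p / d eta, eta = a(theta - b)
    core <- (r_k / p - (n_k - r_k) / (1 - p)) * dpde
    -c(sum(core * (grid - b)), sum(core * (-a)))
  }
  fit <- stats::optim(c(a0, b0), negf, neggr, method = "L-BFGS-B",
                      lower = c(a_bounds[1], b_bounds[1]),
                      upper = c(a_bounds[2], b_bounds[2]),
                      control = list(maxit = 50, factr = 1e4))
  fit$par
}

#' Calibrate item parameters by marginal maximum likelihood (EM)
#'
#' Fits discrimination and difficulty for every item of a dichotomous
#' response matrix under a single-factor 3PL model with the guessing
#' parameter fixed at a common value.  The E-step computes each
#' respondent's posterior weights over an equally spaced N(0,1) quadrature
#' grid on [-4, 4]; the M-step maximises the expected complete-data log
#' likelihood per item (bounded two-parameter quasi-Newton ascent with
#' analytic gradients).  Iteration stops when the marginal log-likelihood
#' gain falls below \code{tol} or \code{max_iter} is reached; the trace is
#' monotone non-decreasing up to numerical slack.
#'
#' Items answered identically by every respondent carry no information
#' about discrimination; they are flagged degenerate and their estimates
#' are kept at the parameter bounds rather than aborting the fit.
#'
#' @param x respondents x items 0/1/NA matrix with item column names, or a
#'   \linkS4class{ComprehensionStudy} (QC items are excluded).
#' @param fixed_c common guessing value in [0, 1) (default 0.25, the chance
#'   floor of four-option multiple choice).
#' @param n_nodes quadrature nodes (default 41).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol marginal log-likelihood convergence gain (default 1e-5).
#' @param a_bounds,b_bounds box constraints preventing divergence on
#'   quasi-degenerate items (defaults [0.01, 5] and [-5, 5]).
#' @return A \linkS4class{CalibrationResult}.
#' @export
calibrateItems <- function(x, fixed_c = 0.25, n_nodes = 41, max_iter = 200,
                           tol = 1e-5, a_bounds = c(0.01, 5),
                           b_bounds = c(-5, 5)) {
  if (is(x, "ComprehensionStudy"))
    x <- t(responses(x)[scoredItemIds(x), , drop = FALSE])
  if (!is.matrix(x) || is.null(colnames(x)))
    stop("'x' must be a respondents x items matrix with item column names")
  if (!all(x %in% c(0, 1, NA))) stop("responses must be 0, 1 or NA")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("calibration needs >= 2 respondents and >= 2 items")
  if (fixed_c < 0 || fixed_c >= 1) stop("'fixed_c' must lie in [0, 1)")

  ids <- colnames(x)
  J <- ncol(x); n <- nrow(x)
  M <- !is.na(x)
  U0 <- ifelse(M, x, 0)
  Umiss <- ifelse(M, 1 - x, 0)    # (1-u) with missing contributing 0

  pbar <- colSums(U0) / pmax(colSums(M), 1)
  flagged <- ids[pbar == 0 | pbar == 1]
  pstar <- pmin(pmax((pbar - fixed_c) / (1 - fixed_c), 0.02), 0.98)
  a <- rep(1, J)
  b <- pmin(pmax(-stats::qlogis(pstar), b_bounds[1]), b_bounds[2])

  grid <- seq(-4, 4, length.out = n_nodes)
  logA <- stats::dnorm(grid, log = TRUE)
  logA <- logA - log(sum(exp(logA)))

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    P <- outer(seq_len(J), seq_along(grid),
               function(j, k) .p3pl(a[j], b[j], fixed_c, grid[k]))
    P <- pmin(pmax(P, .P_EPS), 1 - .P_EPS)
    LLn <- .em_loglik_nodes(U0, Umiss, log(P), log1p(-P))
    lp <- sweep(LLn, 2, logA, "+")
    mx <- apply(lp, 1, max)
    marg <- mx + log(rowSums(exp(lp - mx)))
    trace <- c(trace, sum(marg))
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) {
      converged <- TRUE
      break
    }
    W <- exp(lp - marg)                      # n x K posterior weights
    r_jk <- crossprod(U0, W)                 # J x K expected correct counts
    n_jk <- crossprod(M + 0, W)              # J x K expected exposure
    for (j in seq_len(J)) {
      par <- .mstep_item(r_jk[j, ], n_jk[j, ], grid, fixed_c, a[j], b[j],
                         a_bounds, b_bounds)
      a[j] <- par[1]; b[j] <- par[2]
    }
  }

  new("CalibrationResult",
      items = itemBank(ids, a, b, fixed_c),
      logLikTrace = trace, converged = converged,
      nIterations = as.integer(iter), flags = flagged,
      nRespondents = nrow(x))
}

#' Filter a calibrated item bank to a final test set
#'
#' Applies configurable retention rules to a calibration result, modelling
#' the construction of a short instrument from a larger candidate bank:
#' keep items whose estimated discrimination reaches \code{a_min}, whose
#' absolute difficulty does not exceed \code{b_max}, and which were not
#' flagged degenerate.  Every removal is audited with the rule that caused
#' it.
#'
#' @param calib a \linkS4class{CalibrationResult}.
#' @param a_min minimum discrimination (default 0.5); set to \code{-Inf} to
#'   disable.
#' @param b_max maximum absolute difficulty (default 3); \code{Inf} disables.
#' @param drop_flagged drop items flagged degenerate (default TRUE).
#' @param allow_unconverged proceed even if the EM did not converge.
#' @return list with \code{retained} (character ids) and \code{audit}
#'   (per-item data.frame with the removing rule, \code{NA} if retained).
#' @export
filterItemBank <- function(calib, a_min = 0.5, b_max = 3,
                           drop_flagged = TRUE, allow_unconverged = FALSE) {
  stopifnot(is(calib, "CalibrationResult"))
  if (!emConverged(calib) && !allow_unconverged)
    stop("calibration did not converge; pass allow_unconverged = TRUE to override")
  bank <- calibratedItems(calib)
  df <- as.data.frame(bank)
  rule <- rep(NA_character_, nrow(df))
  if (drop_flagged)
    rule[is.na(rule) & df$item_id %in% itemFlags(calib)] <- "degenerate"
  rule[is.na(rule) & df$discrimination < a_min] <- "discrimination_below_min"
  rule[is.na(rule) & abs(df$difficulty) > b_max] <- "difficulty_out_of_range"
  audit <- data.frame(item_id = df$item_id,
                      discrimination = df$discrimination,
                      difficulty = df$difficulty,
                      flagged = df$item_id %in% itemFlags(calib),
                      removed_by = rule,
                      retained = is.na(rule),
                      stringsAsFactors = FALSE)
  retained <- df$item_id[is.na(rule)]
  if (length(retained) == 0)
    stop("all items removed by the filtering rules: empty bank")
  list(retained = retained, audit = audit)
}
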