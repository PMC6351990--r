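# Synthetic three-arm comprehension study generator.  Defaults emulate the
# published crowdsourced evaluation conditions: a 55-item bank with
# difficulties confined to [-2.2, 0.7], three arms of 41/29/27 respondents
# with latent ability means -0.065 / 0.138 / 0.477 on an N(0,1) scale,
# demographic marginals matching the study's totals, three always-easy
# attention-check (QC) items and a small careless-response rate.

.TABLE1_MARGINALS <- list(
  gender = c("Male" = 53, "Female" = 44) / 97,
  age_band = c("22-34" = 55, "35-44" = 23, "45-54" = 13, "55-64" = 6,
               "65 and older" = 0) / 97,
  ethnicity = c("American Indian or Alaska Native" = 2, "Asian" = 4,
                "Black or African American" = 15, "Hispanic" = 5,
                "White" = 71) / 97,
  education = c("Less than high school" = 1, "High school diploma" = 25,
                "Associates" = 16, "Bachelors" = 48,
                "Masters or higher" = 7) / 97,
  occupation = c("Physician" = 1, "Nurse" = 2, "Medical student" = 3,
                 "Other profession in medicine" = 8,
                 "Other profession" = 83) / 97
)

.ARM_LEVELS <- c("baseline", "mlp", "noteaid")

#' Configuration of a synthetic three-arm cohort
#'
#' Bundles and validates the generator settings.  Defaults reproduce the
#' emulated study conditions: arm sizes 41/29/27, arm latent-ability means
#' -0.065/0.138/0.477 (SD 1), demographic category frequencies from the
#' study-wide totals, and a 2\% careless-response rate on QC items.
#'
#' @param arm_sizes named integer vector over arms baseline/mlp/noteaid.
#' @param arm_theta_means named numeric vector of latent ability means.
#' @param theta_sd within-arm ability SD (>= 0; the trait is on an N(0,1)
#'   scale, so 1 is the natural default).
#' @param demographic_marginals named list of per-variable category
#'   frequency vectors, each summing to 1; category names must come from
#'   the canonical vocabularies.
#' @param careless_rate probability in [0, 1) that any single QC response
#'   is wrong.
#' @param theta_shifts optional association hook: named list mapping a
#'   demographic variable to a named vector of additive latent-ability
#'   shifts per category (e.g. \code{list(education = c("Less than high
#'   school" = -0.5))}).
#' @param seed integer run-level seed.
#' @return A validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(arm_sizes = c(baseline = 41L, mlp = 29L, noteaid = 27L),
                         arm_theta_means = c(baseline = -0.065, mlp = 0.138,
                                             noteaid = 0.477),
                         theta_sd = 1.0,
                         demographic_marginals = .TABLE1_MARGINALS,
                         careless_rate = 0.02,
                         theta_shifts = NULL,
                         seed = 1L) {
  if (!setequal(names(arm_sizes), .ARM_LEVELS) ||
      !setequal(names(arm_theta_means), .ARM_LEVELS))
    stop("arm_sizes and arm_theta_means must be named over: ",
         paste(.ARM_LEVELS, collapse = ", "))
  if (any(arm_sizes < 0) || sum(arm_sizes) == 0)
    stop("arm sizes must be nonnegative and sum > 0")
  if (theta_sd < 0) stop("'theta_sd' must be >= 0")
  if (careless_rate < 0 || careless_rate >= 1)
    stop("'careless_rate' must lie in [0, 1)")
  for (v in names(demographic_marginals)) {
    f <- demographic_marginals[[v]]
    if (abs(sum(f) - 1) > 1e-9)
      stop("marginal frequencies for '", v, "' must sum to 1")
    if (v %in% names(.TABLE1_MARGINALS)) {
      bad <- setdiff(names(f), names(.TABLE1_MARGINALS[[v]]))
      if (length(bad))
        stop("unknown category in marginals for '", v, "': ",
             paste(bad, collapse = ", "))
    }
  }
  if (!is.null(theta_shifts)) {
    bad <- setdiff(names(theta_shifts), names(demographic_marginals))
    if (length(bad))
      stop("theta_shifts refers to unknown variable(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(arm_sizes = arm_sizes[.ARM_LEVELS],
                 arm_theta_means = arm_theta_means[.ARM_LEVELS],
                 theta_sd = theta_sd,
                 demographic_marginals = demographic_marginals,
                 careless_rate = careless_rate,
                 theta_shifts = theta_shifts,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate a synthetic 3PL item bank
#'
#' Difficulties are drawn from a normal distribution truncated to
#' \code{difficulty_range} (default [-2.2, 0.7], centred low at -1.0, so
#' most items are easy, as in an instrument aimed at low-literacy readers);
#' discriminations are log-normal (median \code{exp(meanlog)}, default 1.2);
#' guessing is fixed bank-wide.  Disease categories are assigned uniformly
#' over the six-disease vocabulary.
#'
#' @param n_items number of items (>= 1; default 55).
#' @param difficulty_range ordered pair bounding the difficulties.
#' @param difficulty_center,difficulty_sd location/spread of the truncated
#'   normal difficulty law.
#' @param discrimination_meanlog,discrimination_sdlog log-normal
#'   discrimination law parameters.
#' @param fixed_c common guessing value (default 0.25).
#' @param seed integer seed; the same seed reproduces the bank
#'   field-for-field.
#' @return An \linkS4class{ItemBank}.
#' @export
generateItemBank <- function(n_items = 55, difficulty_range = c(-2.2, 0.7),
                             difficulty_center = -1.0, difficulty_sd = 0.8,
                             discrimination_meanlog = log(1.2),
                             discrimination_sdlog = 0.25,
                             fixed_c = 0.25, seed = NULL) {
  if (n_items < 1) stop("'n_items' must be >= 1")
  if (length(difficulty_range) != 2 ||
      difficulty_range[1] >= difficulty_range[2])
    stop("'difficulty_range' must be an ordered pair")
  if (!is.null(seed)) set.seed(seed)
  lo <- stats::pnorm(difficulty_range[1], difficulty_center, difficulty_sd)
  hi <- stats::pnorm(difficulty_range[2], difficulty_center, difficulty_sd)
  b <- stats::qnorm(stats::runif(n_items, lo, hi),
                    difficulty_center, difficulty_sd)
  b <- pmin(pmax(b, difficulty_range[1]), difficulty_range[2])
  a <- stats::rlnorm(n_items, discrimination_meanlog, discrimination_sdlog)
  cat6 <- sample(.DISEASE_CATEGORIES, n_items, replace = TRUE)
  itemBank(sprintf("item_%02d", seq_len(n_items)), a, b, fixed_c, cat6)
}

.sample_cat <- function(n, freqs) {
  lev <- names(freqs)
  factor(lev[sample.int(length(lev), n, replace = TRUE, prob = freqs)],
         levels = lev)
}

#' Generate a three-arm respondent cohort
#'
#' Draws exactly the configured number of respondents per arm; latent
#' ability is normal around each arm's mean, demographics are sampled
#' independently from the configured marginals, and the optional
#' \code{theta_shifts} hook adds category-specific shifts to latent ability
#' (supporting demographic-effect recovery studies).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return data.frame of respondent profiles: \code{respondent_id},
#'   \code{arm}, five demographic factors and \code{latent_theta}.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- sum(config$arm_sizes)
  arm <- factor(rep(names(config$arm_sizes), config$arm_sizes),
                levels = .ARM_LEVELS)
  theta <- stats::rnorm(n, mean = config$arm_theta_means[as.character(arm)],
                        sd = config$theta_sd)
  prof <- data.frame(
    respondent_id = sprintf("r%03d", seq_len(n)),
    arm = arm, stringsAsFactors = FALSE
  )
  for (v in names(config$demographic_marginals))
    prof[[v]] <- .sample_cat(n, config$demographic_marginals[[v]])
  if (!is.null(config$theta_shifts)) {
    for (v in names(config$theta_shifts)) {
      sh <- config$theta_shifts[[v]]
      idx <- match(as.character(prof[[v]]), names(sh))
      theta <- theta + ifelse(is.na(idx), 0, sh[idx])
    }
  }
  prof$latent_theta <- theta
  prof
}

#' Simulate dichotomous responses for a cohort
#'
#' Scored entries are independent Bernoulli draws with success probability
#' \code{probCorrect(item, latent_theta)}; each attention-check (QC) entry
#' is correct with probability \code{1 - careless_rate}, independently of
#' ability (QC items are designed to be answerable by everyone paying
#' attention).
#'
#' @param items scored \linkS4class{ItemBank}.
#' @param respondents cohort data.frame from \code{\link{generateCohort}}
#'   (needs \code{respondent_id} and \code{latent_theta}).
#' @param n_qc number of QC items (ids \code{qc_1}, ...; default 3).
#' @param careless_rate per-entry QC error probability.
#' @param seed integer seed.
#' @return respondents x items 0/1 matrix; QC columns are prefixed
#'   \code{qc_} and placed last.
#' @export
simulateResponses <- function(items, respondents, n_qc = 3,
                              careless_rate = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- respondents$latent_theta
  n <- length(theta)
  P <- vapply(theta, function(th) probCorrect(items, th),
              numeric(length(items)))          # items x respondents
  scored <- t(matrix(stats::rbinom(length(P), 1, P), nrow = length(items)))
  colnames(scored) <- itemIds(items)
  out <- scored
  if (n_qc > 0) {
    qc <- matrix(stats::rbinom(n * n_qc, 1, 1 - careless_rate), nrow = n)
    colnames(qc) <- sprintf("qc_%d", seq_len(n_qc))
    out <- cbind(scored, qc)
  }
  rownames(out) <- respondents$respondent_id
  out
}

#' Simulate a complete three-arm comprehension study
#'
#' Chains \code{\link{generateItemBank}}, \code{\link{generateCohort}} and
#' \code{\link{simulateResponses}} (component seeds derived from the
#' config's run seed) and assembles the result into a
#' \linkS4class{ComprehensionStudy} whose metadata holds the full
#' generating truth, sufficient to recompute every expected response
#' probability.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param n_items scored items (default 55).
#' @param n_qc QC items (default 3).
#' @param fixed_c common guessing value (default 0.25).
#' @param ... further arguments to \code{\link{generateItemBank}}.
#' @return A \linkS4class{ComprehensionStudy}.
#' @examples
#' st <- simulateStudy(cohortConfig(seed = 7))
#' st
#' @export
simulateStudy <- function(config = cohortConfig(), n_items = 55, n_qc = 3,
                          fixed_c = 0.25, ...) {
  stopifnot(inherits(config, "CohortConfig"))
  bank <- generateItemBank(n_items, fixed_c = fixed_c,
                           seed = config$seed + 1L, ...)
  cohort <- generateCohort(config)
  mat <- simulateResponses(bank, cohort, n_qc = n_qc,
                           careless_rate = config$careless_rate,
                           seed = config$seed + 2L)
  bdf <- as.data.frame(bank)
  qc_ids <- grep("^qc_", colnames(mat), value = TRUE)
  itemData <- DataFrame(
    qc = colnames(mat) %in% qc_ids,
    discrimination = c(bdf$discrimination, rep(NA_real_, length(qc_ids))),
    difficulty = c(bdf$difficulty, rep(NA_real_, length(qc_ids))),
    guessing = c(bdf$guessing, rep(NA_real_, length(qc_ids))),
    category = c(bdf$category, rep(NA_character_, length(qc_ids))),
    row.names = colnames(mat)
  )
  respondentData <- DataFrame(cohort[, -1], row.names = cohort$respondent_id)
  comprehensionStudy(t(mat), itemData, respondentData,
                     metadata = list(truth = list(
                       bank = bdf, config = config,
                       qc_item_ids = qc_ids,
                       careless_rate = config$careless_rate)))
}
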