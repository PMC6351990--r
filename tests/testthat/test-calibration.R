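sim_matrix <- function(n, a, b, cc, seed) {
  bank <- itemBank(sprintf("i%02d", seq_along(a)), a, b, cc)
  prof <- data.frame(respondent_id = sprintf("p%04d", seq_len(n)),
                     latent_theta = rnorm(n))
  set.seed(seed + 1)
  list(bank = bank,
       mat = simulateResponses(bank, prof, n_qc = 0, seed = seed))
}

test_that("MML-EM recovers generating item parameters on the N(0,1) scale", {
  set.seed(61)
  J <- 12
  a <- runif(J, 0.8, 2); b <- runif(J, -2.2, 0.7)
  sm <- sim_matrix(600, a, b, 0.25, seed = 62)
  cal <- calibrateItems(sm$mat, fixed_c = 0.25)
  expect_true(emConverged(cal))
  bb <- unname(difficulty(calibratedItems(cal)))
  aa <- unname(discrimination(calibratedItems(cal)))
  expect_gt(cor(bb, b), 0.9)
  expect_gt(cor(aa, a), 0.6)
  # latent scale pinned by the prior: difficulties on the generating scale
  expect_gt(unname(coef(lm(bb ~ b))[2]), 0.8)
  expect_lt(unname(coef(lm(bb ~ b))[2]), 1.2)
  expect_equal(unique(unname(guessing(calibratedItems(cal)))), 0.25)
  expect_true(all(diff(logLikTrace(cal)) > -1e-8))
})

test_that("pure-noise responses yield near-zero discriminations", {
  set.seed(63)
  mat <- matrix(rbinom(1000 * 10, 1, 0.5), 1000, 10,
                dimnames = list(sprintf("p%04d", 1:1000),
                                sprintf("i%02d", 1:10)))
  cal <- calibrateItems(mat, fixed_c = 0, tol = 1e-4)
  expect_lt(median(abs(discrimination(calibratedItems(cal)))), 0.3)
})

test_that("calibration is invariant to row and column order", {
  set.seed(64)
  sm <- sim_matrix(200, c(1, 1.4, 0.9, 1.8), c(-1.5, -0.5, 0, 0.5), 0.2,
                   seed = 65)
  cal <- calibrateItems(sm$mat, fixed_c = 0.2)
  perm <- sm$mat[sample(nrow(sm$mat)), sample(ncol(sm$mat))]
  cal2 <- calibrateItems(perm, fixed_c = 0.2)
  ord <- itemIds(calibratedItems(cal))
  expect_equal(difficulty(calibratedItems(cal2))[ord],
               difficulty(calibratedItems(cal)), tolerance = 1e-8)
  expect_equal(discrimination(calibratedItems(cal2))[ord],
               discrimination(calibratedItems(cal)), tolerance = 1e-8)
})

test_that("degenerate all-same columns are flagged, not fatal", {
  set.seed(66)
  sm <- sim_matrix(150, c(1, 1.2, 1.5), c(-1, 0, 1), 0, seed = 67)
  mat <- cbind(sm$mat, allright = 1)
  cal <- calibrateItems(mat, fixed_c = 0)
  expect_true("allright" %in% itemFlags(cal))
  expect_true(all(is.finite(difficulty(calibratedItems(cal)))))
})

test_that("the EM optimum dominates an exhaustive 2-item parameter grid", {
  # with 2 dichotomous items there are only 4 response patterns, so the
  # marginal likelihood can be brute-forced over an (a, b) x (a, b) grid
  set.seed(68)
  sm <- sim_matrix(150, c(1.2, 0.9), c(-1, 0.5), 0, seed = 69)
  U <- sm$mat
  nodes <- seq(-4, 4, length.out = 21)
  w <- dnorm(nodes); w <- w / sum(w)
  pat_counts <- table(factor(paste0(U[, 1], U[, 2]),
                             levels = c("00", "01", "10", "11")))
  marg_ll <- function(a1, b1, a2, b2) {
    p1 <- oracle_p(a1, b1, 0, nodes); p2 <- oracle_p(a2, b2, 0, nodes)
    lik <- cbind(`00` = (1 - p1) * (1 - p2), `01` = (1 - p1) * p2,
                 `10` = p1 * (1 - p2), `11` = p1 * p2)
    sum(pat_counts * log(colSums(w * lik)))
  }
  cal <- calibrateItems(U, fixed_c = 0, n_nodes = 21, tol = 1e-8)
  est <- as.data.frame(calibratedItems(cal))
  ll_em <- marg_ll(est$discrimination[1], est$difficulty[1],
                   est$discrimination[2], est$difficulty[2])
  av <- seq(0.2, 3, by = 0.2); bv <- seq(-3, 3, by = 0.25)
  grid_best <- -Inf
  for (a1 in av) for (b1 in bv) {
    ll1 <- vapply(bv, function(b2) max(vapply(av, function(a2)
      marg_ll(a1, b1, a2, b2), numeric(1))), numeric(1))
    grid_best <- max(grid_best, max(ll1))
  }
  expect_gte(ll_em, grid_best - 1e-3)
})

test_that("bank filtering applies audited threshold rules", {
  set.seed(70)
  n <- 154
  a <- rlnorm(n, log(0.9), 0.6)
  b <- rnorm(n, -0.8, 1.8)
  bank <- itemBank(sprintf("c%03d", 1:n), a, b, 0.25)
  flags <- sample(itemIds(bank), 6)
  cal <- new("CalibrationResult", items = bank, logLikTrace = c(-100, -90),
             converged = TRUE, nIterations = 2L, flags = flags,
             nRespondents = 83L)
  res <- filterItemBank(cal, a_min = 0.5, b_max = 3)
  # independent per-item re-application of the thresholds
  keep <- !(itemIds(bank) %in% flags) & a >= 0.5 & abs(b) <= 3
  expect_identical(res$retained, itemIds(bank)[keep])
  expect_equal(sum(res$audit$retained), sum(keep))
  expect_true(all(is.na(res$audit$removed_by[res$audit$retained])))
  expect_true(all(!is.na(res$audit$removed_by[!res$audit$retained])))
  # disabled rules: identity
  all_in <- filterItemBank(cal, a_min = -Inf, b_max = Inf,
                           drop_flagged = FALSE)
  expect_identical(all_in$retained, itemIds(bank))
  # a single under-discriminating item is the only removal
  small <- itemBank(c("ok1", "weak", "ok2"), c(1, 0.05, 1.4), c(0, 0, 0.5),
                    0.25)
  cal2 <- new("CalibrationResult", items = small, logLikTrace = -10,
              converged = TRUE, nIterations = 1L, flags = character(0),
              nRespondents = 50L)
  res2 <- filterItemBank(cal2, a_min = 0.5, b_max = 3)
  expect_identical(res2$retained, c("ok1", "ok2"))
  expect_identical(
    res2$audit$removed_by[res2$audit$item_id == "weak"],
    "discrimination_below_min")
  # all items removed is an explicit error
  expect_error(filterItemBank(cal2, a_min = 10), "empty bank")
  # non-convergence must be overridden explicitly
  cal3 <- cal2; cal3@converged <- FALSE
  expect_error(filterItemBank(cal3), "converge")
  expect_silent(filterItemBank(cal3, allow_unconverged = TRUE))
})
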