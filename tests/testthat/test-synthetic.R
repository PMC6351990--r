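test_that("generated item banks honour the difficulty range and seed", {
  bank <- generateItemBank(seed = 1)
  expect_equal(length(bank), 55L)
  expect_true(all(difficulty(bank) >= -2.2 & difficulty(bank) <= 0.7))
  expect_true(all(discrimination(bank) > 0))
  expect_equal(unique(unname(guessing(bank))), 0.25)
  expect_true(all(itemCategories(bank) %in%
                    c("heart failure", "hypertension", "diabetes",
                      "COPD", "liver failure", "cancer")))
  # most items sit low on the ability scale
  expect_gt(mean(difficulty(bank) < 0), 0.5)
  expect_identical(as.data.frame(generateItemBank(seed = 9)),
                   as.data.frame(generateItemBank(seed = 9)))
  one <- generateItemBank(n_items = 1, seed = 2)
  expect_equal(length(one), 1L)
  expect_error(generateItemBank(n_items = 0), "n_items")
})

test_that("cohorts have exact arm sizes and configured ability structure", {
  prof <- generateCohort(cohortConfig(seed = 4))
  expect_equal(nrow(prof), 97L)
  expect_equal(as.vector(table(prof$arm)[c("baseline", "mlp", "noteaid")]),
               c(41L, 29L, 27L))
  # degenerate spread: every respondent sits at the arm mean
  det <- generateCohort(cohortConfig(theta_sd = 0, seed = 5))
  expect_equal(unique(det$latent_theta[det$arm == "noteaid"]), 0.477)
  # large single-arm run: sample mean within 3 standard errors
  big <- cohortConfig(arm_sizes = c(baseline = 0L, mlp = 0L, noteaid = 10000L),
                      seed = 6)
  th <- generateCohort(big)$latent_theta
  expect_lt(abs(mean(th) - 0.477), 3 / sqrt(10000))
})

test_that("cohort configuration is validated with named errors", {
  expect_error(cohortConfig(demographic_marginals = list(
    gender = c(Male = 0.5, Female = 0.4))), "sum to 1")
  expect_error(cohortConfig(demographic_marginals = list(
    gender = c(Male = 0.5, Unknown = 0.5))), "gender")
  expect_error(cohortConfig(careless_rate = 1), "careless_rate")
  expect_error(cohortConfig(arm_sizes = c(baseline = 0L, mlp = 0L,
                                          noteaid = 0L)), "sum > 0")
  expect_error(cohortConfig(theta_shifts = list(income = c(low = -1))),
               "income")
})

test_that("the association hook shifts latent ability by category", {
  cfg <- cohortConfig(theta_sd = 0, seed = 11, theta_shifts = list(
    education = c("Less than high school" = -0.5)))
  prof <- generateCohort(cfg)
  base <- prof$arm == "baseline"
  lhs <- base & prof$education == "Less than high school"
  if (any(lhs))
    expect_equal(unique(prof$latent_theta[lhs]), -0.065 - 0.5)
  expect_equal(unique(prof$latent_theta[base & !lhs &
                                          prof$education != "Less than high school"]),
               -0.065)
})

test_that("simulated responses follow the 3PL generative law", {
  bank <- generateItemBank(seed = 21)
  # saturation: a +10-ability respondent clears (essentially) every item
  expect_true(all(probCorrect(bank, 10) > 0.995))
  hi <- data.frame(respondent_id = "hi", latent_theta = 10)
  set.seed(1)
  mat <- simulateResponses(bank, hi, n_qc = 3, careless_rate = 0, seed = 22)
  expect_true(all(mat[, grepl("^qc_", colnames(mat))] == 1))
  # model-implied mean raw score at theta = 0, n = 5000
  prof <- data.frame(respondent_id = sprintf("p%04d", 1:5000),
                     latent_theta = 0)
  m0 <- simulateResponses(bank, prof, n_qc = 0, seed = 23)
  pbar <- mean(probCorrect(bank, 0))
  mc_se <- sqrt(sum(probCorrect(bank, 0) * (1 - probCorrect(bank, 0)))) /
    (55 * sqrt(5000))
  expect_lt(abs(mean(rawScores(m0)) - pbar), 3 * mc_se)
})

test_that("simulated studies are deterministic and carry their truth", {
  cfg <- cohortConfig(seed = 31)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(responses(s1), responses(s2))
  expect_identical(as.data.frame(colData(s1)), as.data.frame(colData(s2)))
  truth <- metadata(s1)$truth
  expect_identical(truth$qc_item_ids, c("qc_1", "qc_2", "qc_3"))
  # the truth bundle reproduces expected response probabilities
  bank <- studyItemBank(s1)
  expect_equal(as.data.frame(bank), truth$bank)
  p <- probCorrect(bank, colData(s1)$latent_theta[1])
  expect_true(all(p > 0.25 & p < 1))
})

test_that("studies round-trip losslessly through the CSV interfaces", {
  st <- simulateStudy(cohortConfig(seed = 41), n_items = 10)
  td <- withr::local_tempdir()
  bank <- studyItemBank(st)
  writeItemBank(bank, file.path(td, "bank.csv"))
  expect_equal(as.data.frame(readItemBank(file.path(td, "bank.csv"))),
               as.data.frame(bank))
  mat <- t(responses(st))
  storage.mode(mat) <- "double"  # CSV carries numerals, not storage mode
  mat[1, 2] <- NA  # exercise the blank-cell convention
  writeResponses(mat, file.path(td, "resp.csv"))
  back <- readResponses(file.path(td, "resp.csv"))
  expect_identical(back, mat)
  prof <- as.data.frame(colData(st))
  prof <- data.frame(respondent_id = rownames(prof), prof,
                     row.names = NULL, stringsAsFactors = FALSE)
  prof[] <- lapply(prof, function(x) if (is.factor(x)) as.character(x) else x)
  writeDemographics(prof, file.path(td, "demo.csv"))
  expect_equal(readDemographics(file.path(td, "demo.csv")), prof)
})
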