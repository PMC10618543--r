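test_that("profile sampling is seeded, weighted and covers groups uniformly when asked", {
  w <- default_profile_weights()
  p1 <- sample_profiles(50, w, seed = 5)
  p2 <- sample_profiles(50, w, seed = 5)
  expect_identical(p1, p2)
  # concentrated weights produce a single profile
  lv <- profile_levels()
  w1 <- list(age_group = setNames(c(1, 0, 0, 0, 0, 0), lv$age_group),
             gender = c(female = 1, male = 0),
             smoking = c("non-smoker" = 1, smoker = 0),
             weight_group = c(underweight = 0, normal = 1, overweight = 0))
  pc <- sample_profiles(20, w1, seed = 1)
  expect_equal(nrow(unique(pc)), 1)
  # uniform weights: every group frequency within 3 sigma of n/72
  wu <- lapply(lv, function(l) setNames(rep(1 / length(l), length(l)), l))
  pu <- sample_profiles(1000, wu, seed = 4)
  counts <- tabulate(group_of(pu), nbins = 72)
  p <- 1 / 72
  expect_true(all(abs(counts - 1000 * p) <= 3 * sqrt(1000 * p * (1 - p))))
  expect_error(sample_profiles(5, list(age_group = c(1, 2)), seed = 1),
               "sum to 1")
})

test_that("personalization applies exactly the per-field multipliers", {
  lv <- profile_levels()
  unit <- lapply(default_effects(), function(tab) {
    lapply(tab, function(m) setNames(rep(1, length(m)), names(m)))
  })
  gt_unit <- ground_truth(effects = unit)
  prof <- patient_profile("66+", "female", "smoker", "overweight")
  expect_equal(unclass(personalize_params(gt_unit, prof)),
               unclass(gt_unit$baseline))
  gt <- ground_truth()
  pp <- personalize_params(gt, prof)
  expect_equal(pp$lambda, gt$baseline$lambda * 1.5)         # smoker
  expect_equal(pp$mu_E, gt$baseline$mu_E * 1.5)             # oldest group
  expect_equal(pp$H_m, gt$baseline$H_m * 1.15)              # overweight
  expect_equal(pp$alpha, gt$baseline$alpha * 1.15)          # female
  # fields with unit multipliers do not alter parameters
  eff <- list(smoking = list(lambda = c("non-smoker" = 1, smoker = 2)))
  gt2 <- ground_truth(effects = eff)
  a <- personalize_params(gt2, patient_profile("19-25", "male",
                                               "smoker", "normal"))
  b <- personalize_params(gt2, patient_profile("66+", "female",
                                               "smoker", "underweight"))
  expect_equal(unclass(a), unclass(b))
})

test_that("generated cohorts are reproducible and noise-free at sigma 0", {
  gt0 <- ground_truth(sigma = 0)
  syn <- generate_cohort(gt0, n = 15, seed = 33)
  syn2 <- generate_cohort(gt0, n = 15, seed = 33)
  expect_identical(syn$records, syn2$records)
  expect_equal(syn$records$T_end_cells, syn$noise_free)
  # noisy cohorts multiply the noise-free outcome by the lognormal draw
  gts <- ground_truth(sigma = 0.2)
  syns <- generate_cohort(gts, n = 15, seed = 33)
  expect_identical(syns$records$T_start_cells, syn$records$T_start_cells)
  expect_false(any(syns$records$T_end_cells == syns$noise_free))
})

test_that("hidden true parameters reproduce the noise-free outcomes", {
  syn <- generate_cohort(ground_truth(sigma = 0.1), n = 10, seed = 44)
  for (i in c(1, 5, 10)) {
    out <- predict_outcome(syn$true_params[[i]],
                           record = transform(syn$records[i, ],
                                              T_end_cells = 1))
    expect_equal(out, syn$noise_free[i], tolerance = 1e-5)
  }
})

test_that("a 1.5x growth-rate effect is detectable above sigma = 0.1 noise", {
  truth <- two_group_truth(sigma = 0.1)
  syn <- generate_cohort(truth, n = 200, seed = 13)
  rec <- syn$records
  # response ratio normalises out the presenting-burden spread
  ratio <- log(rec$T_end_cells / rec$T_start_cells)
  ht <- t.test(ratio[rec$smoking == "smoker"],
               ratio[rec$smoking == "non-smoker"])
  expect_lt(ht$p.value, 0.01)
})

test_that("a study-sized cohort generates at desk scale", {
  syn <- generate_cohort(ground_truth(), n = 417, seed = 1)
  expect_equal(nrow(syn$records), 417)
  expect_true(all(syn$records$T_end_cells > 0))
  # unbalanced sampling leaves some of the 72 groups empty
  expect_lt(length(unique(group_of(syn$records))), 72)
})
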