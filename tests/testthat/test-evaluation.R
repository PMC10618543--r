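# A stub model whose predictions are an arbitrary function of the records,
# used to probe the evaluation machinery with known error structures.
predict_burden.mock_model <- function(model, records) model$f(records)
registerS3method("predict_burden", "mock_model", predict_burden.mock_model,
                 envir = asNamespace("bcgdyn"))
mock_model <- function(f) structure(list(f = f), class = "mock_model")

test_that("evaluation reports overall, per-group and marginal errors coherently", {
  syn <- generate_cohort(ground_truth(sigma = 0.1), n = 60, seed = 6)
  rec <- syn$records
  perfect <- mock_model(function(r) r$T_end_cells)
  ev <- evaluate_model(perfect, rec)
  expect_equal(ev$overall, 0)
  expect_true(all(ev$by_group$rmae[ev$by_group$n > 0] == 0))
  # empty groups are flagged as missing, not zero
  expect_true(all(is.na(ev$by_group$rmae[ev$by_group$n == 0])))
  expect_equal(sum(ev$by_group$n), nrow(rec))

  biased <- mock_model(function(r) r$T_end_cells * 1.25)
  ev2 <- evaluate_model(biased, rec)
  expect_equal(ev2$overall, 0.25, tolerance = 1e-12)
  # overall error is the patient-weighted combination of group errors
  bg <- ev2$by_group
  expect_equal(sum(bg$n * bg$rmae, na.rm = TRUE) / sum(bg$n), ev2$overall)

  # a single-group cohort fills exactly one cell of the table
  one <- rec[group_of(rec) == group_of(rec)[1], ]
  ev3 <- evaluate_model(biased, one)
  expect_equal(sum(ev3$by_group$n > 0), 1)
})

test_that("model comparison detects a pointwise-better model and ties honestly", {
  syn <- generate_cohort(ground_truth(sigma = 0.1), n = 120, seed = 19)
  rec <- syn$records
  wobble <- sin(seq_len(nrow(rec)))
  good <- mock_model(function(r) {
    i <- match(r$patient_id, rec$patient_id)
    r$T_end_cells * (1 + 0.05 + 0.02 * wobble[i])
  })
  bad <- mock_model(function(r) {
    i <- match(r$patient_id, rec$patient_id)
    r$T_end_cells * (1 + 0.10 + 0.04 * wobble[i])
  })
  cmp <- suppressWarnings(
    compare_models(list(good = good, bad = bad), rec, n_samples = 30,
                   seed = 3))
  expect_identical(cmp$winner, "good")
  expect_lt(cmp$pairwise_p["good", "bad"], 0.05)
  expect_lt(cmp$anova_p, 0.05)
  # errors of 'good' are half of 'bad' pointwise by construction
  expect_equal(cmp$errors[, "good"] * 2, cmp$errors[, "bad"],
               tolerance = 1e-10)
  # reported means equal the RMAE recomputed from the error matrix
  expect_equal(cmp$summary$mean_rmae, unname(colMeans(cmp$errors)))
  # the evaluation subset has pairwise-distinct profiles
  sub <- rec[match(cmp$sample_ids, rec$patient_id), ]
  expect_equal(anyDuplicated(group_of(sub)), 0L)
  # same seed, same subset
  cmp2 <- suppressWarnings(
    compare_models(list(good = good, bad = bad), rec, n_samples = 30,
                   seed = 3))
  expect_identical(cmp$sample_ids, cmp2$sample_ids)

  # indistinguishable models: no winner
  tie <- suppressWarnings(
    compare_models(list(a = good, b = good, c = good), rec,
                   n_samples = 30, seed = 3))
  expect_true(is.na(tie$winner))
  expect_gt(tie$anova_p, 0.9)
})

test_that("legacy fit is self-consistent on data the legacy model generated", {
  lp <- legacy_params(lambda = 2.5e-3, T0 = 1e6)
  T0s <- exp(seq(log(5e4), log(5e6), length.out = 25))
  outs <- bcgdyn:::batch_outcomes_legacy(lp, T0s, 1008)
  rec <- data.frame(patient_id = seq_along(T0s),
                    patient_profile(rep("46-55", 25), rep("male", 25),
                                    rep("smoker", 25), rep("normal", 25)),
                    T_start_cells = T0s, T_end_cells = outs,
                    t_f_hours = 1008, b = 2.8e6, N = 6, tau = 168)
  cfg <- fit_config(free = c("lambda", "mu_E"), n_restarts = 1,
                    gd_max_iter = 30, seed = 5)
  fit <- fit_legacy(rec, cfg,
                    init = legacy_params(lambda = 1.2e-3, T0 = 1e6))
  expect_lt(fit$loss, 0.05)
  expect_gte(fit$params$lambda, cfg$lower[["lambda"]])
  expect_lte(fit$params$lambda, cfg$upper[["lambda"]])
  # data from the richer six-compartment model leaves residual error
  syn <- generate_cohort(two_group_truth(sigma = 0), n = 40, seed = 9)
  fit2 <- fit_legacy(syn$records, cfg)
  expect_gt(fit2$loss, 0.01)
})

test_that("error contrasts control false positives and flag a planted effect", {
  set.seed(77)
  n <- 400
  profs <- sample_profiles(n, seed = 78)
  base_err <- rlnorm(n, log(0.2), 0.4)
  # permuted labels: each primary test should trip rarely
  hits <- c(smoking = 0, gender = 0, weight = 0, age = 0)
  for (r in 1:100) {
    shuffled <- profs[sample.int(n), ]
    ct <- suppressWarnings(group_contrasts(base_err, shuffled))
    hits["smoking"] <- hits["smoking"] +
      ct$significant[ct$field == "smoking" & ct$test == "t-test"]
    hits["gender"] <- hits["gender"] +
      ct$significant[ct$field == "gender" & ct$test == "t-test"]
    hits["weight"] <- hits["weight"] +
      ct$significant[ct$field == "weight_group" & ct$test == "anova"]
    hits["age"] <- hits["age"] +
      ct$significant[ct$field == "age_group" & ct$test == "anova"]
  }
  expect_true(all(hits <= 10))

  # planted 2x inflation in one weight level is localised by Tukey
  lv <- profile_levels()
  prof2 <- patient_profile(
    rep("46-55", 300), rep("male", 300), rep("smoker", 300),
    rep(lv$weight_group, each = 100))
  err2 <- rlnorm(300, log(0.2), 0.3)
  err2[prof2$weight_group == "underweight"] <-
    err2[prof2$weight_group == "underweight"] * 2
  ct2 <- suppressWarnings(group_contrasts(err2, prof2))
  tk <- ct2[ct2$field == "weight_group" & ct2$test == "tukey", ]
  flagged <- tk$contrast[tk$significant]
  expect_true(all(grepl("underweight", flagged)))
  expect_gte(length(flagged), 2)

  # a level with fewer than two patients is excluded with a warning
  prof3 <- prof2[c(1:99, 101:300), ]
  err3 <- err2[c(1:99, 101:300)]
  prof3$weight_group[1] <- "underweight"
  prof3$weight_group[2:100] <- "normal"
  expect_warning(group_contrasts(err3, prof3), "< 2 patients")
})

test_that("pooled and personalized fits coincide on a homogeneous cohort", {
  # all multipliers 1: there is nothing for personalization to exploit
  lv <- profile_levels()
  unit_eff <- list(smoking = list(lambda = c("non-smoker" = 1, smoker = 1)))
  gt <- ground_truth(effects = unit_eff, sigma = 0)
  syn <- generate_cohort(gt, n = 40, seed = 14)
  cfg <- quick_config(n_augment = 0L)
  pers <- fit_bcg(syn$records, cfg)
  pooled <- fit_no_socio(syn$records, cfg)
  ev_p <- evaluate_model(pers, syn$records)
  ev_0 <- evaluate_model(pooled, syn$records)
  expect_lt(ev_p$overall, 0.06)
  expect_lt(ev_0$overall, 0.06)
  expect_lt(abs(ev_p$overall - ev_0$overall), 0.05)
})
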