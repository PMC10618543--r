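test_that("dose input is a triangular unit-integral pulse train", {
  s <- dose_schedule(b = 2.8e6, epsilon = 0.5)
  # peak height b/epsilon at every dose time
  for (m in 0:5) {
    expect_equal(dose_input(m * 168, s), 2.8e6 / 0.5)
  }
  # zero outside the pulse support and after the last dose
  expect_equal(dose_input(168 + 2 * 0.5, s), 0)
  expect_equal(dose_input(84, s), 0)
  expect_equal(dose_input(6 * 168, s), 0)
  expect_equal(dose_input(-5, s), 0)
  # the time integral across one pulse is the dose b
  integ <- integrate(dose_input, 168 - 0.5, 168 + 0.5, schedule = s,
                     subdivisions = 1000L, rel.tol = 1e-9)
  expect_equal(integ$value, 2.8e6, tolerance = 1e-6)
  # schedule validation
  expect_error(dose_schedule(epsilon = 100), "epsilon")
  expect_error(dose_schedule(n_doses = 0), "n_doses")
  expect_error(dose_input(Inf, s), "finite")
})

test_that("right-hand side vanishes and decouples where it should", {
  p <- model_params()
  # empty bladder: every term has a state factor
  expect_equal(unname(bcg_rhs(10, rep(0, 6), p)), rep(0, 6))
  # lone uninfected tumor grows at lambda, nothing else moves
  d <- bcg_rhs(10, c(0, 0, 0, 5e5, 0, 0), p)
  expect_equal(unname(d), c(0, 0, 0, p$lambda * 5e5, 0, 0))
  # healthy bladder at capacity: logistic bracket vanishes
  d <- bcg_rhs(10, c(0, 0, 0, 0, p$H_m, 0), p)
  expect_equal(unname(d), rep(0, 6))
  expect_error(bcg_rhs(0, c(NA, 0, 0, 0, 0, 0), p), "finite")
})

test_that("initial state fills the bladder to capacity", {
  p <- model_params(e0 = 1e3, T0 = 1e5, H_m = 1.84e9)
  y0 <- initial_state(p)
  expect_equal(unname(y0), c(0, 1e3, 0, 1e5, 1.84e9 - 1e5, 0))
  expect_error(initial_state(update_params(p, T0 = 1.84e9)), "T0")
  expect_error(initial_state(update_params(p, e0 = 0)), "e0")
})

test_that("tumor growth matches the exponential closed form without BCG and effectors", {
  p <- bare_params(lambda = 2e-3, T0 = 1e5)
  s <- dose_schedule(b = 0)
  traj <- simulate_treatment(p, s, t_end = 1008)
  expected <- 1e5 * exp(2e-3 * traj$time)
  expect_lt(max(abs(traj$T_u - expected) / expected), 1e-6)
  # burden is T_i + T_u and equals T0 at t = 0
  expect_equal(tumor_burden(traj, 0), 1e5)
  expect_error(tumor_burden(traj, 2000), "span")
})

test_that("a single instillation decays at mu_B when nothing else consumes BCG", {
  p <- bare_params(mu_B = 4.16e-3, T0 = 1e5)
  s <- dose_schedule(n_doses = 1)
  traj <- simulate_treatment(p, s, t_end = 500)
  tt <- traj$time[traj$time > 1]
  expected <- 2.8e6 * exp(-4.16e-3 * tt)
  expect_lt(max(abs(traj$B[traj$time > 1] - expected) / expected), 1e-4)
})

test_that("dosing conserves: without elimination B accumulates to N * b", {
  p <- bare_params(T0 = 1e5)
  for (mode in c("jump", "pulse")) {
    traj <- simulate_treatment(p, dose_schedule(mode = mode))
    expect_equal(traj$B[nrow(traj)], 6 * 2.8e6, tolerance = 1e-4)
  }
})

test_that("jump and pulse administration agree on the treatment outcome", {
  p <- model_params(T0 = 1e6)
  bj <- tumor_burden(simulate_treatment(p, dose_schedule(mode = "jump")),
                     1008)
  # small-epsilon pulse is the reference for the jump shortcut
  bp <- tumor_burden(
    simulate_treatment(p, dose_schedule(mode = "pulse", epsilon = 0.168)),
    1008)
  expect_lt(abs(bj - bp) / bp, 0.01)
})

test_that("states stay non-negative and within bladder capacity", {
  set.seed(41)
  base <- unlist(model_params()[1:13])
  for (rep in 1:15) {
    scale <- exp(runif(13, log(0.4), log(2.5)))
    vals <- as.list(base * scale)
    vals$T0 <- 10^runif(1, 4, 7)
    p <- do.call(model_params, vals)
    traj <- simulate_treatment(p, dose_schedule())  # errors on negativity
    expect_true(all(as.matrix(traj[, -1]) >= 0))
    total <- traj$T_i + traj$T_u + traj$H_u + traj$H_i
    expect_lt(max(total), p$H_m * (1 + 1e-3))
  }
})

test_that("production solver agrees with a fixed-step RK4 reference", {
  p <- model_params(T0 = 1e6)
  s <- dose_schedule()
  traj <- simulate_treatment(p, s)
  y_ref <- rk4_simulate(p, s, t_end = 1008, h = 0.25)
  burden_ref <- y_ref[["T_i"]] + y_ref[["T_u"]]
  expect_lt(abs(tumor_burden(traj, 1008) - burden_ref) / burden_ref, 1e-4)
})

test_that("trajectories are well-formed", {
  traj <- simulate_treatment(model_params(T0 = 1e5), dose_schedule())
  expect_true(all(diff(traj$time) > 0))
  expect_named(traj, c("time", "B", "E", "T_i", "T_u", "H_u", "H_i"))
  expect_output(print(traj), "final tumor burden")
})

test_that("legacy model reproduces its continuous-instillation structure", {
  lp <- legacy_params(b = 100)
  # empty state: only the constant instillation survives
  expect_equal(unname(legacy_rhs(0, rep(0, 4), lp)), c(100, 0, 0, 0))
  # pure BCG decay
  lp0 <- legacy_params(p1 = 0, p2 = 0, p3 = 0, p4 = 0, p5 = 0, b = 0,
                       mu1 = 0.01, mu2 = 0, alpha = 0, lambda = 0)
  expect_equal(unname(legacy_rhs(0, c(5e5, 0, 0, 0), lp0)),
               c(-0.01 * 5e5, 0, 0, 0))
  # lone tumor grows at lambda
  lpl <- legacy_params(lambda = 3e-3)
  expect_equal(unname(legacy_rhs(0, c(0, 0, 0, 1e4), lpl)),
               c(lpl$b, 0, 0, 3e-3 * 1e4))
  # simulated exponential growth oracle
  lp_exp <- legacy_params(p1 = 0, p2 = 0, p3 = 0, p4 = 0, p5 = 0, b = 0,
                          mu1 = 0, mu2 = 0, alpha = 0, lambda = 2e-3,
                          T0 = 1e5)
  traj <- simulate_legacy(lp_exp, t_end = 500)
  expect_lt(max(abs(traj$T_u - 1e5 * exp(2e-3 * traj$time)) /
                  (1e5 * exp(2e-3 * traj$time))), 1e-6)
})

test_that("batched group integration matches per-patient simulation", {
  p <- model_params()
  s <- dose_schedule()
  T0s <- c(2e4, 3e5, 8e6)
  batch <- bcgdyn:::batch_outcomes(p, T0s, s, 1008)
  single <- vapply(T0s, function(T0) {
    predict_outcome(update_params(p, T0 = T0), schedule = s)
  }, numeric(1))
  expect_equal(batch, single, tolerance = 1e-5)
})
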