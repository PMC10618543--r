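# Independent oracles and shared fixtures, built in code at test time.

# Fixed-step classic RK4 integrator over the R-level right-hand side, with
# jump-mode dosing applied as explicit +b events. Independent of the
# compiled-C / lsoda production path.
rk4_simulate <- function(params, schedule, t_end, h = 0.25) {
  y <- initial_state(params)
  dt <- dose_times(schedule)
  dt <- dt[dt <= t_end]
  bounds <- sort(unique(c(0, dt, t_end)))
  f <- function(t, y) bcg_rhs(t, y, params)
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]
    t1 <- bounds[s + 1]
    if (t0 %in% dt) y[1] <- y[1] + schedule$b
    nstep <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / nstep
    t <- t0
    for (i in seq_len(nstep)) {
      k1 <- f(t, y)
      k2 <- f(t + hh / 2, y + hh / 2 * k1)
      k3 <- f(t + hh / 2, y + hh / 2 * k2)
      k4 <- f(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
  }
  if (t_end %in% dt && t_end == max(bounds) && length(bounds) == 1) {
    y[1] <- y[1] + schedule$b
  }
  y
}

# Central-difference numerical Jacobian of the treatment-free RHS. The RHS
# is at most quadratic in the state, so central differences are exact up to
# rounding; one step at the overall state scale keeps cancellation noise
# far below the comparison tolerance.
numeric_jacobian <- function(params, state, rel_step = 1e-6) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    h <- rel_step * max(abs(state), 1)
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (bcg_rhs(0, up, params) - bcg_rhs(0, dn, params)) / (2 * h)
  }
  J
}

# Parameter set with every rate zeroed except those supplied.
bare_params <- function(...) {
  zeros <- as.list(setNames(rep(0, 13),
                            c(paste0("p", 1:9), "mu_B", "mu_E", "alpha",
                              "lambda")))
  do.call(model_params, utils::modifyList(zeros, list(...)))
}

# Ground truth with exactly two occupied groups (smokers vs non-smokers of
# one fixed age/gender/weight cell) whose parameters differ only in the
# two free parameters lambda and mu_E.
two_group_truth <- function(sigma = 0, baseline = model_params()) {
  lv <- profile_levels()
  w <- list(age_group = setNames(c(0, 0, 0, 1, 0, 0), lv$age_group),
            gender = c(female = 0, male = 1),
            smoking = c("non-smoker" = 0.5, smoker = 0.5),
            weight_group = c(underweight = 0, normal = 1, overweight = 0))
  eff <- list(smoking = list(lambda = c("non-smoker" = 1, smoker = 1.5),
                             mu_E = c("non-smoker" = 1, smoker = 1.3)))
  ground_truth(baseline = baseline, effects = eff, sigma = sigma,
               weights = w)
}

# A minimal single-row cohort record for direct predict_outcome tests.
make_record <- function(T_start, T_end = T_start, t_f = 1008,
                        profile = patient_profile("46-55", "male",
                                                  "smoker", "normal"),
                        b = 2.8e6, N = 6, tau = 168) {
  data.frame(patient_id = 1L, profile, T_start_cells = T_start,
             T_end_cells = T_end, t_f_hours = t_f, b = b, N = N, tau = tau,
             stringsAsFactors = FALSE)
}

quick_config <- function(...) {
  args <- list(k = 2, free = c("lambda", "mu_E"), n_restarts = 1,
               gd_max_iter = 15, gd_refit_iter = 8, n_augment = 5,
               max_aug_rounds = 1, seed = 7)
  do.call(fit_config, utils::modifyList(args, list(...)))
}
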