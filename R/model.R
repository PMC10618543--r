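STATE_NAMES <- c("B", "E", "T_i", "T_u", "H_u", "H_i")

#' Pulsed dosing input
#'
#' Evaluates the instillation forcing term: the sum over doses of
#' `b * delta_eps(t - m tau)`, where `delta_eps` is the triangular
#' unit-integral approximation of the Dirac delta with half-width
#' `epsilon` (peak height `1/epsilon` at the dose time, linear down to 0 at
#' `+/- epsilon`). The time integral of the input across one pulse is
#' exactly `b`, so each instillation raises the BCG compartment by `b`
#' units.
#'
#' @param t time (hours), scalar or vector.
#' @param schedule a [dose_schedule()].
#' @return Dosing rate in BCG units per hour (0 outside pulse supports).
#' @export
#' @examples
#' s <- dose_schedule(b = 2.8e6, epsilon = 0.5)
#' dose_input(0, s)    # peak: b / epsilon
#' dose_input(10, s)   # between pulses: 0
dose_input <- function(t, schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  b <- schedule$b
  tau <- schedule$tau
  eps <- schedule$epsilon
  m <- round(t / tau)
  d <- abs(t - m * tau)
  rate <- ifelse(m >= 0 & m < schedule$n_doses & d < eps,
                 b * (1 - d / eps) / eps, 0)
  as.numeric(rate)
}

#' Right-hand side of the six-compartment model
#'
#' The derivative of the state `(B, E, T_i, T_u, H_u, H_i)`:
#' BCG decays and is consumed by effector uptake and by infecting cancer
#' and healthy cells; effector cells are recruited by infected cells and by
#' BCG and lost while killing; cancer cells grow at rate `lambda`, are
#' infected by BCG and killed by effectors; healthy cells regrow
#' logistically toward the shared capacity `H_m` and are infected by BCG.
#' The dosing term is the triangular pulse input when `schedule` is given
#' in `"pulse"` mode and zero otherwise (in `"jump"` mode doses are applied
#' as state discontinuities by the integrator, not through the RHS).
#'
#' @param t time (hours).
#' @param state numeric vector of length 6 (`B, E, T_i, T_u, H_u, H_i`).
#' @param params a [model_params()] object.
#' @param schedule optional [dose_schedule()]; only a `"pulse"`-mode
#'   schedule contributes a forcing term.
#' @return Named numeric vector of the six derivatives.
#' @export
bcg_rhs <- function(t, state, params, schedule = NULL) {
  if (!all(is.finite(state)) || !is.finite(t)) {
    stop("non-finite state or time", call. = FALSE)
  }
  B <- state[[1]]; E <- state[[2]]; Ti <- state[[3]]
  Tu <- state[[4]]; Hu <- state[[5]]; Hi <- state[[6]]
  p <- params
  dose <- 0
  if (!is.null(schedule) && schedule$mode == "pulse") {
    dose <- dose_input(t, schedule)
  }
  dB <- dose - p$p1 * E * B - p$p2 * B * Tu - p$p8 * B * Hu - p$mu_B * B
  dE <- -p$mu_E * E + p$alpha * (Ti + Hi) + p$p4 * E * B -
    p$p5 * E * Ti - p$p6 * E * Hi
  dTi <- p$p2 * B * Tu - p$p3 * Ti * E
  dTu <- p$lambda * Tu - p$p2 * B * Tu - p$p3 * Tu * E
  dHu <- p$p7 * Hu * (1 - (Hu + Hi + Tu + Ti) / p$H_m) - p$p8 * B * Hu
  dHi <- p$p8 * B * Hu - p$p9 * E * Hi
  setNames(c(dB, dE, dTi, dTu, dHu, dHi), STATE_NAMES)
}

#' Right-hand side of the legacy four-compartment model
#'
#' Continuous-instillation predecessor model over `(B, E, T_i, T_u)`:
#' BCG enters at constant rate `b`, effectors are recruited by infected
#' cancer cells only, and uninfected cancer cells are removed only through
#' BCG infection (no direct effector kill term).
#'
#' @param t time (hours).
#' @param state numeric vector of length 4 (`B, E, T_i, T_u`).
#' @param params a [legacy_params()] object.
#' @return Named numeric vector of the four derivatives.
#' @export
legacy_rhs <- function(t, state, params) {
  if (!all(is.finite(state)) || !is.finite(t)) {
    stop("non-finite state or time", call. = FALSE)
  }
  B <- state[[1]]; E <- state[[2]]; Ti <- state[[3]]; Tu <- state[[4]]
  p <- params
  dB <- -p$p1 * E * B - p$p2 * B * Tu - p$mu1 * B + p$b
  dE <- -p$mu2 * E + p$alpha * Ti + p$p4 * E * B - p$p5 * E * Ti
  dTi <- p$p2 * B * Tu - p$p3 * Ti * E
  dTu <- p$lambda * Tu - p$p2 * B * Tu
  setNames(c(dB, dE, dTi, dTu), c("B", "E", "T_i", "T_u"))
}

#' Initial state at treatment start
#'
#' Treatment begins with no intravesical BCG, a small resident effector
#' population `e0`, no infected cells, `T0` uninfected cancer cells and the
#' remaining bladder capacity filled with healthy cells:
#' `(0, e0, 0, T0, H_m - T0, 0)`.
#'
#' @param params a [model_params()] object with `e0 > 0` and
#'   `0 < T0 < H_m`.
#' @return Named state vector of length 6.
#' @export
#' @examples
#' initial_state(model_params(e0 = 1e3, T0 = 1e5))
initial_state <- function(params) {
  if (params$e0 <= 0) stop("e0 must be positive", call. = FALSE)
  if (params$T0 <= 0 || params$T0 >= params$H_m) {
    stop("T0 must satisfy 0 < T0 < H_m", call. = FALSE)
  }
  setNames(c(0, params$e0, 0, params$T0, params$H_m - params$T0, 0),
           STATE_NAMES)
}

parms_vector <- function(params, schedule, pulse_on) {
  c(params$p1, params$p2, params$p3, params$p4, params$p5, params$p6,
    params$p7, params$p8, params$p9, params$mu_B, params$mu_E,
    params$alpha, params$lambda, params$H_m,
    schedule$b, schedule$n_doses, schedule$tau, schedule$epsilon,
    as.numeric(pulse_on))
}

as_trajectory <- function(out, params) {
  traj <- as.data.frame(out)
  names(traj) <- c("time", STATE_NAMES)
  atols <- state_atol(params)
  low <- vapply(seq_along(STATE_NAMES), function(j) {
    min(traj[[j + 1]])
  }, numeric(1))
  if (any(low < -10 * atols)) {
    stop("integration produced negative states beyond tolerance in: ",
         paste(STATE_NAMES[low < -10 * atols], collapse = ", "),
         call. = FALSE)
  }
  for (j in seq_along(STATE_NAMES)) {  # clip solver-noise negatives on output
    col <- traj[[j + 1]]
    col[col < 0] <- 0
    traj[[j + 1]] <- col
  }
  class(traj) <- c("bcg_trajectory", "data.frame")
  traj
}

state_atol <- function(params) {
  1e-6 * pmax(c(1, params$e0, params$T0, params$T0, params$H_m, params$T0), 1)
}

#' Simulate a BCG treatment course
#'
#' Integrates the six-compartment model from [initial_state()] with the
#' stiff-capable `lsoda` solver. In `"jump"` mode each instillation is a
#' `+b` discontinuity on `B` at `m * tau` (applied through solver events);
#' in `"pulse"` mode the triangular forcing is integrated literally, with
#' the integration started at `-epsilon` so the first pulse delivers its
#' full dose.
#'
#' @param params a [model_params()] object.
#' @param schedule a [dose_schedule()].
#' @param t_end end of the simulation in hours; defaults to `N * tau`.
#' @param times optional output time grid; defaults to hourly output plus
#'   all dose times.
#' @param rtol,atol solver tolerances; `atol` defaults to `1e-6` of each
#'   compartment's characteristic scale.
#' @return A `bcg_trajectory`: a data frame with columns
#'   `time, B, E, T_i, T_u, H_u, H_i`. States are clipped to 0 on output;
#'   an excursion below `-10 * atol` is an error.
#' @export
#' @examples
#' traj <- simulate_treatment(model_params(T0 = 1e6), dose_schedule())
#' tumor_burden(traj, 1008)
simulate_treatment <- function(params, schedule, t_end = NULL, times = NULL,
                               rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(schedule, "dose_schedule"))
  validate_model_params(params)
  if (is.null(t_end)) t_end <- schedule$n_doses * schedule$tau
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (is.null(atol)) atol <- state_atol(params)
  y0 <- initial_state(params)
  dtimes <- dose_times(schedule)
  dtimes <- dtimes[dtimes <= t_end]
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, t_end, by = min(1, t_end / 200)),
                           dtimes, t_end)))
  } else {
    times <- sort(unique(c(times, dtimes[dtimes >= min(times)])))
  }

  if (schedule$mode == "jump") {
    events <- list(data = data.frame(var = "B", time = dtimes,
                                     value = schedule$b, method = "add"))
    out <- deSolve::ode(y = y0, times = times, func = "derivs6",
                        parms = parms_vector(params, schedule, FALSE),
                        dllname = "bcgdyn", initfunc = "initmod6",
                        method = "lsoda", rtol = rtol, atol = atol,
                        events = events)
  } else {
    # start at -epsilon so pulse 0 (support [-eps, eps]) is fully integrated
    times2 <- sort(unique(c(-schedule$epsilon, times)))
    out <- deSolve::ode(y = y0, times = times2, func = "derivs6",
                        parms = parms_vector(params, schedule, TRUE),
                        dllname = "bcgdyn", initfunc = "initmod6",
                        method = "lsoda", rtol = rtol, atol = atol,
                        hmax = schedule$epsilon / 2)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  }
  as_trajectory(out, params)
}

# Integrate a whole patient group (shared parameters, individual presenting
# burdens) as one stacked system; returns final tumor burdens. Jump-mode
# dosing. This is the fitting hot path.
batch_outcomes <- function(params, T0s, schedule, t_f, rtol = 1e-8) {
  np <- length(T0s)
  if (any(T0s <= 0) || any(T0s >= params$H_m)) {
    stop("presenting burdens must satisfy 0 < T0 < H_m", call. = FALSE)
  }
  y0 <- as.vector(vapply(T0s, function(T0) {
    c(0, params$e0, 0, T0, params$H_m - T0, 0)
  }, numeric(6)))
  names(y0) <- paste0(rep(STATE_NAMES, np), ".", rep(seq_len(np), each = 6))
  dt <- dose_times(schedule)
  dt <- dt[dt <= t_f]
  times <- sort(unique(c(0, dt, t_f)))
  atol <- rep(state_atol(update_params(params, T0 = mean(T0s))), np)
  ev <- expand.grid(var = seq(1, 6 * np, by = 6), time = dt)
  events <- list(data = data.frame(var = ev$var, time = ev$time,
                                   value = schedule$b, method = "add"))
  out <- deSolve::ode(y = y0, times = times, func = "derivs6b",
                      parms = parms_vector(params, schedule, FALSE),
                      dllname = "bcgdyn", initfunc = "initmod6",
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed in batched integration", call. = FALSE)
  }
  last <- matrix(out[nrow(out), -1], nrow = 6)
  if (min(last) < -10 * max(atol)) {
    stop("batched integration produced negative states", call. = FALSE)
  }
  pmax(last[3, ] + last[4, ], 0)
}

# Batched legacy counterpart (continuous instillation, 4 compartments).
batch_outcomes_legacy <- function(params, T0s, t_f, rtol = 1e-8) {
  np <- length(T0s)
  y0 <- as.vector(vapply(T0s, function(T0) {
    c(0, params$e0, 0, T0)
  }, numeric(4)))
  atol <- rep(1e-6 * pmax(c(1, params$e0, mean(T0s), mean(T0s)), 1), np)
  pv <- c(params$p1, params$p2, params$p3, params$p4, params$p5,
          params$mu1, params$mu2, params$alpha, params$lambda, params$b)
  out <- deSolve::ode(y = y0, times = c(0, t_f), func = "derivs4b",
                      parms = pv, dllname = "bcgdyn", initfunc = "initmod4",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed in batched legacy integration", call. = FALSE)
  }
  last <- matrix(out[nrow(out), -1], nrow = 4)
  if (min(last) < -10 * max(atol)) {
    stop("batched legacy integration produced negative states", call. = FALSE)
  }
  pmax(last[3, ] + last[4, ], 0)
}

#' Simulate the legacy continuous-instillation model
#'
#' @param params a [legacy_params()] object.
#' @param init optional initial state `(B, E, T_i, T_u)`; defaults to
#'   `(0, e0, 0, T0)`.
#' @param t_end end time in hours.
#' @param times optional output grid.
#' @param rtol,atol solver tolerances.
#' @return A data frame of class `bcg_trajectory_legacy` with columns
#'   `time, B, E, T_i, T_u`.
#' @export
simulate_legacy <- function(params, init = NULL, t_end, times = NULL,
                            rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(params, "bcg_legacy_params"))
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (is.null(init)) init <- c(0, params$e0, 0, params$T0)
  init <- setNames(as.numeric(init), c("B", "E", "T_i", "T_u"))
  if (is.null(atol)) {
    atol <- 1e-6 * pmax(c(1, params$e0, params$T0, params$T0), 1)
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  times <- sort(unique(c(times, t_end)))
  pv <- c(params$p1, params$p2, params$p3, params$p4, params$p5,
          params$mu1, params$mu2, params$alpha, params$lambda, params$b)
  out <- deSolve::ode(y = init, times = times, func = "derivs4",
                      parms = pv, dllname = "bcgdyn", initfunc = "initmod4",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time", "B", "E", "T_i", "T_u")
  for (j in 2:5) {
    if (min(traj[[j]]) < -10 * max(atol)) {
      stop("integration produced negative states beyond tolerance",
           call. = FALSE)
    }
    traj[[j]][traj[[j]] < 0] <- 0
  }
  class(traj) <- c("bcg_trajectory_legacy", "data.frame")
  traj
}

#' Tumor burden along a trajectory
#'
#' The clinically observed quantity: total cancer-cell count
#' `T_i(t) + T_u(t)`, interpolated linearly between stored time points.
#'
#' @param traj a trajectory from [simulate_treatment()] or
#'   [simulate_legacy()].
#' @param t time(s) within the trajectory span (hours).
#' @return Tumor burden in cells at each requested time.
#' @export
tumor_burden <- function(traj, t) {
  if (any(t < min(traj$time)) || any(t > max(traj$time))) {
    stop("time outside trajectory span [", min(traj$time), ", ",
         max(traj$time), "]", call. = FALSE)
  }
  total <- traj$T_i + traj$T_u
  approx(traj$time, total, xout = t, ties = "ordered")$y
}

#' @export
print.bcg_trajectory <- function(x, ...) {
  cat(sprintf("BCG treatment trajectory: %d time points over [%g, %g] h\n",
              nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  final tumor burden: %.4g cells\n",
              x$T_i[nrow(x)] + x$T_u[nrow(x)]))
  invisible(x)
}
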