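#' Model parameters for the six-compartment BCG treatment model
#'
#' Constructs and validates the full rate-constant set of the impulsive
#' six-compartment model. Rates are per hour; cell quantities are absolute
#' counts. The protocol constants shipped as defaults follow the standard
#' weekly induction course: BCG decay `mu_B = 4.16e-3` per hour and bladder
#' capacity `H_m = 1.84e9` cells; see [dose_schedule()] for the dosing
#' constants.
#'
#' The interaction rates are:
#' * `p1` BCG neutralisation by effector cells (APC uptake),
#' * `p2` BCG infection of uninfected cancer cells,
#' * `p3` effector killing of cancer cells (infected and uninfected alike),
#' * `p4` effector activation by intravesical BCG,
#' * `p5` effector loss while destroying infected cancer cells,
#' * `p6` effector loss while destroying infected healthy cells,
#' * `p7` logistic regrowth rate of healthy urothelium,
#' * `p8` BCG infection of healthy cells,
#' * `p9` effector killing of infected healthy cells.
#'
#' `mu_E` is the effector decay rate, `alpha` the effector recruitment rate
#' per infected (cancer or healthy) cell, `lambda` the tumor growth rate,
#' `e0` the effector level at treatment start and `T0` the initial tumor
#' cell count. All parameters are treated as constants within one patient
#' and personalized across socio-demographic groups.
#'
#' @param p1,p2,p3,p4,p5,p6,p7,p8,p9 interaction rates (non-negative).
#' @param mu_B,mu_E decay rates per hour (non-negative).
#' @param alpha effector recruitment rate per infected cell.
#' @param lambda tumor growth rate per hour.
#' @param H_m bladder carrying capacity in cells (> 0).
#' @param e0 initial effector-cell count (> 0 for a valid initial state).
#' @param T0 initial tumor-cell count (must not exceed `H_m`).
#' @return An object of class `bcg_params` (named list).
#' @seealso [initial_state()], [simulate_treatment()], [legacy_params()]
#' @export
#' @examples
#' pars <- model_params(lambda = 2e-3, T0 = 1e6)
#' pars$H_m
model_params <- function(p1 = 1.25e-10,
                         p2 = 2.85e-9,
                         p3 = 1.1e-9,
                         p4 = 1.25e-10,
                         p5 = 3.5e-10,
                         p6 = 3.5e-10,
                         p7 = 1.0e-3,
                         p8 = 1.0e-12,
                         p9 = 1.1e-9,
                         mu_B = 4.16e-3,
                         mu_E = 5.0e-3,
                         alpha = 8.0e-3,
                         lambda = 2.0e-3,
                         H_m = 1.84e9,
                         e0 = 1e3,
                         T0 = 1e6) {
  pars <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6,
               p7 = p7, p8 = p8, p9 = p9, mu_B = mu_B, mu_E = mu_E,
               alpha = alpha, lambda = lambda, H_m = H_m, e0 = e0, T0 = T0)
  validate_model_params(pars)
  structure(pars, class = "bcg_params")
}

validate_model_params <- function(pars) {
  vals <- unlist(pars)
  if (!all(is.finite(vals))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  rates <- vals[setdiff(names(vals), c("H_m", "e0", "T0"))]
  if (any(rates < 0)) {
    stop("model rates must be non-negative: ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  }
  if (pars$H_m <= 0) stop("H_m must be positive", call. = FALSE)
  if (pars$T0 < 0 || pars$T0 > pars$H_m) {
    stop("T0 must lie in [0, H_m]", call. = FALSE)
  }
  invisible(pars)
}

#' @export
print.bcg_params <- function(x, ...) {
  cat("Six-compartment BCG model parameters (per hour / cells):\n")
  print(unlist(x))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `pars` with the named values replaced, revalidated.
#'
#' @param pars a [model_params()] object.
#' @param ... named replacement values.
#' @return A `bcg_params` object.
#' @export
update_params <- function(pars, ...) {
  repl <- list(...)
  if (length(repl) == 1L && is.list(repl[[1]]) && is.null(names(repl))) {
    repl <- repl[[1]]
  }
  unknown <- setdiff(names(repl), names(pars))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pars[names(repl)] <- repl
  validate_model_params(pars)
  structure(pars, class = "bcg_params")
}

#' Parameters of the legacy continuous-instillation model
#'
#' The four-compartment predecessor model (`B`, `E`, `T_i`, `T_u`) in which
#' BCG is instilled continuously at rate `b` (units per hour) rather than as
#' discrete pulses, and uninfected cancer cells are not attacked by effector
#' cells. `mu1` and `mu2` are the BCG and effector decay rates.
#'
#' @param p1,p2,p3,p4,p5 interaction rates (non-negative), with the same
#'   meanings as in [model_params()] where shared.
#' @param mu1,mu2 BCG and effector decay rates per hour.
#' @param alpha effector recruitment rate per infected cancer cell.
#' @param lambda tumor growth rate per hour.
#' @param b continuous BCG instillation rate (units per hour).
#' @param e0,T0 initial effector and tumor cell counts.
#' @return An object of class `bcg_legacy_params`.
#' @export
legacy_params <- function(p1 = 1.25e-10,
                          p2 = 2.85e-9,
                          p3 = 1.1e-9,
                          p4 = 1.25e-10,
                          p5 = 3.5e-10,
                          mu1 = 4.16e-3,
                          mu2 = 5.0e-3,
                          alpha = 8.0e-3,
                          lambda = 2.0e-3,
                          b = 2.8e6 / 168,
                          e0 = 1e3,
                          T0 = 1e6) {
  pars <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
               mu1 = mu1, mu2 = mu2, alpha = alpha, lambda = lambda,
               b = b, e0 = e0, T0 = T0)
  vals <- unlist(pars)
  if (!all(is.finite(vals))) stop("legacy parameters must be finite", call. = FALSE)
  if (any(vals < 0)) {
    stop("legacy parameters must be non-negative: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  structure(pars, class = "bcg_legacy_params")
}

#' Instillation schedule
#'
#' Describes the pulsed BCG administration: `N` instillations of `b` BCG
#' units each, one every `tau` hours starting at time 0. Two numerical
#' administration modes are supported: `"jump"` applies each dose as a state
#' discontinuity (+`b` on the `B` compartment, integration restarted), and
#' `"pulse"` uses the triangular epsilon-approximation of the Dirac delta —
#' a unit-integral triangle of half-width `epsilon` hours centred on each
#' dose time. The two agree as `epsilon` shrinks; `"jump"` is the default
#' because it avoids driving the stiff solver through `1/epsilon`-peaked
#' forcing.
#'
#' @param b dose per instillation, BCG units (default the standard
#'   protocol dose 2.8e6).
#' @param n_doses number of instillations `N` (>= 1; default 6).
#' @param tau inter-dose interval in hours (default 168, i.e. weekly).
#' @param epsilon pulse half-width in hours; must satisfy
#'   `0 < epsilon < tau/2` (default 0.5).
#' @param mode `"jump"` or `"pulse"`.
#' @return An object of class `dose_schedule`.
#' @export
#' @examples
#' sched <- dose_schedule()
#' dose_times(sched)
dose_schedule <- function(b = 2.8e6, n_doses = 6L, tau = 168,
                          epsilon = 0.5, mode = c("jump", "pulse")) {
  mode <- match.arg(mode)
  if (!is.finite(b) || b < 0) stop("b must be a non-negative number", call. = FALSE)
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= tau / 2) {
    stop("epsilon must satisfy 0 < epsilon < tau/2", call. = FALSE)
  }
  structure(list(b = b, n_doses = n_doses, tau = tau, epsilon = epsilon,
                 mode = mode),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("BCG schedule: %d x %.3g units every %g h (%s mode, eps = %g h)\n",
              x$n_doses, x$b, x$tau, x$mode, x$epsilon))
  invisible(x)
}

#' Instillation times of a schedule
#'
#' @param schedule a [dose_schedule()].
#' @return Numeric vector `(0, tau, ..., (N-1) tau)`.
#' @export
dose_times <- function(schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  (seq_len(schedule$n_doses) - 1) * schedule$tau
}
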