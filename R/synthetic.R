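#' Default socio-demographic sampling weights
#'
#' Per-field marginal frequencies emulating a realistic non-invasive
#' bladder-cancer population: strongly skewed toward older, male and
#' smoking patients, with most patients of normal or over-weight. Group
#' frequencies are the products of the marginals (and hence sum to 1 over
#' the 72 groups), leaving many of the young/underweight cells nearly or
#' exactly empty in finite cohorts, as in real registries.
#'
#' @return Named list of per-field probability vectors.
#' @export
default_profile_weights <- function() {
  lv <- profile_levels()
  list(
    age_group = setNames(c(0.01, 0.03, 0.07, 0.16, 0.30, 0.43), lv$age_group),
    gender = setNames(c(0.25, 0.75), lv$gender),
    smoking = setNames(c(0.40, 0.60), lv$smoking),
    weight_group = setNames(c(0.06, 0.46, 0.48), lv$weight_group)
  )
}

#' Default ground-truth effect tables (the "strong" scenario)
#'
#' Multiplicative socio-demographic effects applied to the baseline
#' parameters when generating virtual patients: smoking raises the tumor
#' growth rate `lambda` (1.5x in smokers); age accelerates effector decay
#' `mu_E` (immunosenescence, up to 1.5x in the oldest group); weight
#' scales the bladder capacity `H_m`; gender offsets the effector
#' recruitment rate `alpha`. All multipliers are positive; a table of all
#' ones gives a homogeneous cohort.
#'
#' @return Nested named list: field -> parameter -> per-level multiplier.
#' @export
default_effects <- function() {
  lv <- profile_levels()
  list(
    smoking = list(lambda = c("non-smoker" = 1, "smoker" = 1.5)),
    age_group = list(mu_E = setNames(c(1, 1.05, 1.1, 1.2, 1.35, 1.5),
                                     lv$age_group)),
    weight_group = list(H_m = c(underweight = 0.85, normal = 1,
                                overweight = 1.15)),
    gender = list(alpha = c(female = 1.15, male = 1))
  )
}

#' Ground truth for virtual-cohort generation
#'
#' Bundles everything the generator needs: the baseline parameter set,
#' multiplicative per-field effect tables, the multiplicative lognormal
#' measurement-noise level on observed burdens, per-field sampling
#' weights, and the presenting tumor-burden range (log-uniform).
#'
#' @param baseline a [model_params()] object.
#' @param effects effect tables as in [default_effects()].
#' @param sigma lognormal noise standard deviation (>= 0; default 0.1).
#' @param weights per-field sampling weights as in
#'   [default_profile_weights()].
#' @param t_start_range presenting tumor burden range in cells (log-uniform).
#' @return An object of class `bcg_ground_truth`.
#' @export
ground_truth <- function(baseline = model_params(),
                         effects = default_effects(),
                         sigma = 0.1,
                         weights = default_profile_weights(),
                         t_start_range = c(1e4, 1e7)) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  lv <- profile_levels()
  for (f in names(effects)) {
    if (!f %in% PROFILE_FIELDS) stop("unknown effect field: ", f, call. = FALSE)
    for (par in names(effects[[f]])) {
      mult <- effects[[f]][[par]]
      if (!all(lv[[f]] %in% names(mult))) {
        stop("effect table ", f, "/", par, " must cover all levels",
             call. = FALSE)
      }
      if (any(mult <= 0)) {
        stop("effect multipliers must be positive (", f, "/", par, ")",
             call. = FALSE)
      }
    }
  }
  for (f in PROFILE_FIELDS) {
    w <- weights[[f]]
    if (is.null(w) || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("weights for ", f, " must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (t_start_range[1] <= 0 || t_start_range[2] < t_start_range[1]) {
    stop("invalid t_start_range", call. = FALSE)
  }
  structure(list(baseline = baseline, effects = effects, sigma = sigma,
                 weights = weights, t_start_range = t_start_range),
            class = "bcg_ground_truth")
}

#' Sample socio-demographic profiles
#'
#' Draws `n` profiles independently per field from the weighted
#' categorical vocabularies; deterministic under `seed`.
#'
#' @param n number of profiles (>= 1).
#' @param weights per-field probability vectors.
#' @param seed integer seed.
#' @return A `patient_profile` data frame with `n` rows.
#' @export
sample_profiles <- function(n, weights = default_profile_weights(),
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lv <- profile_levels()
  set.seed(seed)
  cols <- lapply(PROFILE_FIELDS, function(f) {
    w <- weights[[f]]
    if (is.null(w) || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("weights for ", f, " must be non-negative and sum to 1",
           call. = FALSE)
    }
    sample(lv[[f]], n, replace = TRUE, prob = w[lv[[f]]])
  })
  names(cols) <- PROFILE_FIELDS
  prof <- as.data.frame(cols, stringsAsFactors = FALSE)
  class(prof) <- c("patient_profile", "data.frame")
  prof
}

#' Personalize baseline parameters for one profile
#'
#' Applies each field's multiplicative effect to the baseline parameter
#' set; deterministic. With all-unit effect tables the baseline is
#' returned unchanged.
#'
#' @param truth a [ground_truth()] object.
#' @param profile a single-row profile data frame.
#' @return A `bcg_params` object.
#' @export
personalize_params <- function(truth, profile) {
  stopifnot(inherits(truth, "bcg_ground_truth"))
  validate_profiles(profile)
  pars <- truth$baseline
  for (f in names(truth$effects)) {
    level <- profile[[f]][1]
    for (par in names(truth$effects[[f]])) {
      pars[[par]] <- pars[[par]] * truth$effects[[f]][[par]][[level]]
    }
  }
  validate_model_params(pars)
  structure(pars, class = "bcg_params")
}

#' Generate a virtual patient cohort
#'
#' Emulates the structure of two-timepoint clinical BCG data: for each
#' sampled profile a presenting tumor burden is drawn log-uniformly,
#' parameters are personalized by the ground-truth effect tables, the
#' six-compartment model is simulated over the full course
#' (`t_f = N * tau`), and the observed final burden is the noise-free
#' simulated burden times a lognormal factor `exp(N(0, sigma^2))`. The
#' hidden per-patient true parameters and noise-free outcomes are retained
#' for testing.
#'
#' @param truth a [ground_truth()] object.
#' @param n cohort size.
#' @param seed integer seed (drives profiles, burdens and noise).
#' @param schedule a [dose_schedule()]; also supplies `t_f = N * tau`.
#' @return A `bcg_synthetic_cohort`: list with `records` (a `bcg_cohort`
#'   data frame), `truth`, `true_params` (per-patient list) and
#'   `noise_free` (per-patient noise-free final burdens).
#' @export
#' @examples
#' syn <- generate_cohort(ground_truth(sigma = 0), n = 5, seed = 42)
#' syn$records$T_end_cells
generate_cohort <- function(truth, n, seed = 1L,
                            schedule = dose_schedule()) {
  stopifnot(inherits(truth, "bcg_ground_truth"))
  profiles <- sample_profiles(n, truth$weights, seed = seed)
  # continue the seeded stream for burdens and noise
  lr <- log(truth$t_start_range)
  t_starts <- exp(runif(n, lr[1], lr[2]))
  noise <- exp(rnorm(n, 0, truth$sigma))
  t_f <- schedule$n_doses * schedule$tau

  true_params <- vector("list", n)
  noise_free <- numeric(n)
  gid <- group_of(profiles)
  for (g in unique(gid)) {  # one batched integration per profile group
    ix <- which(gid == g)
    pars_g <- personalize_params(truth, profiles[ix[1], , drop = FALSE])
    noise_free[ix] <- tryCatch(
      batch_outcomes(pars_g, t_starts[ix], schedule, t_f),
      error = function(e) {
        stop("simulation failed for patient(s) ",
             paste(head(ix, 3), collapse = ", "), ": ",
             conditionMessage(e), call. = FALSE)
      })
    for (i in ix) {
      true_params[[i]] <- update_params(pars_g, T0 = t_starts[i])
    }
  }
  records <- data.frame(patient_id = seq_len(n), profiles,
                        T_start_cells = t_starts,
                        T_end_cells = noise_free * noise,
                        t_f_hours = t_f,
                        b = schedule$b, N = schedule$n_doses,
                        tau = schedule$tau,
                        stringsAsFactors = FALSE)
  class(records) <- c("bcg_cohort", "data.frame")
  structure(list(records = records, truth = truth,
                 true_params = true_params, noise_free = noise_free,
                 seed = seed),
            class = "bcg_synthetic_cohort")
}

#' @export
print.bcg_synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic BCG cohort: %d patients, %d occupied groups, sigma = %g\n",
              nrow(x$records), length(unique(group_of(x$records))),
              x$truth$sigma))
  invisible(x)
}
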