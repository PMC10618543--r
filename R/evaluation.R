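#' Predicted burdens from any fitted model
#'
#' Common prediction surface for the three fitted-model flavours compared
#' by [compare_models()]: the personalized fit, the pooled
#' (no-socio-demographics) fit, and the legacy continuous-instillation
#' fit.
#'
#' @param model a fitted model object.
#' @param records a cohort data frame.
#' @return Numeric vector of predicted final tumor burdens.
#' @export
predict_burden <- function(model, records) {
  UseMethod("predict_burden")
}

#' @export
predict_burden.bcg_fit <- function(model, records) {
  predict(model, records)
}

#' @export
predict_burden.bcg_legacy_fit <- function(model, records) {
  preds <- rep(NA_real_, nrow(records))
  for (tf in unique(records$t_f_hours)) {
    ix <- which(records$t_f_hours == tf)
    preds[ix] <- batch_outcomes_legacy(model$params,
                                       records$T_start_cells[ix], tf)
  }
  preds
}

#' Evaluate a fitted model on a cohort
#'
#' Computes the overall RMAE and its breakdown over the 72
#' socio-demographic groups. Groups with no evaluation patients are kept
#' in the table with `NA` error and `n = 0` (the unassessable cells of a
#' per-group error map); marginal RMAEs per category level are also
#' returned.
#'
#' @param model a fitted model usable with [predict_burden()].
#' @param records a non-empty cohort data frame.
#' @return A `bcg_evaluation` list: `overall` (RMAE), `by_group` (72-row
#'   data frame: group labels, `n`, `rmae`), `by_level` (long data frame
#'   of marginal RMAEs), and `errors` (per-patient).
#' @export
evaluate_model <- function(model, records) {
  if (NROW(records) == 0) stop("no evaluation records", call. = FALSE)
  preds <- predict_burden(model, records)
  errs <- abs(preds - records$T_end_cells) / records$T_end_cells
  groups <- enumerate_groups()
  gid <- group_of(records)
  groups$n <- as.integer(tabulate(gid, nbins = 72))
  groups$rmae <- vapply(seq_len(72), function(g) {
    if (groups$n[g] == 0) NA_real_ else mean(errs[gid == g])
  }, numeric(1))
  by_level <- do.call(rbind, lapply(PROFILE_FIELDS, function(f) {
    lv <- profile_levels()[[f]]
    data.frame(field = f, level = lv,
               n = vapply(lv, function(l) sum(records[[f]] == l), integer(1)),
               rmae = vapply(lv, function(l) {
                 ix <- records[[f]] == l
                 if (!any(ix)) NA_real_ else mean(errs[ix])
               }, numeric(1)),
               row.names = NULL)
  }))
  structure(list(overall = mean(errs), by_group = groups,
                 by_level = by_level, errors = errs),
            class = "bcg_evaluation")
}

#' @export
print.bcg_evaluation <- function(x, ...) {
  cat(sprintf("Model evaluation: overall RMAE %.3f over %d patients (%d groups present)\n",
              x$overall, length(x$errors), sum(x$by_group$n > 0)))
  invisible(x)
}

#' Fit the pooled (no socio-demographics) variant
#'
#' The same three-step procedure with every patient pooled into a single
#' group and the socio-demographic features excluded from the pipelines;
#' only the presenting burden remains as a feature. This is the ablation
#' baseline that isolates the value of personalization.
#'
#' @param cohort a cohort data frame.
#' @param config a [fit_config()]; `use_socio` is forced off.
#' @return A `bcg_fit` object.
#' @export
fit_no_socio <- function(cohort, config = fit_config()) {
  config$use_socio <- FALSE
  fit_bcg(cohort, config)
}

#' Fit the legacy continuous-instillation model
#'
#' Gradient-descent fit of the four-compartment predecessor model (single
#' pooled group, continuous instillation at rate `b/tau`) with the same
#' RMAE loss, stencil gradients, log-space parameterization and bounds as
#' [gd_fit()].
#'
#' @param cohort a cohort data frame.
#' @param config a [fit_config()]; `free` entries among
#'   `p1..p5, mu2 (as mu_E), alpha, lambda, e0` are honoured (others are
#'   not part of the legacy model and are ignored).
#' @param init optional starting [legacy_params()].
#' @return A `bcg_legacy_fit` (fields `params`, `loss`, `trace`).
#' @export
fit_legacy <- function(cohort, config = fit_config(), init = NULL) {
  validate_cohort(cohort)
  if (is.null(init)) {
    b_rate <- mean(cohort$b / cohort$tau)  # same average dose per interval
    init <- legacy_params(b = b_rate,
                          mu2 = config$init$mu_E,
                          alpha = config$init$alpha,
                          lambda = config$init$lambda,
                          p1 = config$init$p1, p2 = config$init$p2,
                          p3 = config$init$p3, p4 = config$init$p4,
                          p5 = config$init$p5, e0 = config$init$e0)
  }
  name_map <- c(p1 = "p1", p2 = "p2", p3 = "p3", p4 = "p4", p5 = "p5",
                mu_E = "mu2", alpha = "alpha", lambda = "lambda", e0 = "e0")
  free6 <- intersect(config$free, names(name_map))
  if (!length(free6)) stop("no legacy-fittable free parameters", call. = FALSE)
  free <- unname(name_map[free6])
  lower_log <- log(pmax(config$lower[free6], 1e-300))
  upper_log <- log(config$upper[free6])
  set.seed(config$seed)

  loss <- function(theta_log) {
    pars <- init
    pars[free] <- as.list(exp(theta_log))
    preds <- rep(NA_real_, nrow(cohort))
    for (tf in unique(cohort$t_f_hours)) {
      ix <- which(cohort$t_f_hours == tf)
      preds[ix] <- tryCatch(
        batch_outcomes_legacy(pars, cohort$T_start_cells[ix], tf),
        error = function(e) rep(NA_real_, length(ix)))
    }
    if (any(!is.finite(preds))) return(Inf)
    rmae(preds, cohort$T_end_cells)
  }
  theta0 <- pmin(pmax(log(unlist(init[free])), lower_log), upper_log)
  best <- NULL
  for (r in seq_len(max(1L, config$n_restarts))) {
    start <- if (r == 1) theta0 else theta0 + runif(length(theta0), -1, 1)
    res <- gd_descend(loss, start, lower_log, upper_log, config,
                      config$gd_max_iter)
    if (is.null(best) || res$loss < best$loss) best <- res
  }
  out <- init
  out[free] <- as.list(exp(best$theta))
  structure(list(params = structure(out, class = "bcg_legacy_params"),
                 loss = best$loss, trace = best$trace, free = free),
            class = "bcg_legacy_fit")
}

#' Three-way model comparison
#'
#' Reproduces the evaluation design of the model comparison: an
#' evaluation subset of `n_samples` records with pairwise-distinct
#' socio-demographic profiles is drawn (seeded); each model's per-sample
#' absolute relative errors are computed; a one-way ANOVA tests for any
#' difference between models, followed by one-tailed paired t-tests for
#' every ordered pair (alternative: the row model's errors are smaller
#' than the column model's). The winner is the model with the lowest mean
#' error if it beats every other model at level `alpha`.
#'
#' @param models named list of >= 2 fitted models ([predict_burden()]
#'   surface).
#' @param records a cohort with at least `n_samples` distinct profiles
#'   (fewer triggers a warning and uses all distinct profiles).
#' @param n_samples evaluation subset size (default 50).
#' @param alpha significance level.
#' @param seed integer seed for the subset draw.
#' @return A `bcg_comparison` list: `summary` (per-model mean, sd, n),
#'   `anova_F`, `anova_p`, `pairwise_p` (matrix of one-tailed p-values),
#'   `winner` (name or `NA`), `errors` (matrix), `sample_ids`.
#' @export
compare_models <- function(models, records, n_samples = 50L, alpha = 0.05,
                           seed = 1L) {
  if (length(models) < 2) stop("need at least two models", call. = FALSE)
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be named", call. = FALSE)
  }
  validate_cohort(records)
  set.seed(seed)
  gid <- group_of(records)
  # one record per distinct profile, sampled; then subsample the profiles
  reps <- vapply(split(seq_len(nrow(records)), gid), function(ix) {
    if (length(ix) == 1L) ix else sample(ix, 1L)
  }, integer(1))
  if (length(reps) < n_samples) {
    warning("only ", length(reps), " distinct profiles available; using all",
            call. = FALSE)
    chosen <- reps
  } else {
    chosen <- sample(reps, n_samples)
  }
  eval_set <- records[chosen, , drop = FALSE]
  errors <- vapply(models, function(m) {
    preds <- predict_burden(m, eval_set)
    abs(preds - eval_set$T_end_cells) / eval_set$T_end_cells
  }, numeric(nrow(eval_set)))
  errors <- matrix(errors, ncol = length(models),
                   dimnames = list(NULL, names(models)))

  long <- data.frame(error = as.vector(errors),
                     model = factor(rep(names(models),
                                        each = nrow(errors)),
                                    levels = names(models)))
  fit_aov <- aov(error ~ model, data = long)
  tab <- summary(fit_aov)[[1]]
  anova_F <- tab[["F value"]][1]
  anova_p <- tab[["Pr(>F)"]][1]

  nm <- names(models)
  pairwise_p <- matrix(NA_real_, length(nm), length(nm),
                       dimnames = list(nm, nm))
  for (a in nm) {
    for (b in setdiff(nm, a)) {
      ht <- tryCatch(t.test(errors[, a], errors[, b], paired = TRUE,
                            alternative = "less"),
                     error = function(e) NULL)
      pairwise_p[a, b] <- if (is.null(ht)) NA_real_ else ht$p.value
    }
  }
  means <- colMeans(errors)
  best <- nm[which.min(means)]
  beats_all <- all(pairwise_p[best, setdiff(nm, best)] < alpha, na.rm = FALSE)
  winner <- if (isTRUE(beats_all)) best else NA_character_
  summary_df <- data.frame(model = nm, mean_rmae = means,
                           sd = apply(errors, 2, sd),
                           n = nrow(errors), row.names = NULL)
  structure(list(summary = summary_df, anova_F = anova_F, anova_p = anova_p,
                 pairwise_p = pairwise_p, winner = winner, errors = errors,
                 sample_ids = eval_set$patient_id),
            class = "bcg_comparison")
}

#' @export
print.bcg_comparison <- function(x, ...) {
  cat("Model comparison on", nrow(x$errors), "unique-profile samples:\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s RMAE %.3f +/- %.3f\n", s$model[i], s$mean_rmae[i],
                s$sd[i]))
  }
  cat(sprintf("  ANOVA F = %.2f, p = %.3g; winner: %s\n", x$anova_F,
              x$anova_p, ifelse(is.na(x$winner), "none", x$winner)))
  invisible(x)
}

#' Socio-demographic contrasts of model errors
#'
#' Tests whether per-patient model errors differ across the levels of
#' each socio-demographic field: two-tailed two-sample t-tests for the
#' binary fields (smoking, gender) and one-way ANOVA with post-hoc Tukey
#' pairwise comparisons for weight and age. Levels with fewer than two
#' patients are excluded with a warning.
#'
#' @param errors per-patient absolute relative errors.
#' @param profiles aligned data frame with the four profile columns.
#' @param alpha significance level used for the `significant` flag.
#' @return A data frame with one row per test (or Tukey pair): `field`,
#'   `test`, `contrast`, `statistic`, `p_value`, `significant`.
#' @export
group_contrasts <- function(errors, profiles, alpha = 0.05) {
  validate_profiles(profiles)
  if (length(errors) != nrow(profiles)) {
    stop("errors and profiles must align", call. = FALSE)
  }
  rows <- list()
  add <- function(field, test, contrast, statistic, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      field = field, test = test, contrast = contrast,
      statistic = statistic, p_value = p, significant = !is.na(p) & p < alpha)
  }
  prune <- function(field) {
    counts <- table(profiles[[field]])
    keep_lv <- names(counts)[counts >= 2]
    dropped <- setdiff(names(counts), keep_lv)
    if (length(dropped)) {
      warning("excluding ", field, " level(s) with < 2 patients: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    profiles[[field]] %in% keep_lv
  }
  for (field in c("smoking", "gender")) {
    keep <- prune(field)
    lv <- unique(profiles[[field]][keep])
    if (length(lv) < 2) {
      add(field, "t-test", paste(lv, collapse = " vs "), NA_real_, NA_real_)
      next
    }
    x <- errors[keep & profiles[[field]] == lv[1]]
    y <- errors[keep & profiles[[field]] == lv[2]]
    ht <- t.test(x, y, alternative = "two.sided")
    add(field, "t-test", paste(sort(lv), collapse = " vs "),
        unname(ht$statistic), ht$p.value)
  }
  for (field in c("weight_group", "age_group")) {
    keep <- prune(field)
    f <- factor(profiles[[field]][keep],
                levels = profile_levels()[[field]])
    f <- droplevels(f)
    if (nlevels(f) < 2) {
      add(field, "anova", "all", NA_real_, NA_real_)
      next
    }
    e <- errors[keep]
    fit <- aov(e ~ f)
    tab <- summary(fit)[[1]]
    add(field, "anova", "all", tab[["F value"]][1], tab[["Pr(>F)"]][1])
    tk <- TukeyHSD(fit)$f
    for (i in seq_len(nrow(tk))) {
      add(field, "tukey", rownames(tk)[i], tk[i, "diff"], tk[i, "p adj"])
    }
  }
  do.call(rbind, rows)
}
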