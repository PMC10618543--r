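FITTABLE_PARAMS <- c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9",
                     "mu_E", "alpha", "lambda", "e0")

#' Relative mean absolute error
#'
#' The fitting loss and headline evaluation metric: the mean over patients
#' of `|predicted - observed| / observed`, with burdens as the observed
#' quantity.
#'
#' @param predicted,observed equal-length numeric vectors; `observed` must
#'   be strictly positive.
#' @return A single non-negative number.
#' @export
#' @examples
#' rmae(c(1, 3), c(2, 2))  # 0.5
rmae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("observed burdens must be positive and finite", call. = FALSE)
  }
  mean(abs(predicted - observed) / observed)
}

#' Predicted treatment outcome for one patient
#'
#' Simulates the six-compartment model from the standard initial state
#' under the patient's schedule and returns the tumor burden
#' `T_i(t_f) + T_u(t_f)` at the end of treatment. Either a cohort `record`
#' (one row, supplying `T0`, the schedule and `t_f`) or an explicit
#' `schedule`/`t_f` pair may be given.
#'
#' @param params a [model_params()] object.
#' @param record optional single cohort row.
#' @param schedule optional [dose_schedule()] (ignored when `record` is
#'   given).
#' @param t_f treatment end time in hours (defaults to `N * tau`).
#' @return Final tumor burden in cells.
#' @export
predict_outcome <- function(params, record = NULL, schedule = NULL,
                            t_f = NULL) {
  if (!is.null(record)) {
    schedule <- record_schedule(record)
    t_f <- record$t_f_hours
    params <- update_params(params, T0 = record$T_start_cells)
  }
  if (is.null(schedule)) stop("either record or schedule required", call. = FALSE)
  if (is.null(t_f)) t_f <- schedule$n_doses * schedule$tau
  traj <- simulate_treatment(params, schedule, t_end = t_f,
                             times = c(0, t_f))
  n <- nrow(traj)
  traj$T_i[n] + traj$T_u[n]
}

#' Five-point-stencil gradient
#'
#' Fourth-order central finite-difference gradient of a scalar loss:
#' per coordinate `(-f(x+2h) + 8 f(x+h) - 8 f(x-h) + f(x-2h)) / (12 h)`.
#' Exact for polynomials of degree up to four.
#'
#' @param loss function of a numeric vector returning a finite scalar.
#' @param theta point at which to differentiate.
#' @param h stencil step (default 1e-3).
#' @return Numeric gradient, same length as `theta`.
#' @export
#' @examples
#' stencil_gradient(function(x) x^2, 3)  # exactly 6
stencil_gradient <- function(loss, theta, h = 1e-3) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    shift <- function(d) {
      th <- theta
      th[i] <- th[i] + d
      loss(th)
    }
    vals <- c(shift(2 * h), shift(h), shift(-h), shift(-2 * h))
    if (any(!is.finite(vals))) {
      stop("non-finite loss in stencil evaluation", call. = FALSE)
    }
    g[i] <- (-vals[1] + 8 * vals[2] - 8 * vals[3] + vals[4]) / (12 * h)
  }
  g
}

#' Fitting configuration
#'
#' Collects every tunable of the three-step fitting procedure. Defaults:
#' 5 folds, each fold split 60/20/20 into train/test/validate; gradient
#' descent in log-parameter space with five-point-stencil gradients and
#' per-coordinate adaptive moment scaling (learning rate `gd_step`, at
#' most `gd_max_iter` iterations, 3 seeded restarts, best-seen iterate
#' kept); 20 augmentation samples per round with at most 3 rounds and a
#' paired one-sided t-test gate at `alpha = 0.05`; and the fixed pipeline
#' candidate set of [pipeline_search()].
#'
#' @param k number of folds (>= 2).
#' @param free names of the free (fitted) parameters, a subset of
#'   `p1..p9, mu_E, alpha, lambda, e0`. The protocol constants
#'   (`mu_B`, `b`, `N`, `tau`, `H_m`) are always held fixed.
#' @param init baseline [model_params()] used as the GD starting point
#'   and as the source of the non-fitted parameter values.
#' @param split fractions for train/test/validate (must sum to 1).
#' @param gd_step gradient-descent learning rate in log-space.
#' @param gd_max_iter,gd_refit_iter iteration caps for the initial fit
#'   and the post-augmentation refits.
#' @param gd_tol relative loss-change convergence threshold.
#' @param gd_patience iterations without meaningful improvement before the
#'   descent stops early.
#' @param stencil_h five-point-stencil step in log-space.
#' @param n_restarts number of seeded GD restarts.
#' @param lower,upper named parameter bounds (natural scale).
#' @param n_augment synthetic samples accepted per augmentation round
#'   (0 disables augmentation).
#' @param max_aug_rounds cap on augmentation rounds.
#' @param max_attempt_mult attempt cap per round, as a multiple of
#'   `n_augment`.
#' @param alpha significance level of the augmentation gate.
#' @param knn_grid neighbour counts searched for the gate KNN.
#' @param pipelines candidate pipeline names (see [pipeline_search()]).
#' @param min_group_n minimum training patients for a direct group fit.
#' @param use_socio if `FALSE`, all patients are pooled into one group and
#'   socio-demographic features are excluded from the pipelines.
#' @param seed integer seed governing every random choice of the fit.
#' @return A `bcg_fit_config` list.
#' @export
fit_config <- function(k = 5L,
                       free = FITTABLE_PARAMS,
                       init = model_params(),
                       split = c(train = 0.6, test = 0.2, validate = 0.2),
                       gd_step = 0.1,
                       gd_max_iter = 60L,
                       gd_refit_iter = 20L,
                       gd_tol = 1e-6,
                       gd_patience = 50L,
                       stencil_h = 1e-3,
                       n_restarts = 3L,
                       lower = NULL,
                       upper = NULL,
                       n_augment = 20L,
                       max_aug_rounds = 3L,
                       max_attempt_mult = 50L,
                       alpha = 0.05,
                       knn_grid = c(1L, 3L, 5L, 7L),
                       pipelines = c("global_mean", "group_mean", "linear",
                                     "knn", "forest"),
                       min_group_n = 1L,
                       use_socio = TRUE,
                       seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8 || any(split <= 0)) {
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  }
  bad <- setdiff(free, FITTABLE_PARAMS)
  if (length(bad)) {
    stop("not fittable: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  default_lower <- c(p1 = 1e-15, p2 = 1e-15, p3 = 1e-15, p4 = 1e-15,
                     p5 = 1e-15, p6 = 1e-15, p7 = 1e-15, p8 = 1e-16,
                     p9 = 1e-15, mu_E = 1e-5, alpha = 1e-6,
                     lambda = 1e-6, e0 = 1)
  default_upper <- c(p1 = 1e-5, p2 = 1e-5, p3 = 1e-5, p4 = 1e-5,
                     p5 = 1e-5, p6 = 1e-5, p7 = 1e-1, p8 = 1e-7,
                     p9 = 1e-5, mu_E = 1, alpha = 10,
                     lambda = 0.05, e0 = 1e8)
  if (is.null(lower)) lower <- default_lower
  if (is.null(upper)) upper <- default_upper
  if (any(lower[free] < 0) || any(upper[free] < lower[free])) {
    stop("bounds must be non-negative with upper >= lower", call. = FALSE)
  }
  structure(list(k = as.integer(k), free = free, init = init, split = split,
                 gd_step = gd_step, gd_max_iter = as.integer(gd_max_iter),
                 gd_refit_iter = as.integer(gd_refit_iter), gd_tol = gd_tol,
                 gd_patience = as.integer(gd_patience),
                 stencil_h = stencil_h, n_restarts = as.integer(n_restarts),
                 lower = lower, upper = upper,
                 n_augment = as.integer(n_augment),
                 max_aug_rounds = as.integer(max_aug_rounds),
                 max_attempt_mult = as.integer(max_attempt_mult),
                 alpha = alpha, knn_grid = as.integer(knn_grid),
                 pipelines = pipelines,
                 min_group_n = as.integer(min_group_n),
                 use_socio = isTRUE(use_socio), seed = as.integer(seed)),
            class = "bcg_fit_config")
}

params_from_theta <- function(init, free, theta_log) {
  pars <- init
  pars[free] <- as.list(exp(theta_log))
  structure(pars, class = "bcg_params")
}

# Predict outcomes for many records sharing one parameter set, batching
# the integration per identical schedule. NA on solver failure.
batch_records <- function(params, records) {
  sig <- paste(records$b, records$N, records$tau, records$t_f_hours)
  preds <- rep(NA_real_, nrow(records))
  for (s in unique(sig)) {
    ix <- which(sig == s)
    sched <- record_schedule(records[ix[1], , drop = FALSE])
    preds[ix] <- tryCatch(
      batch_outcomes(params, records$T_start_cells[ix], sched,
                     records$t_f_hours[ix[1]]),
      error = function(e) rep(NA_real_, length(ix)))
  }
  preds
}

cohort_loss <- function(records, init, free) {
  force(records); force(init); force(free)
  function(theta_log) {
    pars <- params_from_theta(init, free, theta_log)
    preds <- batch_records(pars, records)
    if (any(!is.finite(preds))) return(Inf)
    rmae(preds, records$T_end_cells)
  }
}

# Projected gradient descent in log-parameter space with five-point-stencil
# gradients and per-coordinate adaptive moment scaling (Adam-style), which
# copes with the strong parameter collinearity of outcome-only fitting.
# The best-seen iterate is tracked throughout and returned; `trace` records
# the improving (accepted) iterates and is therefore non-increasing.
gd_descend <- function(loss, theta0, lower_log, upper_log, config,
                       max_iter, patience = NULL) {
  if (is.null(patience)) {
    patience <- if (is.null(config$gd_patience)) 50L else config$gd_patience
  }
  clamp <- function(th) pmin(pmax(th, lower_log), upper_log)
  theta <- clamp(theta0)
  cur <- loss(theta)
  best_theta <- theta
  best <- cur
  trace <- cur
  m <- v <- numeric(length(theta))
  last_gain <- 0L
  for (it in seq_len(max_iter)) {
    g <- tryCatch(stencil_gradient(loss, theta, h = config$stencil_h),
                  error = function(e) NULL)
    if (is.null(g)) break
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    mh <- m / (1 - 0.9^it)
    vh <- v / (1 - 0.999^it)
    theta <- clamp(theta - config$gd_step * mh / (sqrt(vh) + 1e-12))
    cur <- loss(theta)
    if (is.finite(cur) && cur < best - config$gd_tol * max(best, 1e-12)) {
      last_gain <- it
    }
    if (is.finite(cur) && cur < best) {
      best <- cur
      best_theta <- theta
      trace <- c(trace, cur)
    }
    if (it - last_gain >= patience) break
  }
  list(theta = best_theta, loss = best, trace = trace)
}

#' Gradient-descent parameter fit for one patient group
#'
#' Minimises the RMAE between simulated and observed final tumor burdens
#' over the free parameters, in log-space with projection to bounds.
#' Gradients come from the five-point stencil; updates use per-coordinate
#' adaptive moment scaling, which handles the strong collinearity between
#' growth and immune rates that outcome-only data induces. The best-seen
#' iterate is tracked and returned, so the accepted-step loss trace is
#' non-increasing. `n_restarts` seeded starts (the supplied `init` plus
#' log-space perturbations) guard against local minima.
#'
#' @param train a non-empty cohort data frame (the training records).
#' @param init starting [model_params()]; also supplies fixed parameters.
#' @param config a [fit_config()].
#' @param max_iter iteration cap (defaults to `config$gd_max_iter`).
#' @return List with `params` (fitted `bcg_params`), `loss` (best train
#'   RMAE) and `trace` (accepted-step losses, non-increasing).
#' @export
gd_fit <- function(train, init = NULL, config = fit_config(),
                   max_iter = NULL) {
  if (is.null(init)) init <- config$init
  if (NROW(train) == 0) stop("empty training set", call. = FALSE)
  if (is.null(max_iter)) max_iter <- config$gd_max_iter
  free <- config$free
  lower_log <- log(pmax(config$lower[free], 1e-300))
  upper_log <- log(config$upper[free])
  loss <- cohort_loss(train, init, free)
  theta0 <- pmin(pmax(log(unlist(init[free])), lower_log), upper_log)
  if (!is.finite(loss(theta0))) {
    stop("loss not finite at the starting parameters", call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(max(1L, config$n_restarts))) {
    start <- if (r == 1) theta0 else theta0 + runif(length(theta0), -1, 1)
    res <- gd_descend(loss, start, lower_log, upper_log, config, max_iter)
    if (is.null(best) || res$loss < best$loss) best <- res
  }
  list(params = params_from_theta(init, free, best$theta),
       loss = best$loss, trace = best$trace)
}

# ---- features ---------------------------------------------------------------

record_features <- function(records, use_socio = TRUE) {
  X <- matrix(log10(records$T_start_cells), ncol = 1,
              dimnames = list(NULL, "log10_T_start"))
  if (use_socio) X <- cbind(encode_features(records), X)
  X
}

group_key <- function(records, use_socio = TRUE) {
  if (use_socio) group_of(records) else rep(1L, NROW(records))
}

# ---- KNN regression (shared by the augmentation gate and a pipeline) --------

knn_scale <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

knn_apply_scale <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
}

knn_predict_raw <- function(Xtr, ytr, Xq, k) {
  k <- min(k, nrow(Xtr))
  pred <- numeric(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    d2 <- colSums((t(Xtr) - Xq[i, ])^2)
    nb <- order(d2)[seq_len(k)]
    pred[i] <- mean(ytr[nb])
  }
  pred
}

#' Optimised nearest-neighbour outcome model
#'
#' KNN regression from patient features to observed final burden, with the
#' neighbour count chosen by leave-one-out relative error over
#' `config$knn_grid`. Used as the acceptance yardstick for synthetic
#' augmentation samples.
#'
#' @param records training cohort.
#' @param config a [fit_config()].
#' @return A `bcg_knn` object with a `$predict(records)` function.
#' @export
fit_knn <- function(records, config = fit_config()) {
  X <- record_features(records, config$use_socio)
  y <- records$T_end_cells
  sc <- knn_scale(X)
  Xs <- knn_apply_scale(X, sc)
  grid <- config$knn_grid[config$knn_grid < nrow(Xs)]
  if (!length(grid)) grid <- 1L
  loo <- vapply(grid, function(k) {
    errs <- vapply(seq_len(nrow(Xs)), function(i) {
      p <- knn_predict_raw(Xs[-i, , drop = FALSE], y[-i],
                           Xs[i, , drop = FALSE], k)
      abs(p - y[i]) / y[i]
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  k_best <- grid[which.min(loo)]
  structure(list(
    k = k_best, loo = setNames(loo, grid),
    predict = function(newrecords) {
      Xq <- knn_apply_scale(record_features(newrecords, config$use_socio), sc)
      knn_predict_raw(Xs, y, Xq, k_best)
    }), class = "bcg_knn")
}

nearest_level <- function(block_values, levels) {
  levels[which.max(block_values)]
}

#' Augment a training set with KNN-gated synthetic samples
#'
#' Draws candidate feature vectors uniformly per column between the
#' training minima and maxima (one-hot coordinates are rounded back to the
#' nearest valid profile), labels each candidate with the current fitted
#' model's simulated outcome, and accepts it only when the model's
#' prediction error on that outcome is lower than an optimised KNN's.
#' Accepted records are appended (column `synthetic = TRUE`); originals
#' are never altered or removed. If the attempt cap is reached first, a
#' warning is issued and the partial augmentation returned.
#'
#' @param train training cohort.
#' @param group_params named list of fitted [model_params()] per group id,
#'   the current model used to label candidates.
#' @param config a [fit_config()].
#' @param knn optional pre-fitted [fit_knn()] model (fitted on `train`
#'   otherwise).
#' @return The augmented cohort data frame.
#' @export
augment_train <- function(train, group_params, config = fit_config(),
                          knn = NULL) {
  if (config$n_augment == 0L) return(train)
  if (NROW(train) == 0) stop("empty training set", call. = FALSE)
  if (is.null(knn)) knn <- fit_knn(train, config)
  if (!"synthetic" %in% names(train)) train$synthetic <- FALSE
  lv <- profile_levels()
  Xoh <- encode_features(train)
  oh_min <- apply(Xoh, 2, min)
  oh_max <- apply(Xoh, 2, max)
  ts_range <- range(train$T_start_cells)
  accepted <- 0L
  attempts <- 0L
  cap <- config$max_attempt_mult * config$n_augment
  rows <- list()
  next_id <- max(train$patient_id) + 1L
  while (accepted < config$n_augment && attempts < cap) {
    attempts <- attempts + 1L
    # uniform draw per feature column, then snap one-hots to a valid profile
    u <- runif(length(oh_min), oh_min, oh_max)
    off <- 0L
    labels <- list()
    for (f in PROFILE_FIELDS) {
      nl <- length(lv[[f]])
      labels[[f]] <- nearest_level(u[off + seq_len(nl)], lv[[f]])
      off <- off + nl
    }
    t_start <- runif(1, ts_range[1], ts_range[2])
    template <- train[sample.int(nrow(train), 1L), , drop = FALSE]
    cand <- template
    cand$patient_id <- next_id
    for (f in PROFILE_FIELDS) cand[[f]] <- labels[[f]]
    cand$T_start_cells <- t_start
    cand$synthetic <- TRUE
    gid <- as.character(group_key(cand, config$use_socio))
    if (!gid %in% names(group_params)) next
    outcome <- tryCatch(
      predict_outcome(group_params[[gid]], record = cand),
      error = function(e) NA_real_)
    if (!is.finite(outcome) || outcome <= 0) next
    cand$T_end_cells <- outcome
    model_err <- 0  # the label is the model's own simulated outcome
    knn_err <- abs(knn$predict(cand) - outcome) / outcome
    if (model_err < knn_err) {
      rows[[length(rows) + 1L]] <- cand
      accepted <- accepted + 1L
      next_id <- next_id + 1L
    }
  }
  if (accepted < config$n_augment) {
    warning("augmentation accepted only ", accepted, " of ",
            config$n_augment, " samples within the attempt cap",
            call. = FALSE)
  }
  if (length(rows)) train <- rbind(train, do.call(rbind, rows))
  rownames(train) <- NULL
  train
}

#' Significance gate for augmented fits
#'
#' Paired one-sided t-test on per-patient absolute relative errors over
#' the held-out test set: the augmented model is accepted only when its
#' errors are significantly smaller than the pre-augmentation model's at
#' level `alpha`. Degenerate inputs (fewer than two patients, or
#' identical error vectors) are rejected with a warning.
#'
#' @param errors_before,errors_after per-patient absolute relative errors
#'   of the models before and after augmentation, on the same test
#'   patients.
#' @param alpha significance level.
#' @return List with `accept` (logical) and `p_value`.
#' @export
significance_gate <- function(errors_before, errors_after, alpha = 0.05) {
  if (length(errors_before) != length(errors_after)) {
    stop("error vectors must have the same length", call. = FALSE)
  }
  if (length(errors_before) < 2) {
    warning("too few test patients for the significance gate; rejecting",
            call. = FALSE)
    return(list(accept = FALSE, p_value = NA_real_))
  }
  d <- errors_after - errors_before
  if (sd(d) < 1e-15) {
    warning("degenerate (all-equal) error differences; rejecting",
            call. = FALSE)
    return(list(accept = FALSE, p_value = NA_real_))
  }
  ht <- t.test(errors_after, errors_before, paired = TRUE,
               alternative = "less")
  list(accept = ht$p.value < alpha, p_value = ht$p.value)
}

# ---- parameter-regression pipelines -----------------------------------------

make_pipelines <- function(config) {
  cands <- list(
    global_mean = function(X, Y, groups) {
      mu <- colMeans(Y)
      function(Xq, groups_q) {
        matrix(mu, nrow(Xq), length(mu), byrow = TRUE,
               dimnames = list(NULL, colnames(Y)))
      }
    },
    group_mean = function(X, Y, groups) {
      mu <- colMeans(Y)
      by_g <- lapply(split(seq_len(nrow(Y)), groups), function(ix) {
        colMeans(Y[ix, , drop = FALSE])
      })
      function(Xq, groups_q) {
        out <- matrix(mu, nrow(Xq), ncol(Y), byrow = TRUE,
                      dimnames = list(NULL, colnames(Y)))
        hit <- as.character(groups_q) %in% names(by_g)
        for (i in which(hit)) out[i, ] <- by_g[[as.character(groups_q[i])]]
        out
      }
    },
    linear = function(X, Y, groups) {
      A <- cbind(1, X)
      beta <- qr.coef(qr(A), Y)
      beta[is.na(beta)] <- 0
      function(Xq, groups_q) {
        out <- cbind(1, Xq) %*% beta
        colnames(out) <- colnames(Y)
        out
      }
    },
    knn = function(X, Y, groups) {
      sc <- knn_scale(X)
      Xs <- knn_apply_scale(X, sc)
      k <- min(5L, nrow(Xs))
      function(Xq, groups_q) {
        Xqs <- knn_apply_scale(Xq, sc)
        out <- matrix(0, nrow(Xqs), ncol(Y), dimnames = list(NULL, colnames(Y)))
        for (i in seq_len(nrow(Xqs))) {
          d2 <- colSums((t(Xs) - Xqs[i, ])^2)
          nb <- order(d2)[seq_len(k)]
          out[i, ] <- colMeans(Y[nb, , drop = FALSE])
        }
        out
      }
    },
    forest = function(X, Y, groups) {
      fits <- lapply(seq_len(ncol(Y)), function(j) {
        randomForest::randomForest(x = X, y = Y[, j], ntree = 150,
                                   nodesize = 3)
      })
      function(Xq, groups_q) {
        out <- vapply(fits, function(f) {
          as.numeric(predict(f, newdata = Xq))
        }, numeric(nrow(Xq)))
        out <- matrix(out, nrow = nrow(Xq), dimnames = list(NULL, colnames(Y)))
        out
      }
    }
  )
  names_wanted <- config$pipelines
  if (!config$use_socio) {
    names_wanted <- setdiff(names_wanted, "group_mean")
  }
  cands[names_wanted]
}

#' Select a parameter-regression pipeline
#'
#' The extrapolation step of the fitting procedure: each candidate
#' pipeline learns the map from patient features (socio-demographic
#' one-hot encoding plus the log presenting burden) to the fitted
#' log-parameters, and candidates are scored by a metric `M` on the
#' validation records — by default the RMAE of the simulated outcome using
#' the pipeline-predicted parameters. The argmin candidate is returned;
#' ties break by candidate order.
#'
#' @param X feature matrix of the training pairs.
#' @param Y matrix of log free-parameter targets (one column per free
#'   parameter).
#' @param groups group ids aligned with the rows of `X`.
#' @param validation validation cohort records.
#' @param config a [fit_config()].
#' @param metric optional function `(predict_params, validation) ->`
#'   scalar score, lower better; the default simulates each validation
#'   record with the predicted parameters and computes the RMAE.
#' @return List with `name`, `predict` (the fitted winner), `score`, and
#'   `scores` for every candidate.
#' @export
pipeline_search <- function(X, Y, groups, validation, config = fit_config(),
                            metric = NULL) {
  candidates <- make_pipelines(config)
  if (length(candidates) < 2) {
    stop("need at least two candidate pipelines", call. = FALSE)
  }
  if (NROW(validation) == 0) stop("empty validation set", call. = FALSE)
  if (is.null(metric)) {
    metric <- function(predict_params, validation) {
      preds <- predict_params(
        record_features(validation, config$use_socio),
        group_key(validation, config$use_socio))
      outs <- vapply(seq_len(nrow(validation)), function(i) {
        pars <- params_from_theta(config$init, colnames(Y), preds[i, ])
        tryCatch(
          predict_outcome(pars, record = validation[i, , drop = FALSE]),
          error = function(e) NA_real_)
      }, numeric(1))
      if (any(!is.finite(outs))) return(Inf)
      rmae(outs, validation$T_end_cells)
    }
  }
  scores <- rep(Inf, length(candidates))
  fitted <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fitted[[i]] <- tryCatch(suppressWarnings(candidates[[i]](X, Y, groups)),
                            error = function(e) NULL)
    if (is.null(fitted[[i]])) next
    scores[i] <- tryCatch(metric(fitted[[i]], validation),
                          error = function(e) Inf)
  }
  if (all(!is.finite(scores))) {
    stop("all candidate pipelines failed", call. = FALSE)
  }
  best <- which.min(scores)  # first minimum: ties break by candidate order
  list(name = names(candidates)[best], predict = fitted[[best]],
       score = scores[best], scores = setNames(scores, names(candidates)))
}

# ---- the full three-step procedure ------------------------------------------

# Predictions for a fold: direct group parameters where fitted (batched per
# group), the fold's pipeline otherwise (per record, since the predicted
# parameters depend on the record's features).
predict_fold <- function(records, fold, config) {
  gids <- as.character(group_key(records, config$use_socio))
  preds <- rep(NA_real_, nrow(records))
  direct <- gids %in% names(fold$group_params)
  for (g in unique(gids[direct])) {
    ix <- which(gids == g)
    preds[ix] <- batch_records(fold$group_params[[g]],
                               records[ix, , drop = FALSE])
  }
  miss <- which(!direct)
  if (length(miss)) {
    sub <- records[miss, , drop = FALSE]
    th <- fold$pipeline$predict(record_features(sub, config$use_socio),
                                group_key(sub, config$use_socio))
    for (j in seq_along(miss)) {
      pars <- params_from_theta(config$init, config$free, th[j, ])
      preds[miss[j]] <- tryCatch(
        predict_outcome(pars, record = records[miss[j], , drop = FALSE]),
        error = function(e) NA_real_)
    }
  }
  preds
}

# Per-patient errors using direct group fits plus a shared fallback
# parameter set for unfitted groups (used inside the augmentation gate,
# before a pipeline exists).
fold_errors <- function(records, group_params, fallback, config) {
  gids <- as.character(group_key(records, config$use_socio))
  preds <- rep(NA_real_, nrow(records))
  for (g in unique(gids)) {
    ix <- which(gids == g)
    pars <- if (g %in% names(group_params)) group_params[[g]] else fallback
    preds[ix] <- batch_records(pars, records[ix, , drop = FALSE])
  }
  abs(preds - records$T_end_cells) / records$T_end_cells
}

mean_params <- function(group_params, config) {
  if (!length(group_params)) return(config$init)
  TH <- vapply(group_params, function(p) log(unlist(p[config$free])),
               numeric(length(config$free)))
  TH <- matrix(TH, nrow = length(config$free))
  params_from_theta(config$init, config$free, rowMeans(TH))
}

fit_groups <- function(train, config, inits, max_iter) {
  gids <- group_key(train, config$use_socio)
  out <- list()
  for (g in unique(gids)) {
    rows <- train[gids == g, , drop = FALSE]
    if (nrow(rows) < config$min_group_n) next
    init_g <- inits[[as.character(g)]]
    if (is.null(init_g)) init_g <- config$init
    fit <- tryCatch(gd_fit(rows, init = init_g, config = config,
                           max_iter = max_iter),
                    error = function(e) NULL)
    if (!is.null(fit)) out[[as.character(g)]] <- fit$params
  }
  out
}

#' Fit the personalized BCG model to a cohort
#'
#' The full three-step procedure. The cohort is divided into `k` folds;
#' each fold's data is split into train/test/validate. Step 1 fits each
#' socio-demographic group present in the training set by gradient descent
#' ([gd_fit()]). Step 2 augments the training set with KNN-gated synthetic
#' samples ([augment_train()]) and refits, keeping the augmented fit only
#' when the [significance_gate()] confirms a significant improvement on
#' the test set (up to `max_aug_rounds` rounds; otherwise the
#' pre-augmentation fit is kept). Step 3 trains candidate pipelines on the
#' (augmented train + test) pairs of features and fitted group parameters
#' and keeps the best on the validation set ([pipeline_search()]).
#' Predictions average over folds, using each fold's direct group
#' parameters where the group was fitted and its pipeline otherwise.
#'
#' @param cohort a cohort data frame (>= `k` patients).
#' @param config a [fit_config()].
#' @return A `bcg_fit` object.
#' @seealso [predict.bcg_fit()], [evaluate_model()]
#' @export
fit_bcg <- function(cohort, config = fit_config()) {
  validate_cohort(cohort)
  if (nrow(cohort) < config$k) {
    stop("cohort must contain at least k patients", call. = FALSE)
  }
  set.seed(config$seed)
  n <- nrow(cohort)
  fold_id <- sample(rep(seq_len(config$k), length.out = n))
  folds <- vector("list", config$k)
  for (i in seq_len(config$k)) {
    data_i <- cohort[fold_id == i, , drop = FALSE]
    ni <- nrow(data_i)
    perm <- sample.int(ni)
    n_tr <- max(1L, round(config$split[["train"]] * ni))
    n_te <- max(1L, round(config$split[["test"]] * ni))
    n_tr <- min(n_tr, ni - 2L)
    idx_tr <- perm[seq_len(n_tr)]
    idx_te <- perm[n_tr + seq_len(min(n_te, ni - n_tr - 1L))]
    idx_va <- setdiff(perm, c(idx_tr, idx_te))
    train <- data_i[idx_tr, , drop = FALSE]
    test <- data_i[idx_te, , drop = FALSE]
    validation <- data_i[idx_va, , drop = FALSE]

    group_params <- fit_groups(train, config, list(), config$gd_max_iter)
    fallback <- mean_params(group_params, config)
    errs_before <- fold_errors(test, group_params, fallback, config)

    train_aug <- train
    if (config$n_augment > 0L && config$max_aug_rounds > 0L) {
      params_before <- group_params
      accepted <- FALSE
      for (round in seq_len(config$max_aug_rounds)) {
        train_aug <- suppressWarnings(
          augment_train(train_aug, group_params, config))
        group_params_new <- fit_groups(train_aug, config, group_params,
                                       config$gd_refit_iter)
        fallback_new <- mean_params(group_params_new, config)
        errs_after <- fold_errors(test, group_params_new, fallback_new,
                                  config)
        ok <- complete.cases(errs_before, errs_after)
        gate <- suppressWarnings(
          significance_gate(errs_before[ok], errs_after[ok],
                            alpha = config$alpha))
        group_params <- group_params_new
        fallback <- fallback_new
        if (gate$accept) {
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        group_params <- params_before
        fallback <- mean_params(group_params, config)
        train_aug <- train
      }
    }

    # step 3: pipeline over (augmented train + test) feature/parameter pairs
    pair_pool <- rbind(train_aug[, names(train), drop = FALSE], test)
    pool_gid <- as.character(group_key(pair_pool, config$use_socio))
    keep <- pool_gid %in% names(group_params)
    pair_pool <- pair_pool[keep, , drop = FALSE]
    pool_gid <- pool_gid[keep]
    X <- record_features(pair_pool, config$use_socio)
    Y <- t(vapply(pool_gid, function(g) {
      log(unlist(group_params[[g]][config$free]))
    }, numeric(length(config$free))))
    colnames(Y) <- config$free
    pipeline <- pipeline_search(X, Y, pool_gid, validation, config)

    fold <- list(group_params = group_params, pipeline = pipeline,
                 fallback = fallback)
    rmae_of <- function(records) {
      preds <- predict_fold(records, fold, config)
      mean(abs(preds - records$T_end_cells) / records$T_end_cells,
           na.rm = TRUE)
    }
    fold$rmae <- c(train = rmae_of(train), test = rmae_of(test),
                   validate = rmae_of(validation))
    folds[[i]] <- fold
  }
  structure(list(folds = folds, config = config, free = config$free),
            class = "bcg_fit")
}

#' @export
print.bcg_fit <- function(x, ...) {
  rm <- t(vapply(x$folds, `[[`, numeric(3), "rmae"))
  cat(sprintf("Personalized BCG model fit: %d folds, free = {%s}\n",
              length(x$folds), paste(x$free, collapse = ", ")))
  cat(sprintf("  mean RMAE  train %.3f | test %.3f | validate %.3f\n",
              mean(rm[, 1]), mean(rm[, 2]), mean(rm[, 3])))
  for (i in seq_along(x$folds)) {
    cat(sprintf("  fold %d: %d groups fitted, pipeline = %s\n", i,
                length(x$folds[[i]]$group_params),
                x$folds[[i]]$pipeline$name))
  }
  invisible(x)
}

#' Predict treatment outcomes with a fitted model
#'
#' For each record and each fold, simulates with the fold's direct group
#' parameters when the record's group was fitted in that fold and with the
#' fold's pipeline-predicted parameters otherwise, then averages the
#' per-fold predictions.
#'
#' @param object a `bcg_fit`.
#' @param newdata a cohort data frame.
#' @param ... unused.
#' @return Numeric vector of predicted final tumor burdens (cells).
#' @export
predict.bcg_fit <- function(object, newdata, ...) {
  config <- object$config
  preds <- vapply(object$folds, function(fold) {
    predict_fold(newdata, fold, config)
  }, numeric(nrow(newdata)))
  rowMeans(matrix(preds, nrow = nrow(newdata)))
}
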