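#' Equilibria of the treatment-free model
#'
#' With dosing off (after the last instillation) the model has exactly two
#' equilibria: the trivial state in which every compartment is empty, and
#' the healthy state in which the bladder is filled to capacity with
#' uninfected healthy cells, `(0, 0, 0, 0, H_m, 0)`. Both are verified by
#' substitution into the right-hand side.
#'
#' @param params a [model_params()] object.
#' @return A list of two `bcg_equilibrium` objects (fields `state`,
#'   `label`).
#' @export
#' @examples
#' eqs <- find_equilibria(model_params())
#' sapply(eqs, `[[`, "label")
find_equilibria <- function(params) {
  validate_model_params(params)
  trivial <- setNames(rep(0, 6), STATE_NAMES)
  healthy <- setNames(c(0, 0, 0, 0, params$H_m, 0), STATE_NAMES)
  eqs <- list(
    structure(list(state = trivial, label = "trivial"),
              class = "bcg_equilibrium"),
    structure(list(state = healthy, label = "healthy"),
              class = "bcg_equilibrium")
  )
  for (eq in eqs) {
    resid <- max(abs(bcg_rhs(0, eq$state, params)))
    if (resid > 1e-9 * params$H_m) {
      stop("candidate equilibrium '", eq$label,
           "' does not satisfy rhs = 0", call. = FALSE)
    }
  }
  eqs
}

#' Jacobian of the six-compartment model
#'
#' The exact matrix of partial derivatives of the treatment-free
#' right-hand side, derived analytically from the implemented equations
#' (row order `B, E, T_i, T_u, H_u, H_i`). Use this, not the simplified
#' fixture matrices of [reference_jacobians()], for stability work.
#'
#' @param params a [model_params()] object.
#' @param state numeric state vector of length 6.
#' @return A 6 x 6 numeric matrix.
#' @export
model_jacobian <- function(params, state) {
  if (!all(is.finite(state))) stop("non-finite state", call. = FALSE)
  p <- params
  B <- state[[1]]; E <- state[[2]]; Ti <- state[[3]]
  Tu <- state[[4]]; Hu <- state[[5]]; Hi <- state[[6]]
  J <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  J[1, ] <- c(-p$p1 * E - p$p2 * Tu - p$p8 * Hu - p$mu_B,
              -p$p1 * B, 0, -p$p2 * B, -p$p8 * B, 0)
  J[2, ] <- c(p$p4 * E,
              -p$mu_E + p$p4 * B - p$p5 * Ti - p$p6 * Hi,
              p$alpha - p$p5 * E, 0, 0, p$alpha - p$p6 * E)
  J[3, ] <- c(p$p2 * Tu, -p$p3 * Ti, -p$p3 * E, p$p2 * B, 0, 0)
  J[4, ] <- c(-p$p2 * Tu, -p$p3 * Tu, 0,
              p$lambda - p$p2 * B - p$p3 * E, 0, 0)
  J[5, ] <- c(-p$p8 * Hu, 0, -p$p7 * Hu / p$H_m, -p$p7 * Hu / p$H_m,
              p$p7 * (1 - (2 * Hu + Hi + Tu + Ti) / p$H_m) - p$p8 * B,
              -p$p7 * Hu / p$H_m)
  J[6, ] <- c(p$p8 * Hu, -p$p9 * Hi, 0, 0, p$p8 * B, -p$p9 * E)
  J
}

#' Linear stability of an equilibrium
#'
#' Computes the eigenvalues of the Jacobian at an equilibrium and
#' classifies it by the signs of their real parts: `"unstable"` if any
#' real part exceeds `tol`, `"stable"` if all are below `-tol`, and
#' `"non-hyperbolic"` otherwise. Both model equilibria carry at least one
#' zero eigenvalue (the infected-cell rows vanish there), and whenever the
#' tumor growth rate `lambda` is positive the eigenvalue `lambda` from the
#' uninfected-cancer row makes them unstable: an arbitrarily small tumor
#' seed grows.
#'
#' @param params a [model_params()] object.
#' @param eq a `bcg_equilibrium` from [find_equilibria()], or a bare state
#'   vector at equilibrium.
#' @param tol zero threshold on real parts; defaults to `1e-9` times the
#'   largest rate magnitude.
#' @return A `bcg_stability` object: fields `eigenvalues` (complex, sorted
#'   by decreasing real part), `classification`, `label`.
#' @export
classify_stability <- function(params, eq, tol = NULL) {
  state <- if (inherits(eq, "bcg_equilibrium")) eq$state else eq
  label <- if (inherits(eq, "bcg_equilibrium")) eq$label else NA_character_
  if (is.null(tol)) {
    rates <- unlist(params[c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8",
                             "p9", "mu_B", "mu_E", "alpha", "lambda")])
    tol <- 1e-9 * max(rates)
  }
  ev <- eigen(model_jacobian(params, state), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  re <- Re(ev)
  classification <- if (any(re > tol)) {
    "unstable"
  } else if (all(re < -tol)) {
    "stable"
  } else {
    "non-hyperbolic"
  }
  structure(list(eigenvalues = ev, classification = classification,
                 label = label, tol = tol),
            class = "bcg_stability")
}

#' @export
print.bcg_stability <- function(x, ...) {
  cat(sprintf("Equilibrium%s: %s\n",
              if (is.na(x$label)) "" else paste0(" (", x$label, ")"),
              x$classification))
  cat("  eigenvalues (Re):",
      paste(signif(Re(x$eigenvalues), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Reference linearization fixtures at the two equilibria
#'
#' Returns the simplified 6 x 6 linearization matrices at the trivial and
#' healthy equilibria in their commonly reproduced closed form, kept
#' verbatim as regression fixtures. They contain known simplifications
#' that differ from the exact Jacobian of the implemented equations
#' (bare `-1/H_m` entries without the regrowth-rate factor, a `p7 + 2`
#' diagonal term, and a dropped infection coupling); use
#' [model_jacobian()] for any quantitative analysis. Their headline
#' features — an all-zero infected-cancer row, hence a zero eigenvalue,
#' and the positive eigenvalue `lambda` — agree with the exact Jacobian.
#'
#' @param params a [model_params()] object.
#' @return A list with elements `trivial` and `healthy`, each a 6 x 6
#'   matrix.
#' @export
reference_jacobians <- function(params) {
  p <- params
  nm <- list(STATE_NAMES, STATE_NAMES)
  J_trivial <- matrix(0, 6, 6, dimnames = nm)
  J_trivial[1, 1] <- -p$mu_B
  J_trivial[2, 2] <- -p$mu_E
  J_trivial[2, 3] <- p$alpha
  J_trivial[2, 6] <- p$alpha
  J_trivial[4, 4] <- p$lambda
  J_trivial[5, 3] <- -1 / p$H_m
  J_trivial[5, 4] <- -1 / p$H_m
  J_trivial[5, 5] <- p$p7
  J_trivial[5, 6] <- -1 / p$H_m

  J_healthy <- J_trivial
  J_healthy[5, 1] <- -p$p8 * p$H_m
  J_healthy[5, 5] <- p$p7 + 2
  J_healthy[6, 1] <- p$p8 * p$H_m

  list(trivial = J_trivial, healthy = J_healthy)
}
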