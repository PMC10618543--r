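#' Read a treatment-protocol configuration
#'
#' Protocol constants (BCG decay `mu_B`, dose `b`, number of instillations
#' `N`, inter-dose interval `tau` in hours, and bladder capacity `H_m`)
#' can be stored as a small JSON file; the copy shipped at
#' `system.file("extdata", "protocol_defaults.json", package = "bcgdyn")`
#' holds the standard weekly induction protocol. The returned bundle plugs
#' straight into the simulator.
#'
#' @param path path to a JSON file with any subset of the keys
#'   `mu_B, b, N, tau, H_m`; missing keys fall back to the shipped
#'   defaults. `NULL` reads the shipped file itself.
#' @return List with elements `params` (a [model_params()] object with
#'   `mu_B` and `H_m` applied) and `schedule` (a [dose_schedule()] with
#'   `b`, `N`, `tau` applied).
#' @export
#' @examples
#' cfg <- read_protocol()
#' cfg$schedule
read_protocol <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protocol_defaults.json",
                        package = "bcgdyn")
  }
  raw <- paste(readLines(path, warn = FALSE), collapse = "")
  # the config is flat {name: number}; parse without a JSON dependency
  raw <- gsub("[{}\"[:space:]]", "", raw)
  fields <- strsplit(strsplit(raw, ",")[[1]], ":")
  vals <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  names(vals) <- vapply(fields, `[[`, character(1), 1)
  known <- c("mu_B", "b", "N", "tau", "H_m")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("non-numeric protocol value", call. = FALSE)
  defaults <- c(mu_B = 4.16e-3, b = 2.8e6, N = 6, tau = 1.68e2, H_m = 1.84e9)
  defaults[names(vals)] <- vals
  list(params = model_params(mu_B = defaults[["mu_B"]],
                             H_m = defaults[["H_m"]]),
       schedule = dose_schedule(b = defaults[["b"]],
                                n_doses = defaults[["N"]],
                                tau = defaults[["tau"]]))
}
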