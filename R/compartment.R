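# Two-compartment tissue sodium model:
#   total [Na+] = (1 - EVF) * [Na+]i + EVF * [Na+]e,   EVF = 1 - IVF.
# Forward and both inverse directions, exact algebra. Non-physiological
# solutions (EVF outside [0,1], negative concentrations) are returned with
# flags rather than clamped: the model ignores blood and ductal
# compartments, so out-of-range output is diagnostic information.

#' Forward two-compartment mixture
#'
#' Total tissue sodium from the compartment concentrations and the
#' extracellular volume fraction.
#'
#' @param nai intracellular sodium, mM (>= 0).
#' @param nae extracellular sodium, mM (>= 0).
#' @param evf extracellular volume fraction, in \[0, 1\].
#' @return total tissue sodium, mM.
#' @export
#' @examples
#' forward_total(25.9, 157.8, 0.159)
forward_total <- function(nai, nae, evf) {
  check_scalar(nai, "nai", lower = 0)
  check_scalar(nae, "nae", lower = 0)
  check_scalar(evf, "evf", lower = 0, upper = 1)
  (1 - evf) * nai + evf * nae
}

#' Solve the mixture for the volume fractions
#'
#' `EVF = (total - nai) / (nae - nai)`, `IVF = 1 - EVF`. An EVF outside
#' \[0, 1\] is returned as computed with `physiological = FALSE`.
#'
#' @param total total tissue sodium, mM.
#' @param nai intracellular sodium, mM.
#' @param nae extracellular sodium, mM; must differ from `nai`.
#' @return list: `evf`, `ivf`, `physiological`.
#' @export
#' @examples
#' solve_evf(46.9, 25.9, 157.8) # evf 0.159, ivf 0.841
solve_evf <- function(total, nai, nae) {
  check_scalar(total, "total")
  check_scalar(nai, "nai")
  check_scalar(nae, "nae")
  if (nae == nai)
    stop_config("nae equals nai: volume fractions are unidentifiable")
  evf <- (total - nai) / (nae - nai)
  list(evf = evf, ivf = 1 - evf,
       physiological = evf >= 0 && evf <= 1)
}

#' Solve the mixture for intracellular sodium
#'
#' `nai = (total - evf * nae) / (1 - evf)`. A negative result is returned
#' with `physiological = FALSE`.
#'
#' @param total total tissue sodium, mM.
#' @param evf extracellular volume fraction, in \[0, 1).
#' @param nae extracellular sodium, mM.
#' @return list: `nai`, `physiological`.
#' @export
#' @examples
#' solve_nai(29.7, 0.159, 158) # ~5.4 mM
solve_nai <- function(total, evf, nae) {
  check_scalar(total, "total")
  check_scalar(nae, "nae")
  check_scalar(evf, "evf", lower = 0, upper = 1)
  if (evf == 1)
    stop_config("evf = 1: no intracellular compartment to solve for")
  nai <- (total - evf * nae) / (1 - evf)
  list(nai = nai, physiological = nai >= 0)
}

#' Complete, validated compartment state
#'
#' Assembles (total, nai, nae, evf, ivf) and verifies the mixture identity
#' and `ivf = 1 - evf` to tight tolerance. Concentrations are kept at full
#' precision; use [format_compartment()] for report-style rounding
#' (fractions to 3 d.p., concentrations to 1 d.p.).
#'
#' @param total,nai,nae concentrations, mM.
#' @param evf extracellular volume fraction.
#' @param tol identity tolerance (default 1e-9).
#' @return list of class `compartment_state`.
#' @export
compartment_state <- function(total, nai, nae, evf, tol = 1e-9) {
  check_scalar(evf, "evf", lower = 0, upper = 1)
  if (abs(total - forward_total(nai, nae, evf)) > tol)
    stop_config("state violates the mixture identity beyond tolerance")
  structure(list(total = total, nai = nai, nae = nae,
                 evf = evf, ivf = 1 - evf),
            class = "compartment_state")
}

#' @rdname compartment_state
#' @param state a `compartment_state`.
#' @return `format_compartment()`: named character vector of rounded values.
#' @export
format_compartment <- function(state) {
  stopifnot(inherits(state, "compartment_state"))
  c(total_mM = sprintf("%.1f", state$total),
    nai_mM = sprintf("%.1f", state$nai),
    nae_mM = sprintf("%.1f", state$nae),
    evf = sprintf("%.3f", state$evf),
    ivf = sprintf("%.3f", state$ivf))
}

#' @export
print.compartment_state <- function(x, ...) {
  f <- format_compartment(x)
  cat(sprintf("<compartment_state> total %s mM = (1 - %s) x %s + %s x %s\n",
              f["total_mM"], f["evf"], f["nai_mM"], f["evf"], f["nae_mM"]))
  invisible(x)
}
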