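# Parameterization of the CPEB1-alphaCaMKII loop.
#
# Rate constants follow the published table for the loop; the free
# concentrations (phosphatase P, translation machinery T, total CPEB1 YT,
# resting Ca4CaM) are configuration inputs frozen by the calibration in
# calibration.R.  Units: concentrations in uM, first-order rates in 1/s,
# second-order rates in 1/(uM s).

param_fields <- c(
  "k1", "k2", "k3", "k4", "k5", "k55", "k6", "k7", "k8", "k88", "k9",
  "k10", "k1010", "lambda1", "lambda2", "P", "T", "YT", "U_basal",
  "Xbasal", "XPbasal"
)

#' Construct a parameter set for the polyadenylation loop
#'
#' Builds the full rate-constant and concentration configuration of the
#' CPEB1-alphaCaMKII feedback loop.  Defaults are the published table
#' values for condition I (fast autophosphorylation, `k3 = 500`/s); the
#' free concentrations `P`, `T`, `YT` and `U_basal` have no published
#' values and default to the calibrated frozen configuration (see
#' [calibrate_free_concentrations()]).
#'
#' @param k1,k2 association (1/(uM s)) and dissociation (1/s) rates of the
#'   X.XP autophosphorylation complex C1.
#' @param k3 autophosphorylation catalysis rate C1 -> 2 XP (1/s).
#' @param k4 XP dephosphorylation by the phosphatase (1/(uM s)).
#' @param k5,k55 association/dissociation rates of the CPEB1.XP complex C2.
#' @param k6 CPEB1 phosphorylation catalysis rate C2 -> YP + XP (1/s).
#' @param k7 YP dephosphorylation by the phosphatase (1/(uM s)).
#' @param k8,k88 association/dissociation rates of the YP.T translation
#'   complex C3.
#' @param k9 synthesis catalysis rate C3 -> YP + X + T (1/s).
#' @param k10,k1010 Ca4CaM activation of X and its reverse (1/(uM s), 1/s).
#' @param lambda1,lambda2 degradation rates acting on free XP and free X
#'   (1/s).  The reduced models require `lambda1 == lambda2`.
#' @param P phosphatase concentration (uM).
#' @param T translation-machinery concentration (uM).
#' @param YT total CPEB1 concentration (uM).
#' @param U_basal resting Ca4CaM concentration (uM).
#' @param Xbasal,XPbasal basal concentrations toward which free X and XP
#'   relax (uM).
#' @return an object of class `loop_params` (a validated named list).
#' @seealso [derive_constants()], [make_condition()], [frozen_config()]
#' @export
loop_params <- function(k1 = 0.085, k2 = 0.143, k3 = 500, k4 = 0.0012,
                        k5 = 0.0072, k55 = 20, k6 = 0.962, k7 = 0.012,
                        k8 = 0.08, k88 = 10, k9 = 0.08, k10 = 0.001,
                        k1010 = 0.8, lambda1 = 1e-4, lambda2 = 1e-4,
                        P = 0.01, T = 0.3, YT = 50, U_basal = 1e-6,
                        Xbasal = 1e-4, XPbasal = 0) {
  p <- mget(param_fields, environment())
  validate_params(p)
}

#' Validate a parameter set
#'
#' @param p named list with exactly the `loop_params` fields.
#' @return the validated object, classed `loop_params`.
#' @export
validate_params <- function(p) {
  p <- unclass(p)
  if (!setequal(names(p), param_fields) || anyDuplicated(names(p))) {
    extra <- setdiff(names(p), param_fields)
    missing <- setdiff(param_fields, names(p))
    loop_error(sprintf(
      "invalid parameter set: unknown fields [%s], missing fields [%s]",
      paste(extra, collapse = ", "), paste(missing, collapse = ", ")),
      "loop_schema_error")
  }
  if (any(lengths(p) != 1)) {
    loop_error("every parameter must be a scalar", "loop_schema_error")
  }
  p <- lapply(p[param_fields],
              function(x) suppressWarnings(as.double(x)))
  vals <- unlist(p, use.names = FALSE)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    loop_error("all parameters must be finite numerics", "loop_invalid_parameter")
  }
  if (any(vals < 0)) {
    loop_error("all parameters must be nonnegative", "loop_invalid_parameter")
  }
  structure(p, class = "loop_params")
}

# single degradation rate of the reduced models; unequal values are an
# error rather than an average because the reductions assume one lambda
lambda_reduced <- function(p) {
  if (p$lambda1 != p$lambda2) {
    loop_error(
      "reduced models require lambda1 == lambda2 (a single degradation rate)",
      "loop_invalid_parameter")
  }
  p$lambda1
}

#' Derived constants of the reduction
#'
#' Computes the lumped constants used throughout the pseudo-steady-state
#' reduction: `a = k5*k6/(k55+k6)` (effective CPEB1 activation,
#' 1/(uM s)), `N = k5/(k55+k6)` and `M = k1/(k2+k3)` (complex/free ratios,
#' 1/uM), `b = k9*k8*T/(k88+k9)` and `c = b*YT` (synthesis capacity,
#' c in uM/s), `P7 = k7*P` and `P4 = k4*P` (dephosphorylation rates, 1/s),
#' and the steady-XP elimination constants `a1 = k3*k1/(k2+k3)`,
#' `a2 = k10*U`, `DI = P4 + k1010`, `d1 = a`.
#'
#' @param p a `loop_params` object.
#' @param U Ca4CaM concentration entering `a2` (defaults to `U_basal`).
#' @return a named list of class `derived_constants`.
#' @export
derive_constants <- function(p, U = p$U_basal) {
  p <- validate_params(p)
  if (p$k55 + p$k6 <= 0 || p$k2 + p$k3 <= 0 || p$k88 + p$k9 <= 0) {
    loop_error("zero denominator in derived constants (k55+k6, k2+k3 or k88+k9)",
               "loop_invalid_parameter")
  }
  a <- p$k5 * p$k6 / (p$k55 + p$k6)
  N <- p$k5 / (p$k55 + p$k6)
  M <- p$k1 / (p$k2 + p$k3)
  b <- p$k9 * p$k8 * p$T / (p$k88 + p$k9)
  structure(list(
    a = a, N = N, M = M, b = b, c = b * p$YT,
    P7 = p$k7 * p$P, P4 = p$k4 * p$P,
    a1 = p$k3 * p$k1 / (p$k2 + p$k3), a2 = p$k10 * U,
    DI = p$k4 * p$P + p$k1010, d1 = a
  ), class = "derived_constants")
}

#' @export
print.loop_params <- function(x, ...) {
  cat("<loop_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " = ", format(v, digits = 6)),
      sep = "\n")
  invisible(x)
}

#' Write a parameter set to JSON
#'
#' One key per field; units are documented in the schema file shipped at
#' `system.file("extdata", "params_schema.json", package = "cpebswitch")`.
#'
#' @param p a `loop_params` object.
#' @param path output file path.
#' @export
write_params_json <- function(p, path) {
  p <- validate_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' Unknown keys are rejected to catch misspelled rate constants.
#'
#' @param path JSON file written by [write_params_json()] or by hand.
#' @return a `loop_params` object.
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_params(raw)
}
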