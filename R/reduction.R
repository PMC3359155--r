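# Staged reduction of the six-ODE loop.
#
# Level 1 (reduced3): pseudo-steady-state elimination of the complexes
# C1-C3 and the approximation Y = YT - YP leave three dynamical variables
# (XT, XP, YP).  Level 2 (one_d, see inversion.R): the XP and YP
# nullclines turn the pool balance dXT/dt = k9*C3 - lambda*XT into a
# single ODE G'(XT) - F(XT) once XP = h(XT) is obtained by a polynomial
# fit.  The exact steady-state map XT = f(XP) used for that fit is
# xt_of_xp() below.

#' Pseudo-steady-state complex concentrations
#'
#' Eliminates the fast complex dynamics: `C1 = k1*X*XP/(k2+k3)`,
#' `C2 = k5*Y*XP/(k55+k6)`, `C3 = k8*YP*T/(k88+k9)`.
#'
#' @param X,XP,Y,YP free concentrations in uM.
#' @param params a `loop_params` object.
#' @return list with components `C1`, `C2`, `C3` (uM).
#' @export
pssa_complexes <- function(X, XP, Y, YP, params) {
  p <- params
  check_nonneg(c(X, XP, Y, YP), "pssa_complexes inputs")
  if (p$k2 + p$k3 <= 0 || p$k55 + p$k6 <= 0 || p$k88 + p$k9 <= 0) {
    loop_error("zero denominator in complex elimination", "loop_invalid_parameter")
  }
  list(C1 = p$k1 * X * XP / (p$k2 + p$k3),
       C2 = p$k5 * Y * XP / (p$k55 + p$k6),
       C3 = p$k8 * YP * p$T / (p$k88 + p$k9))
}

#' Phospho-CPEB1 nullcline
#'
#' Steady state of the CPEB1 phosphorylation cycle:
#' `YP = a*YT*XP / (k7*P + a*XP)`.  Saturates at `YT`; the
#' half-saturation point is `XP = P7/a`.
#'
#' @param XP phospho-alphaCaMKII concentration (uM), vectorized.
#' @param params a `loop_params` object.
#' @return YP on the nullcline (uM), in `[0, YT)`.
#' @export
yp_nullcline <- function(XP, params) {
  check_nonneg(XP, "XP")
  d <- derive_constants(params)
  den <- d$P7 + d$a * XP
  if (any(den <= 0)) {
    loop_error("k7*P + a*XP must be positive on the YP nullcline",
               "loop_degenerate_input")
  }
  d$a * params$YT * XP / den
}

#' Free inactive alphaCaMKII from the pool composition
#'
#' Inverts `XT = X + XP + 2*C1 + C2` for X with the complexes at their
#' pseudo-steady state: `X = (XT - XP - N*Y*XP) / (1 + 2*M*XP)`.  When
#' `YP` is not supplied it is taken on its nullcline, which reproduces
#' the printed closed form of the reduction.
#'
#' @param XT,XP total and phosphorylated alphaCaMKII (uM), `XT >= XP`.
#' @param params a `loop_params` object.
#' @param YP optional phospho-CPEB1; default uses [yp_nullcline()].
#' @return free X (uM).  A negative result signals an infeasible
#'   composition (XP too large for this XT) and raises an error.
#' @export
x_free <- function(XT, XP, params, YP = NULL) {
  check_nonneg(c(XT, XP), "XT, XP")
  if (any(XP > XT + 1e-12)) {
    loop_error("XP exceeds XT", "loop_infeasible_composition")
  }
  d <- derive_constants(params)
  if (is.null(YP)) YP <- yp_nullcline(XP, params)
  Y <- params$YT - YP
  X <- (XT - XP - d$N * Y * XP) / (1 + 2 * d$M * XP)
  if (any(X < -1e-9 * pmax(XT, 1))) {
    loop_error(
      "free X is negative: composition infeasible (shrink XP for this XT)",
      "loop_infeasible_composition")
  }
  pmax(X, 0)
}

# smooth extension of the reduced3 right-hand side: free X is computed
# without the feasibility check so root finders and numerical Jacobians
# can step slightly past the XP <= XT boundary
reduced3_core <- function(XT, XP, YP, params, U) {
  lam <- lambda_reduced(params)
  d <- derive_constants(params)
  Y <- params$YT - YP
  X <- (XT - XP - d$N * Y * XP) / (1 + 2 * d$M * XP)
  C3 <- params$k8 * YP * params$T / (params$k88 + params$k9)
  c(XT = params$k9 * C3 - lam * XT,
    XP = params$k3 * d$M * X * XP - d$P4 * XP + params$k10 * X * U -
      params$k1010 * XP,
    YP = d$a * (params$YT - YP) * XP - d$P7 * YP)
}

#' Right-hand side of the three-variable reduced model
#'
#' State `(XT, XP, YP)`.  The pool obeys `dXT/dt = k9*C3 - lambda*XT`;
#' `dYP/dt = a*(YT-YP)*XP - P7*YP` (complex eliminations applied);
#' `dXP/dt = k3*M*X*XP - P4*XP + k10*X*U - k1010*XP` with X recovered
#' from the composition at the current YP.
#'
#' @param state numeric vector `c(XT, XP, YP)`.
#' @param params a `loop_params` object (requires `lambda1 == lambda2`).
#' @param U Ca4CaM concentration (uM).
#' @return named derivative vector, uM/s.
#' @export
reduced3_rhs <- function(state, params, U = params$U_basal) {
  XT <- state[[1]]; XP <- state[[2]]; YP <- state[[3]]
  check_nonneg(c(XT, XP, YP, U), "reduced3 state")
  x_free(XT, XP, params, YP = YP)  # errors on infeasible compositions
  reduced3_core(XT, XP, YP, params, U)
}

#' Steady-state total alphaCaMKII as a function of XP
#'
#' The XP-nullcline map `XT = f(XP)` obtained by exact elimination:
#' setting `dXP/dt = 0` gives `X = DI*XP/(a1*XP + a2)`, and the
#' composition with YP on its nullcline gives
#' `XT = X*(1 + 2*M*XP) + XP + N*YT*P7*XP/(P7 + a*XP)`.
#'
#' @param XP phospho-alphaCaMKII (uM), vectorized.
#' @param params a `loop_params` object.
#' @param U Ca4CaM concentration entering the activation term (uM).
#' @return XT on the XP nullcline (uM); `xt_of_xp(0) == 0`.
#' @export
xt_of_xp <- function(XP, params, U = params$U_basal) {
  check_nonneg(XP, "XP")
  d <- derive_constants(params, U = U)
  den <- d$a1 * XP + d$a2
  X <- ifelse(XP == 0 & den == 0, 0, d$DI * XP / den)
  X * (1 + 2 * d$M * XP) + XP +
    d$N * params$YT * d$P7 * XP / (d$P7 + d$a * XP)
}

#' Printed-form diagnostic of the steady-state map
#'
#' Evaluates the literal published four-term decomposition
#' `XT = I1 + I2 + I3 + I4`.  I1-I3 coincide algebraically with
#' [xt_of_xp()]; the printed I4 denominator (`k6/d1 + XP/P7`) differs
#' from the derivation (`k6/d1 + k6*XP/P7`) by a factor k6 on its second
#' term.  Kept as a diagnostic only.
#'
#' @inheritParams xt_of_xp
#' @return XT per the literal printed expression (uM).
#' @export
xt_of_xp_printed <- function(XP, params, U = params$U_basal) {
  d <- derive_constants(params, U = U)
  p <- params
  I1 <- d$DI * XP / (d$a1 * XP + d$a2)
  I2 <- d$DI * XP^2 / (p$k3 * XP / 2 + p$k3 * d$a2 / (2 * d$a1))
  I2[XP == 0] <- 0
  I3 <- XP
  I4 <- XP * p$YT / (p$k6 / d$d1 + XP / d$P7)
  I1 + I2 + I3 + I4
}

#' Compare the derived and printed steady-state maps
#'
#' Scans a grid of XP values and reports where the literal printed
#' expression diverges from the exact elimination by more than `tol`
#' relative.  Divergences are reported, never averaged in.
#'
#' @param params a `loop_params` object.
#' @param XP grid of XP values (uM).
#' @param tol relative divergence threshold (default 1%).
#' @return data frame with columns `XP`, `XT`, `XT_printed`, `rel_diff`;
#'   attribute `max_rel_diff`.  A warning is raised if any point exceeds
#'   `tol`.
#' @export
xt_printed_check <- function(params, XP = 10^seq(-3, log10(150), length.out = 200),
                             tol = 0.01) {
  xt <- xt_of_xp(XP, params)
  xtp <- xt_of_xp_printed(XP, params)
  rel <- abs(xtp - xt) / pmax(abs(xt), 1e-12)
  out <- data.frame(XP = XP, XT = xt, XT_printed = xtp, rel_diff = rel)
  attr(out, "max_rel_diff") <- max(rel)
  if (max(rel) > tol) {
    warning(sprintf(
      "printed steady-state map diverges from the elimination by up to %.2f%%",
      100 * max(rel)))
  }
  out
}
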