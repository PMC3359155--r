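# The full six-variable mass-action model.
#
# Reactions:
#   R1: X + Ca4CaM <-> XP                  (k10 / k1010)
#   R2: X + XP <-> C1 -> 2 XP              (k1 / k2, k3)
#   R3: XP + P -> X + P                    (k4)
#   R4: Y + XP <-> C2 -> YP + XP           (k5 / k55, k6)
#   R5: YP + P -> Y + P                    (k7)
#   R6: YP + T <-> C3 -> YP + X + T        (k8 / k88, k9)
#
# X is inactive alphaCaMKII, XP its phosphorylated/active form, Y / YP
# unphosphorylated / phosphorylated CPEB1, C1-C3 the three complexes.
# Free CPEB1 is carried by exact conservation Y = YT - YP - C2 - C3, so
# six ODEs close the system.  Degradation/relaxation acts on free X and
# XP only; complexes do not degrade.

full_fields <- c("X", "XP", "YP", "C1", "C2", "C3")

#' Construct a full-model state
#'
#' @param X,XP,YP,C1,C2,C3 concentrations in uM (all nonnegative).
#' @param params optional `loop_params`; when supplied, the implied free
#'   CPEB1 `Y = YT - YP - C2 - C3` is checked to be nonnegative.
#' @return named numeric vector of class `full_state`.
#' @export
full_state <- function(X = 0, XP = 0, YP = 0, C1 = 0, C2 = 0, C3 = 0,
                       params = NULL) {
  s <- c(X = X, XP = XP, YP = YP, C1 = C1, C2 = C2, C3 = C3)
  check_nonneg(s, "full-model state")
  if (!is.null(params)) {
    if (y_free(s, params) < -1e-12) {
      loop_error("implied free CPEB1 (YT - YP - C2 - C3) is negative",
                 "loop_infeasible_composition")
    }
  }
  structure(s, class = c("full_state", "numeric"))
}

# implied free CPEB1 under exact conservation
y_free <- function(state, p) {
  unname(p$YT - state[["YP"]] - state[["C2"]] - state[["C3"]])
}

#' Right-hand side of the full six-ODE model
#'
#' Mass-action fluxes of reactions R1-R6 plus the basal relaxation terms
#' `-lambda1*(XP - XPbasal)` and `-lambda2*(X - Xbasal)` on the free
#' kinase forms.  Ca4CaM (`U`) is an exogenous input.
#'
#' @param state named state vector (see [full_state()]).
#' @param params a `loop_params` object.
#' @param U Ca4CaM concentration in uM.
#' @return named vector of time derivatives, uM/s.
#' @export
full_rhs <- function(state, params, U = params$U_basal) {
  p <- params
  s <- unclass(state)[full_fields]
  if (any(!is.finite(unlist(s)))) {
    loop_error("non-finite state passed to full_rhs", "loop_invalid_input")
  }
  check_nonneg(c(unlist(s), U), "full_rhs inputs")
  X <- s[["X"]]; XP <- s[["XP"]]; YP <- s[["YP"]]
  C1 <- s[["C1"]]; C2 <- s[["C2"]]; C3 <- s[["C3"]]
  Y <- p$YT - YP - C2 - C3

  dX <- -p$k1 * X * XP + p$k2 * C1 + p$k4 * XP * p$P + p$k9 * C3 -
    p$k10 * X * U + p$k1010 * XP - p$lambda2 * (X - p$Xbasal)
  dXP <- -p$k1 * X * XP + p$k2 * C1 + 2 * p$k3 * C1 - p$k4 * XP * p$P +
    p$k55 * C2 + p$k6 * C2 - p$k5 * Y * XP + p$k10 * X * U -
    p$k1010 * XP - p$lambda1 * (XP - p$XPbasal)
  dYP <- -p$k7 * YP * p$P + p$k6 * C2 - p$k8 * YP * p$T +
    p$k88 * C3 + p$k9 * C3
  dC1 <- p$k1 * X * XP - (p$k2 + p$k3) * C1
  dC2 <- p$k5 * Y * XP - (p$k55 + p$k6) * C2
  dC3 <- p$k8 * YP * p$T - (p$k88 + p$k9) * C3

  out <- c(X = dX, XP = dXP, YP = dYP, C1 = dC1, C2 = dC2, C3 = dC3)
  if (any(!is.finite(out))) {
    loop_error("full_rhs produced non-finite derivatives", "loop_invalid_input")
  }
  out
}

#' Total alphaCaMKII concentration of a state
#'
#' `XT = X + XP + 2*C1 + C2`: both kinase molecules of the C1 complex and
#' the one bound in C2 count toward the pool; C3 contains none.
#'
#' @param state a full-model state vector.
#' @return total concentration in uM.
#' @export
total_camkii <- function(state) {
  s <- unclass(state)
  unname(s[["X"]] + s[["XP"]] + 2 * s[["C1"]] + s[["C2"]])
}
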