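# Polynomial inversion XP = h(XT) and the one-variable model.
#
# The steady-state map XT = f(XP) cannot be inverted in closed form, so
# XP is fitted as a degree-9 polynomial in XT with zero intercept.  The
# fitted h feeds the synthesis function G'(XT) = c*h/(h + P7/a) of the
# single-ODE model dXT/dt = G'(XT) - lambda*XT.
#
# Numerical notes.  The map has a sharp corner at XT = DI/a1 (~9.4 uM at
# the reference configuration) where sustained autophosphorylation turns
# on; below it the true XP is of order a2/a1 ~ 1e-8 uM.  A global
# degree-9 polynomial cannot follow that corner exactly, so the fit is
# excellent on the upper branch and biased by a fraction of a uM around
# the corner; h is clamped at zero inside G' to avoid spurious negative
# synthesis.  The basis is evaluated in the scaled variable XT/domain_hi
# for conditioning.

#' Fit the polynomial inversion XP = h(XT)
#'
#' Least-squares fit of XP against XT over a mixed geometric + linear
#' grid of XP values mapped through [xt_of_xp()], with basis
#' `{XT^1, ..., XT^9}` (zero intercept, so `h(0) == 0` exactly).
#'
#' @param params a `loop_params` object.
#' @param domain_hi upper end of the fit domain in XT (uM).  Default:
#'   1.5 times the upper stable fixed point of the quartic level.
#' @param grid_size number of XP grid points (>= 50; default 500, split
#'   evenly between a geometric and a linear grid).
#' @param degree polynomial degree (default 9).
#' @return object of class `inversion_fit`: coefficients on the original
#'   XT scale (`coefficients`), scaled-basis coefficients and scale,
#'   `domain_lo`/`domain_hi`, `max_abs_residual` (uM) and `grid_size`.
#' @export
fit_inversion <- function(params, domain_hi = NULL, grid_size = 500,
                          degree = 9) {
  if (grid_size < 50) {
    loop_error("grid_size must be at least 50", "loop_invalid_input")
  }
  lambda_reduced(params)
  if (is.null(domain_hi)) {
    fps <- solve_fixed_points(params, level = "quartic")
    up <- max(fps$XT)
    if (up <= 0) {
      loop_error("cannot pick a fit domain: no positive fixed point",
                 "loop_degenerate_input")
    }
    domain_hi <- 1.5 * up
  }
  if (domain_hi <= 0) {
    loop_error("domain_hi must be positive", "loop_invalid_input")
  }
  xp_hi <- stats::uniroot(function(x) xt_of_xp(x, params) - domain_hi,
                          c(1e-12, 1e6), tol = 1e-13)$root
  n_geo <- floor(grid_size / 2)
  n_lin <- grid_size - n_geo
  xp <- c(0,
          exp(seq(log(1e-9), log(xp_hi), length.out = n_geo)),
          seq(xp_hi / n_lin, xp_hi, length.out = n_lin))
  xt <- xt_of_xp(xp, params)
  s <- xt / domain_hi
  B <- outer(s, seq_len(degree), `^`)
  qrB <- qr(B)
  if (qrB$rank < degree) {
    warning("inversion fit basis is rank deficient; reducing degree")
  }
  beta <- qr.coef(qrB, xp)
  beta[is.na(beta)] <- 0
  fitted <- drop(B %*% beta)
  structure(list(
    coefficients = beta / domain_hi^seq_len(degree),
    beta_scaled = beta,
    degree = degree,
    domain_lo = 0,
    domain_hi = domain_hi,
    max_abs_residual = max(abs(fitted - xp)),
    grid_size = length(xp),
    params = params
  ), class = "inversion_fit")
}

#' Evaluate the fitted inversion h(XT)
#'
#' @param fit an `inversion_fit`.
#' @param XT total alphaCaMKII (uM), vectorized; must lie inside the fit
#'   domain unless `extrapolate = TRUE`.
#' @param extrapolate allow evaluation outside `[domain_lo, domain_hi]`.
#' @return fitted XP (uM); can be slightly negative near the corner, see
#'   [one_d_rhs()] which clamps at zero.
#' @export
eval_inversion <- function(fit, XT, extrapolate = FALSE) {
  if (!extrapolate &&
      any(XT < fit$domain_lo - 1e-9 | XT > fit$domain_hi * (1 + 1e-9))) {
    loop_error("XT outside the inversion fit domain", "loop_extrapolation")
  }
  s <- XT / fit$domain_hi
  drop(outer(s, seq_len(fit$degree), `^`) %*% fit$beta_scaled)
}

#' @export
predict.inversion_fit <- function(object, XT, ...) eval_inversion(object, XT)

#' @export
print.inversion_fit <- function(x, ...) {
  cat(sprintf(
    "<inversion_fit> degree %d, domain [0, %.4g] uM, %d grid points, max |resid| = %.3g uM\n",
    x$degree, x$domain_hi, x$grid_size, x$max_abs_residual))
  invisible(x)
}

#' Right-hand side of the one-variable model
#'
#' `dXT/dt = G'(XT) - F(XT)` with synthesis
#' `G'(XT) = c*h(XT)/(h(XT) + P7/a)` and degradation `F(XT) = lambda*XT`.
#' The fitted `h` is clamped at zero so the synthesis function stays in
#' `[0, c]`.
#'
#' @param XT total alphaCaMKII (uM), vectorized, inside the fit domain.
#' @param params a `loop_params` object.
#' @param fit an `inversion_fit` for these parameters.
#' @return dXT/dt in uM/s.
#' @export
one_d_rhs <- function(XT, params, fit) {
  lam <- lambda_reduced(params)
  d <- derive_constants(params)
  h <- pmax(eval_inversion(fit, XT), 0)
  d$c * h / (h + d$P7 / d$a) - lam * XT
}

#' Synthesis and degradation curves of the one-variable model
#'
#' Convenience export of the two terms whose intersections are the fixed
#' points, for tabulation.
#'
#' @inheritParams one_d_rhs
#' @return data frame with columns `XT`, `XP_fit`, `G_prime`, `F`.
#' @export
one_d_curves <- function(XT, params, fit) {
  lam <- lambda_reduced(params)
  d <- derive_constants(params)
  h <- pmax(eval_inversion(fit, XT), 0)
  data.frame(XT = XT, XP_fit = h,
             G_prime = d$c * h / (h + d$P7 / d$a),
             F = lam * XT)
}
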