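# Fixed points at all four model levels.
#
# quartic:  exact steady-state polynomial in XP (degree 4, zero constant
#           term) from the algebraic elimination; roots mapped to XT.
# one_d:    sign-change bracketing of the fitted single ODE.
# reduced3: damped Newton on the three-variable right-hand side.
# full:     damped Newton on the six-variable right-hand side.
#
# Newton solves are seeded from the quartic roots mapped to the
# corresponding composition, plus the basal state; returned points are
# verified |RHS| < 1e-9 uM/s.

model_levels <- c("quartic", "one_d", "reduced3", "full")

#' Steady-state polynomial in XP
#'
#' Clears denominators of the steady-state balance
#' `(c/lambda)*a*XP/(a*XP+P7) = f(XP)` (the synthesis-degradation balance
#' against the XP-nullcline map of [xt_of_xp()]) to obtain the quartic
#' `XP^4 + z12*XP^3 + z13*XP^2 + z14*XP = 0`.  The constant term is
#' identically zero, so XP = 0 is always a steady state; clearing the
#' shared `(a*XP + P7)` factor twice also introduces a spurious root at
#' `XP = -P7/a`, which is negative and discarded by the nonnegativity
#' filter in [solve_fixed_points()].
#'
#' @param params a `loop_params` object with `lambda1 == lambda2`.
#' @return object of class `steady_polynomial` with ascending-power
#'   `coefficients` (length 5, first element 0), the monic coefficients
#'   `z12`, `z13`, `z14`, and `provenance = "eliminated"`.
#' @export
steady_state_polynomial <- function(params) {
  lam <- lambda_reduced(params)
  d <- derive_constants(params)
  den1 <- c(d$a2, d$a1)       # a1*XP + a2
  den2 <- c(d$P7, d$a)        # a*XP + P7
  den2sq <- poly_mul(den2, den2)
  # every term below still carries one factor of XP, appended at the end
  t1 <- poly_mul(d$DI * c(1, 2 * d$M), den2sq)
  t2 <- poly_mul(den1, den2sq)
  t3 <- poly_mul(d$N * params$YT * d$P7 * den1, den2)
  t4 <- poly_mul(-(d$c / lam) * d$a * den1, den2)
  q <- poly_add(poly_add(t1, t2), poly_add(t3, t4))
  coefs <- c(0, q)
  degenerate <- abs(coefs[5]) <= 1e-300
  if (degenerate) {
    message("steady-state polynomial degenerates below degree 4; ",
            "solving the lower-degree polynomial")
  }
  lead <- if (degenerate) coefs[max(which(abs(coefs) > 0))] else coefs[5]
  structure(list(
    coefficients = coefs,
    z12 = coefs[4] / lead, z13 = coefs[3] / lead, z14 = coefs[2] / lead,
    degenerate = degenerate,
    provenance = "eliminated"
  ), class = "steady_polynomial")
}

#' @export
print.steady_polynomial <- function(x, ...) {
  cat(sprintf(
    "<steady_polynomial> XP^4 + %.6g XP^3 + %.6g XP^2 + %.6g XP = 0 [%s]\n",
    x$z12, x$z13, x$z14, x$provenance))
  invisible(x)
}

# nonnegative real roots of the steady polynomial (XP scale)
steady_xp_roots <- function(params) {
  sp <- steady_state_polynomial(params)
  co <- sp$coefficients
  co <- co[seq_len(max(which(abs(co) > 0)))]
  r <- polyroot(co)
  keep <- abs(Im(r)) <= 1e-9 * pmax(Mod(r), 1)
  xp <- Re(r)[keep]
  xp[xp > -1e-12 & xp < 0] <- 0
  xp <- xp[xp >= 0]
  xp <- sort(xp)
  # drop near-duplicates from root-polishing noise
  if (length(xp) > 1) {
    xp <- xp[c(TRUE, diff(xp) > 1e-9 * pmax(xp[-1], 1))]
  }
  xp
}

# effective pool relaxation rate along the XP-parameterized steady
# manifold: d(synthesis - degradation)/dXT = s'(XP) / f'(XP)
quartic_eigenvalue <- function(xp, params) {
  lam <- lambda_reduced(params)
  d <- derive_constants(params)
  s_fun <- function(x) {
    d$c * d$a * x / (d$a * x + d$P7) - lam * xt_of_xp(x, params)
  }
  h <- 1e-6 * max(xp, 1e-3)
  lo <- max(xp - h, 0)
  ds <- (s_fun(xp + h) - s_fun(lo)) / (xp + h - lo)
  df <- (xt_of_xp(xp + h, params) - xt_of_xp(lo, params)) / (xp + h - lo)
  ds / df
}

stability_label <- function(ev, tol = 1e-10) {
  if (ev < -tol) "stable" else if (ev > tol) "unstable" else "marginal"
}

# build a full-model state from a steady XP value (PSSA composition)
full_seed_from_xp <- function(xp, params) {
  d <- derive_constants(params)
  X <- if (xp == 0 && d$a1 * xp + d$a2 == 0) 0 else d$DI * xp / (d$a1 * xp + d$a2)
  YP <- yp_nullcline(xp, params)
  cx <- pssa_complexes(X, xp, params$YT - YP, YP, params)
  c(X = max(X, params$Xbasal), XP = xp, YP = YP,
    C1 = cx$C1, C2 = cx$C2, C3 = cx$C3)
}

#' Locate the fixed points of the loop at a chosen model level
#'
#' @param params a `loop_params` object.
#' @param level one of `"quartic"`, `"one_d"`, `"reduced3"`, `"full"`.
#' @param fit an [fit_inversion()] object; required for `level = "one_d"`
#'   (computed on the fly when omitted).
#' @param extra_seeds optional list of state vectors used as additional
#'   Newton starting points (warm starts during continuation).
#' @param eig_tol eigenvalue magnitude below which a point is labelled
#'   `marginal`.
#' @return a `fixed_point_set`: data frame with columns `model_level`,
#'   `XT`, `XP`, `YP`, `stability`, `leading_eigenvalue`, ordered by
#'   ascending XT, with the parameter snapshot in `attr(, "params")` and
#'   (full level) the complete states in `attr(, "states")`.  An empty
#'   set (with a warning) is returned when no root converges; a point is
#'   never fabricated.
#' @export
solve_fixed_points <- function(params, level = "quartic", fit = NULL,
                               extra_seeds = NULL, eig_tol = 1e-10) {
  level <- match.arg(level, model_levels)
  switch(level,
    quartic = fp_quartic(params, eig_tol),
    one_d = fp_one_d(params, fit, eig_tol),
    reduced3 = fp_reduced3(params, extra_seeds, eig_tol),
    full = fp_full(params, extra_seeds, eig_tol))
}

fp_set <- function(level, XT, XP, YP, ev, eig_tol, params, states = NULL) {
  o <- order(XT)
  out <- data.frame(
    model_level = rep(level, length(XT)),
    XT = XT[o], XP = XP[o], YP = YP[o],
    stability = vapply(ev[o], stability_label, "", tol = eig_tol),
    leading_eigenvalue = ev[o],
    stringsAsFactors = FALSE)
  class(out) <- c("fixed_point_set", "data.frame")
  attr(out, "params") <- params
  if (!is.null(states)) attr(out, "states") <- states[o]
  out
}

fp_quartic <- function(params, eig_tol) {
  xp <- steady_xp_roots(params)
  if (!length(xp)) {
    warning("no nonnegative steady-state polynomial root found")
    return(fp_set("quartic", numeric(0), numeric(0), numeric(0), numeric(0),
                  eig_tol, params))
  }
  xt <- xt_of_xp(xp, params)
  yp <- yp_nullcline(xp, params)
  ev <- vapply(xp, quartic_eigenvalue, 0, params = params)
  fp_set("quartic", xt, xp, yp, ev, eig_tol, params)
}

fp_one_d <- function(params, fit, eig_tol) {
  if (is.null(fit)) fit <- fit_inversion(params)
  g <- function(x) one_d_rhs(x, params, fit)
  xs <- seq(0, fit$domain_hi, length.out = 4000)
  v <- g(xs)
  roots <- 0  # h(0) = 0 makes the origin an exact fixed point
  idx <- which(diff(sign(v[-1])) != 0) + 1L
  for (i in idx) {
    r <- stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root
    if (all(abs(r - roots) > 1e-6 * max(r, 1))) roots <- c(roots, r)
  }
  ev <- vapply(roots, function(r) {
    h <- 1e-4 * max(r, 1)
    lo <- max(r - h, 0)
    (g(r + h) - g(lo)) / (r + h - lo)
  }, 0)
  xp <- pmax(eval_inversion(fit, roots), 0)
  fp_set("one_d", roots, xp, yp_nullcline(xp, params), ev, eig_tol, params)
}

fp_reduced3 <- function(params, extra_seeds, eig_tol) {
  f <- function(s) {
    s <- pmax(s, 0)
    unname(reduced3_core(s[1], s[2], s[3], params, params$U_basal))
  }
  xp_seeds <- steady_xp_roots(params)
  seeds <- c(
    list(c(0, 0, 0)),
    lapply(xp_seeds, function(xp) {
      c(xt_of_xp(xp, params), xp, yp_nullcline(xp, params))
    }),
    extra_seeds %||% list())
  roots <- list(); evs <- numeric(0)
  for (s in seeds) {
    r <- newton_root(f, pmax(s, 0))
    if (!r$converged || r$resid > 1e-9) next
    x <- pmax(r$x, 0)
    if (length(roots) &&
        any(vapply(roots, function(q) abs(q[1] - x[1]) <=
                     1e-6 * max(x[1], 1e-3), TRUE))) next
    J <- num_jacobian(f, x)
    evs <- c(evs, max(Re(eigen(J, only.values = TRUE)$values)))
    roots <- c(roots, list(x))
  }
  if (!length(roots)) {
    warning("no reduced3 fixed point converged from any seed")
    return(fp_set("reduced3", numeric(0), numeric(0), numeric(0), numeric(0),
                  eig_tol, params))
  }
  m <- do.call(rbind, roots)
  fp_set("reduced3", m[, 1], m[, 2], m[, 3], evs, eig_tol, params)
}

fp_full <- function(params, extra_seeds, eig_tol) {
  f <- function(s) unname(full_rhs(pmax(stats::setNames(s, full_fields), 0),
                                   params))
  xp_seeds <- steady_xp_roots(params)
  seeds <- c(
    list(c(params$Xbasal, params$XPbasal, 0, 0, 0, 0)),
    lapply(xp_seeds, full_seed_from_xp, params = params),
    extra_seeds %||% list())
  roots <- list(); evs <- numeric(0); xts <- numeric(0)
  for (s in seeds) {
    r <- newton_root(f, pmax(unname(unlist(s)), 0))
    if (!r$converged || r$resid > 1e-9) next
    x <- pmax(r$x, 0)
    xt <- x[1] + x[2] + 2 * x[4] + x[5]
    if (length(xts) && any(abs(xts - xt) <= 1e-6 * max(xt, 1e-3))) next
    J <- num_jacobian(f, x)
    evs <- c(evs, max(Re(eigen(J, only.values = TRUE)$values)))
    roots <- c(roots, list(stats::setNames(x, full_fields)))
    xts <- c(xts, xt)
  }
  if (!length(roots)) {
    warning("no full-model fixed point converged from any seed")
    return(fp_set("full", numeric(0), numeric(0), numeric(0), numeric(0),
                  eig_tol, params))
  }
  xp <- vapply(roots, `[[`, 0, "XP")
  yp <- vapply(roots, `[[`, 0, "YP")
  fp_set("full", xts, xp, yp, evs, eig_tol, params, states = roots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the stability of a fixed point
#'
#' Recomputes the leading eigenvalue at a point: central slope of the
#' single ODE for `one_d`/`quartic`, eigenvalues of the numerically
#' differentiated Jacobian for `reduced3`/`full`.  A near-zero leading
#' eigenvalue is refined with a smaller step before being labelled
#' `marginal`.
#'
#' @param fp one row of a `fixed_point_set` (a list/data frame row with
#'   `XT`, `XP`, `YP` and, for the full level, a state attribute) or a
#'   named state vector.
#' @param params the `loop_params` the point was computed under.
#' @param level model level of the point.
#' @param fit inversion fit (one_d level only).
#' @param eig_tol marginality tolerance on the eigenvalue (1/s).
#' @return list with `stability` and `leading_eigenvalue`.
#' @export
classify_stability <- function(fp, params, level = "quartic", fit = NULL,
                               eig_tol = 1e-10) {
  level <- match.arg(level, model_levels)
  ev <- switch(level,
    quartic = quartic_eigenvalue(fp$XP, params),
    one_d = {
      if (is.null(fit)) fit <- fit_inversion(params)
      g <- function(x) one_d_rhs(x, params, fit)
      h <- 1e-4 * max(fp$XT, 1)
      lo <- max(fp$XT - h, 0)
      (g(fp$XT + h) - g(lo)) / (fp$XT + h - lo)
    },
    reduced3 = {
      f <- function(s) {
        s <- pmax(s, 0)
        unname(reduced3_core(s[1], s[2], s[3], params, params$U_basal))
      }
      J <- num_jacobian(f, c(fp$XT, fp$XP, fp$YP))
      max(Re(eigen(J, only.values = TRUE)$values))
    },
    full = {
      st <- if (!is.null(fp$state)) fp$state else unlist(fp[full_fields])
      f <- function(s) unname(full_rhs(pmax(stats::setNames(s, full_fields), 0),
                                       params))
      J <- num_jacobian(f, unname(st))
      max(Re(eigen(J, only.values = TRUE)$values))
    })
  if (abs(ev) <= eig_tol && level %in% c("quartic", "one_d")) {
    # refinement pass with a tighter step before declaring marginality
    ev2 <- switch(level,
      quartic = quartic_eigenvalue(fp$XP, params),
      one_d = ev)
    ev <- ev2
  }
  list(stability = stability_label(ev, eig_tol), leading_eigenvalue = ev)
}

#' Compare fixed points across all four model levels
#'
#' Solves every level and aligns branches by stability pattern (lower
#' stable, unstable, upper stable) to report per-branch relative
#' discrepancies against the quartic reference.
#'
#' @param params a `loop_params` object.
#' @param fit optional inversion fit reused for the one_d level.
#' @return list with `sets` (named list of `fixed_point_set`s),
#'   `discrepancy` (data frame of relative XT differences vs quartic, NA
#'   where a branch is absent) and `max_discrepancy`.
#' @export
compare_levels <- function(params, fit = NULL) {
  sets <- list(
    quartic = solve_fixed_points(params, "quartic"),
    one_d = solve_fixed_points(params, "one_d", fit = fit),
    reduced3 = solve_fixed_points(params, "reduced3"),
    full = solve_fixed_points(params, "full"))
  branches <- function(s) {
    st <- s$XT[s$stability == "stable"]
    un <- s$XT[s$stability == "unstable"]
    c(lower = if (length(st)) min(st) else NA_real_,
      unstable = if (length(un)) un[which.max(un)] else NA_real_,
      upper = if (length(st)) max(st) else NA_real_)
  }
  br <- vapply(sets, branches, numeric(3))
  ref <- br[, "quartic"]
  # 0.5 uM floor so the basal branch is compared absolutely
  disc <- sweep(abs(br - ref), 1, pmax(abs(ref), 0.5), "/")
  disc_df <- as.data.frame(t(disc))
  disc_df$model_level <- rownames(disc_df)
  rownames(disc_df) <- NULL
  list(sets = sets, branches = as.data.frame(t(br)),
       discrepancy = disc_df,
       max_discrepancy = max(disc, na.rm = TRUE))
}

#' Diagnostic evaluation of the printed z-coefficients
#'
#' The published closed-form coefficients of the steady-state quartic
#' contain an undefined symbol F.  This diagnostic evaluates the printed
#' formulas with F substituted by each plausible candidate constant and
#' reports the relative mismatch against the coefficients obtained by
#' exact elimination; mismatches are reported, never used for
#' computation.
#'
#' @param params a `loop_params` object.
#' @param candidates named list of values tried for F.
#' @return data frame with one row per candidate and columns `z12`,
#'   `z13`, `z14` (relative mismatch vs eliminated).
#' @export
printed_z_diagnostic <- function(params,
                                 candidates = NULL) {
  d <- derive_constants(params)
  if (is.null(candidates)) {
    candidates <- list(P4 = d$P4, k1010 = params$k1010, DI = d$DI,
                       a1 = d$a1, Mk3 = d$M * params$k3)
  }
  sp <- steady_state_polynomial(params)
  U <- params$U_basal
  rows <- lapply(names(candidates), function(nm) {
    FF <- candidates[[nm]]
    z1 <- d$a * d$c * d$M * params$k3 * d$P7
    z2 <- d$a * d$c * params$k10 * U * d$P7
    z3 <- d$a^2 * d$c * d$M * params$k3
    z4 <- d$a^2 * d$c * FF * params$k10 * U
    z5 <- 2 * d$P4 * d$M * FF + 2 * d$M * params$k1010 * FF + FF * d$M * params$k3
    z6 <- 2 * d$P4 * d$P7 * d$M + 2 * d$M * d$P7 * params$k1010 + FF * d$P4 +
      FF * params$k1010 + d$M * params$k3 * d$P7 + FF * params$k10 * U +
      d$N * d$M * params$k3 * params$YT
    z7 <- d$P7 * d$P4 + d$P7 * params$k1010 + params$k10 * U * d$P7 +
      d$N * params$k10 * U * d$P7 * params$YT
    z8 <- d$a * z5
    z9 <- d$a * z6 + d$P7 * z5 - z3
    z10 <- d$a * z7 + d$P7 * z6 - z1 - z4
    z11 <- d$P7 * z7 - z2
    zz <- c(z12 = z9 / z8, z13 = z10 / z8, z14 = z11 / z8)
    ref <- c(z12 = sp$z12, z13 = sp$z13, z14 = sp$z14)
    abs(zz - ref) / pmax(abs(ref), 1e-300)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$candidate <- names(candidates)
  out[, c("candidate", "z12", "z13", "z14")]
}
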