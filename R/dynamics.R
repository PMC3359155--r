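# Time integration through stimulus protocols.
#
# The Ca4CaM input U(t) is a square pulse; integration is split at the
# pulse edges so the discontinuity is never smoothed across.  All levels
# use lsoda with rtol 1e-8 / atol 1e-12 uM, tolerances chosen for the
# six-order-of-magnitude spread between the basal (1e-4 uM) and
# up-regulated (~1e2 uM) states.

#' Construct a square Ca4CaM stimulus protocol
#'
#' @param duration pulse length in seconds (>= 0; 0 gives a null
#'   stimulus).
#' @param amplitude Ca4CaM concentration during the pulse (uM).
#' @param t_on pulse onset time (s).
#' @param U_baseline Ca4CaM outside the pulse (uM).
#' @return object of class `stimulus_protocol`.
#' @export
make_stimulus <- function(duration = 10, amplitude = 10, t_on = 10,
                          U_baseline = 1e-6) {
  if (duration < 0) loop_error("duration must be >= 0", "loop_invalid_input")
  if (amplitude < 0) loop_error("amplitude must be >= 0", "loop_invalid_input")
  if (amplitude < U_baseline) {
    loop_error("amplitude must be >= U_baseline", "loop_invalid_input")
  }
  structure(list(t_on = t_on, duration = duration, U_stim = amplitude,
                 U_baseline = U_baseline),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> U = %.3g uM for t in [%g, %g] s, baseline %.3g uM\n",
              x$U_stim, x$t_on, x$t_on + x$duration, x$U_baseline))
  invisible(x)
}

default_down_state <- function(params, level) {
  switch(level,
    full = c(X = params$Xbasal, XP = params$XPbasal, YP = 0,
             C1 = 0, C2 = 0, C3 = 0),
    reduced3 = c(XT = params$Xbasal + params$XPbasal, XP = params$XPbasal,
                 YP = 0),
    one_d = c(XT = params$Xbasal + params$XPbasal))
}

#' Primed initial state for up-state runs
#'
#' A bolus of phosphorylated kinase equal to `margin` times the
#' separatrix (the unstable fixed point's XT at the quartic level) is
#' added to the basal state.  A 10-s Ca4CaM pulse alone cannot carry the
#' basal pool (1e-4 uM) across a separatrix near 10 uM -- synthesis is
#' capped at c uM/s and phospho-CPEB1 charging at a*YT*XP uM/s -- so
#' up-state experiments start from this primed state and the pulse is
#' applied on top of it.
#'
#' @param params a `loop_params` object.
#' @param level model level the state is built for.
#' @param margin multiple of the separatrix XT used for the bolus.
#' @return state vector appropriate for [integrate_loop()] at `level`.
#' @export
up_state_init <- function(params, level = "full", margin = 2) {
  level <- match.arg(level, c("full", "reduced3", "one_d"))
  fps <- solve_fixed_points(params, "quartic")
  un <- fps$XT[fps$stability == "unstable"]
  if (!length(un)) {
    loop_error("system is not bistable: no separatrix to clear",
               "loop_degenerate_input")
  }
  xp0 <- margin * max(un)
  switch(level,
    full = c(X = params$Xbasal, XP = xp0, YP = 0, C1 = 0, C2 = 0, C3 = 0),
    reduced3 = c(XT = params$Xbasal + xp0, XP = xp0, YP = 0),
    one_d = c(XT = params$Xbasal + xp0))
}

#' Integrate the loop through a stimulus protocol
#'
#' Integrates the chosen model level from `state0` through the square
#' pulse of `protocol` up to `t_end`, splitting the integration at the
#' pulse edges.  The one-variable model has no Ca4CaM dependence; the
#' protocol is carried along for bookkeeping only.
#'
#' @param params a `loop_params` object.
#' @param state0 initial state for the level (default: basal down state).
#' @param protocol a `stimulus_protocol` (default: null stimulus at the
#'   basal Ca4CaM level).
#' @param t_end end time (s); must exceed the pulse end.
#' @param level `"full"`, `"reduced3"` or `"one_d"`.
#' @param fit inversion fit (one_d only; computed if omitted).
#' @param n_out approximate number of saved time points.
#' @return a `loop_trajectory`: data frame with `t`, the state columns
#'   and `XT`, with the protocol and parameters as attributes.  States
#'   are clipped at zero within a -1e-9 numerical slack; larger
#'   negativity raises an error.
#' @export
integrate_loop <- function(params, state0 = NULL, protocol = NULL,
                           t_end = 10 / lambda_reduced(params),
                           level = "full", fit = NULL, n_out = 400) {
  level <- match.arg(level, c("full", "reduced3", "one_d"))
  if (is.null(protocol)) {
    protocol <- make_stimulus(duration = 0, amplitude = params$U_basal,
                              t_on = 0, U_baseline = params$U_basal)
  }
  if (is.null(state0)) state0 <- default_down_state(params, level)
  pulse_end <- protocol$t_on + protocol$duration
  if (protocol$duration > 0 && t_end <= pulse_end) {
    loop_error("t_end must exceed the end of the stimulus pulse",
               "loop_invalid_input")
  }
  if (level == "one_d" && is.null(fit)) fit <- fit_inversion(params)

  deriv <- switch(level,
    full = function(t, y, parms) {
      list(unname(full_rhs(stats::setNames(pmax(y, 0), full_fields), params,
                           U = parms$U)))
    },
    reduced3 = function(t, y, parms) {
      y <- pmax(y, 0)
      list(unname(reduced3_core(y[1], y[2], y[3], params, parms$U)))
    },
    one_d = function(t, y, parms) {
      list(one_d_rhs(min(max(y, 0), fit$domain_hi), params, fit))
    })

  edges <- sort(unique(c(0, protocol$t_on, pulse_end, t_end)))
  edges <- edges[edges >= 0 & edges <= t_end]
  segs <- cbind(utils::head(edges, -1), utils::tail(edges, -1))
  u_of <- function(t0) {
    if (protocol$duration > 0 && t0 >= protocol$t_on && t0 < pulse_end) {
      protocol$U_stim
    } else protocol$U_baseline
  }
  y <- unname(state0)
  rows <- NULL
  for (i in seq_len(nrow(segs))) {
    tt <- seq(segs[i, 1], segs[i, 2],
              length.out = max(3, ceiling(n_out * (segs[i, 2] - segs[i, 1]) /
                                            t_end)))
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(U = u_of(segs[i, 1])),
                          rtol = 1e-8, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0) {
      loop_error(sprintf("integrator failed on [%g, %g] s",
                         segs[i, 1], segs[i, 2]), "loop_integration_failure")
    }
    m <- as.matrix(sol)
    if (min(m[, -1]) < -1e-9) {
      loop_error("trajectory left the nonnegative orthant beyond tolerance",
                 "loop_integration_failure")
    }
    m[, -1][m[, -1] < 0] <- 0
    rows <- rbind(rows, if (is.null(rows)) m else m[-1, , drop = FALSE])
    y <- unname(m[nrow(m), -1])
  }
  nm <- switch(level, full = full_fields, reduced3 = c("XT", "XP", "YP"),
               one_d = "XT")
  out <- as.data.frame(rows)
  names(out) <- c("t", nm)
  out$XT <- switch(level,
    full = out$X + out$XP + 2 * out$C1 + out$C2,
    reduced3 = out$XT,
    one_d = out$XT)
  class(out) <- c("loop_trajectory", "data.frame")
  attr(out, "level") <- level
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  out
}

#' Minimal stimulus that reaches the up-regulated basin
#'
#' Bisection over one stimulus knob: the priming bolus `xp0` (initial
#' phosphorylated-kinase concentration), the pulse `duration`, or the
#' pulse amplitude `U_stim`.  A run is classified "up" when the terminal
#' XT exceeds the midpoint between the unstable and upper fixed points.
#' With the reference configuration only `xp0` admits a finite
#' threshold: no physiological Ca4CaM pulse can move the basal pool
#' across the separatrix (see [up_state_init()]), and in that case the
#' result is marked `no_switch`.
#'
#' @param params a `loop_params` object (must be bistable).
#' @param level model level used for the trial integrations.
#' @param vary which stimulus parameter to bisect over.
#' @param lo,hi initial bracket for the varied parameter.
#' @param t_end integration horizon per trial (s).
#' @param rel_tol relative bracket width at which bisection stops.
#' @param protocol base protocol for the trials.
#' @return list with `threshold` (NA if no switching in the bracket),
#'   `bracket`, `vary`, and `bistable`.
#' @export
switching_threshold <- function(params, level = "reduced3",
                                vary = c("xp0", "duration", "U_stim"),
                                lo = NULL, hi = NULL,
                                t_end = 20 / lambda_reduced(params),
                                rel_tol = 0.01, protocol = NULL) {
  vary <- match.arg(vary)
  fps <- solve_fixed_points(params, "quartic")
  un <- fps$XT[fps$stability == "unstable"]
  up <- max(fps$XT[fps$stability == "stable"])
  if (!length(un) || up <= max(un)) {
    return(list(threshold = NA_real_, bracket = c(NA_real_, NA_real_),
                vary = vary, bistable = FALSE))
  }
  sep <- max(un)
  cut <- (sep + up) / 2
  if (is.null(protocol)) {
    protocol <- make_stimulus(duration = 10, amplitude = 10,
                              U_baseline = params$U_basal)
  }
  if (is.null(lo)) lo <- switch(vary, xp0 = 0, duration = 0, U_stim = 0)
  if (is.null(hi)) hi <- switch(vary, xp0 = 4 * sep, duration = 100,
                                U_stim = 1e3)
  goes_up <- function(v) {
    pr <- protocol
    s0 <- default_down_state(params, level)
    if (vary == "xp0") {
      s0 <- switch(level,
        full = c(X = params$Xbasal, XP = v, YP = 0, C1 = 0, C2 = 0, C3 = 0),
        reduced3 = c(XT = params$Xbasal + v, XP = v, YP = 0),
        one_d = c(XT = params$Xbasal + v))
    } else if (vary == "duration") {
      pr$duration <- v
    } else {
      pr$U_stim <- max(v, pr$U_baseline)
    }
    tr <- integrate_loop(params, state0 = s0, protocol = pr,
                         t_end = max(t_end, pr$t_on + pr$duration + 1),
                         level = level, n_out = 50)
    utils::tail(tr$XT, 1) > cut
  }
  if (goes_up(lo)) {
    return(list(threshold = lo, bracket = c(lo, lo), vary = vary,
                bistable = TRUE))
  }
  if (!goes_up(hi)) {
    return(list(threshold = NA_real_, bracket = c(lo, hi), vary = vary,
                bistable = TRUE, no_switch = TRUE))
  }
  while ((hi - lo) > rel_tol * max(abs(hi), 1e-12)) {
    mid <- (lo + hi) / 2
    if (goes_up(mid)) hi <- mid else lo <- mid
  }
  list(threshold = (lo + hi) / 2, bracket = c(lo, hi), vary = vary,
       bistable = TRUE)
}
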