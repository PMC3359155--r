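# Small numerical utilities shared across the package: classed error
# conditions, polynomial arithmetic for the steady-state elimination, a
# numerical Jacobian, and a damped Newton root finder used for the
# three-variable and six-variable fixed-point solves.

loop_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "loop_error")))
}

#' @noRd
check_nonneg <- function(x, what) {
  if (any(!is.finite(x))) {
    loop_error(sprintf("%s contains non-finite values", what), "loop_invalid_input")
  }
  if (any(x < 0)) {
    loop_error(sprintf("%s must be nonnegative", what), "loop_invalid_input")
  }
  invisible(x)
}

# polynomial coefficient vectors in ascending powers
poly_mul <- function(u, v) {
  n <- length(u) + length(v) - 1L
  r <- numeric(n)
  for (i in seq_along(u)) {
    idx <- i:(i + length(v) - 1L)
    r[idx] <- r[idx] + u[i] * v
  }
  r
}

poly_add <- function(u, v) {
  n <- max(length(u), length(v))
  c(u, numeric(n - length(u))) + c(v, numeric(n - length(v)))
}

#' Numerical Jacobian by forward differences
#'
#' @param f vector-valued function of a numeric vector.
#' @param x point of evaluation.
#' @param eps relative step size.
#' @return the Jacobian matrix df_i/dx_j.
#' @keywords internal
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  n <- length(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[j]), 1)
    xj <- x
    xj[j] <- x[j] + h
    J[, j] <- (f(xj) - f0) / h
  }
  J
}

#' Damped Newton iteration for square nonlinear systems
#'
#' Step-halving line search on the residual sum of squares; a step that
#' throws (e.g. an infeasible composition inside the reduced model) is
#' treated as an increase and halved.
#'
#' @param f residual function, length(f(x)) == length(x).
#' @param x0 starting point.
#' @param tol convergence tolerance on max |f|.
#' @param maxit maximum Newton iterations.
#' @return list with elements `x`, `converged`, `iterations`, `resid`.
#' @keywords internal
newton_root <- function(f, x0, tol = 1e-11, maxit = 200) {
  x <- x0
  safe_ss <- function(x) {
    v <- tryCatch(f(x), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v))) Inf else sum(v^2)
  }
  for (i in seq_len(maxit)) {
    fx <- tryCatch(f(x), error = function(e) NULL)
    if (is.null(fx) || any(!is.finite(fx))) {
      return(list(x = x, converged = FALSE, iterations = i, resid = Inf))
    }
    if (max(abs(fx)) < tol) {
      return(list(x = x, converged = TRUE, iterations = i, resid = max(abs(fx))))
    }
    J <- num_jacobian(f, x)
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) {
      return(list(x = x, converged = FALSE, iterations = i, resid = max(abs(fx))))
    }
    s0 <- sum(fx^2)
    lam <- 1
    repeat {
      xn <- x + lam * dx
      if (safe_ss(xn) < s0 || lam < 1e-10) break
      lam <- lam / 2
    }
    if (lam < 1e-10) {
      return(list(x = x, converged = FALSE, iterations = i, resid = max(abs(fx))))
    }
    x <- xn
  }
  fx <- tryCatch(f(x), error = function(e) rep(Inf, length(x)))
  list(x = x, converged = max(abs(fx)) < 1e-9, iterations = maxit,
       resid = max(abs(fx)))
}
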