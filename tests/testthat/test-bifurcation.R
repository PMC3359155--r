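lambda_grid <- sort(unique(c(seq(2e-5, 1e-3, length.out = 60),
                             c(6e-5, 1e-4, 3e-4, 6e-4))))

test_that("the degradation sweep moves the loop from bistable to mono-stable", {
  p <- frozen_test_params()
  dg <- sweep_bifurcation(p, "lambda", lambda_grid, level = "quartic")
  counts <- vapply(dg$sets, nrow, 0L)
  for (lam in c(6e-5, 1e-4, 3e-4)) {
    expect_equal(counts[which.min(abs(dg$grid - lam))], 3L)
  }
  # by the top of the table's lambda range degradation wins outright
  expect_equal(counts[length(counts)], 1L)
  expect_length(dg$saddle_nodes, 1)
  # upper branch decreases monotonically with lambda (c/lambda scaling)
  up <- vapply(dg$sets, function(s) {
    st <- s$XT[s$stability == "stable"]
    if (length(st) && max(st) > 1) max(st) else NA_real_
  }, 0)
  up <- up[!is.na(up)]
  expect_true(all(diff(up) < 0))
  # parity: one boundary crossing of bistability, one saddle-node
  expect_equal(length(dg$saddle_nodes) %% 2,
               as.integer(counts[1] >= 3) - as.integer(counts[length(counts)] >= 3))
})

test_that("the upper state tracks the saturation limit c/lambda", {
  p <- frozen_test_params()
  d <- derive_constants(p)
  for (lam in c(1e-4, 3e-4)) {
    q <- p; q$lambda1 <- q$lambda2 <- lam
    fps <- solve_fixed_points(validate_params(q), "quartic")
    up <- max(fps$XT[fps$stability == "stable"])
    expect_equal(up, d$c / lam, tolerance = 0.1)
  }
})

test_that("a single-point grid degenerates to one fixed-point set", {
  p <- frozen_test_params()
  dg <- sweep_bifurcation(p, "lambda", 1e-4, level = "quartic")
  expect_length(dg$sets, 1)
  expect_equal(sort(dg$sets[[1]]$XT),
               sort(solve_fixed_points(p, "quartic")$XT))
  expect_error(sweep_bifurcation(p, "lambda", numeric(0)),
               class = "loop_invalid_input")
})

test_that("CPEB1 activation sustains bistability across three decades", {
  p <- frozen_test_params()
  dk <- sweep_bifurcation(p, "k5", 10^seq(-5, -1, length.out = 200),
                          level = "quartic")
  br <- bistable_range(dk)
  expect_false(br$empty)
  expect_gte(br$decades, 3)
  # the weakest activation on the grid is mono-stable
  expect_equal(nrow(dk$sets[[1]]), 1L)
  # an everywhere-mono-stable diagram yields an empty interval
  q <- p; q$lambda1 <- q$lambda2 <- 5e-3
  dmono <- sweep_bifurcation(validate_params(q), "lambda",
                             c(4e-3, 5e-3, 6e-3), level = "quartic")
  expect_true(bistable_range(dmono)$empty)
})

test_that("branch collision at the saddle-node and hysteresis of quasi-static sweeps", {
  p <- frozen_test_params()
  dg <- sweep_bifurcation(p, "lambda", lambda_grid, level = "quartic")
  sn <- dg$saddle_nodes[1]
  # collision: just inside bistability the unstable and upper branches
  # have nearly merged
  q <- p; q$lambda1 <- q$lambda2 <- sn * 0.995
  fps <- solve_fixed_points(validate_params(q), "quartic")
  expect_equal(nrow(fps), 3)
  expect_lt(abs(fps$XT[3] - fps$XT[2]) / fps$XT[3], 0.5)

  # quasi-static forward sweep in lambda: ride the upper branch, then
  # jump to basal within one grid step of the recorded saddle-node
  fit <- fit_inversion(p)
  lams <- 10^seq(log10(1e-4), log10(1e-3), length.out = 40)
  x <- max(solve_fixed_points(p, "one_d", fit = fit)$XT)
  trace_fwd <- numeric(length(lams))
  for (i in seq_along(lams)) {
    q <- p; q$lambda1 <- q$lambda2 <- lams[i]
    tr <- integrate_loop(validate_params(q), state0 = x, t_end = 8 / lams[i],
                         level = "one_d", fit = fit, n_out = 12)
    x <- tail(tr$XT, 1)
    trace_fwd[i] <- x
  }
  # the jump is the collapse onto the basal branch, not the smooth
  # decline of the upper branch with lambda
  jump <- which(trace_fwd < 1 & c(Inf, utils::head(trace_fwd, -1)) > 5)[1]
  expect_false(is.na(jump))
  expect_gte(sn, lams[jump - 1])
  expect_lte(sn, lams[jump])
  # backward sweep from the mono-stable side never jumps up: in this
  # lambda range the switch is one-sided (irreversible by degradation)
  x <- 1e-4
  trace_bwd <- numeric(length(lams))
  for (i in rev(seq_along(lams))) {
    q <- p; q$lambda1 <- q$lambda2 <- lams[i]
    tr <- integrate_loop(validate_params(q), state0 = x, t_end = 8 / lams[i],
                         level = "one_d", fit = fit, n_out = 12)
    x <- tail(tr$XT, 1)
    trace_bwd[i] <- x
  }
  expect_lt(max(trace_bwd), 1)
})

test_that("diagrams from all levels match in condition I but not condition II", {
  cfg <- frozen_test_config()
  grid <- seq(6e-5, 4e-4, length.out = 12)
  pI <- make_condition("I", cfg)
  # shared fit sized so the upper branch at the smallest lambda is inside
  # the fit domain (the steady map itself does not depend on lambda)
  q <- pI; q$lambda1 <- q$lambda2 <- grid[1]
  fitI <- fit_inversion(validate_params(q))
  dI <- lapply(c("quartic", "one_d", "reduced3", "full"), function(lv) {
    sweep_bifurcation(pI, "lambda", grid, level = lv,
                      fit = if (lv == "one_d") fitI)
  })
  agI <- diagram_agreement(dI)
  expect_identical(agI$verdict, "match")

  pII <- make_condition("II", cfg)
  dII <- lapply(c("quartic", "full"), function(lv) {
    sweep_bifurcation(pII, "lambda", grid, level = lv)
  })
  agII <- diagram_agreement(dII)
  expect_identical(agII$verdict, "mismatch")
  expect_gt(agII$per_branch["full", "upper"], 1)

  # a diagram agrees with itself exactly
  self <- diagram_agreement(list(dI[[1]], dI[[1]]))
  expect_equal(self$pairwise_max, 0)
  expect_error(
    diagram_agreement(list(dI[[1]],
                           sweep_bifurcation(pI, "lambda", grid[1:3]))),
    class = "loop_invalid_input")
})
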