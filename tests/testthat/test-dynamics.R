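test_that("the basal state is invariant without a stimulus", {
  p <- frozen_test_params()
  tr <- integrate_loop(p, t_end = 2e4, level = "full", n_out = 30)
  expect_lt(abs(tail(tr$XT, 1) - (p$Xbasal + p$XPbasal)), 1e-6)
  expect_true(all(tr$XT >= 0))
  # a null-duration pulse is a null stimulus
  pr0 <- make_stimulus(duration = 0, amplitude = 10, U_baseline = p$U_basal)
  tr0 <- integrate_loop(p, protocol = pr0, t_end = 2e4, level = "full",
                        n_out = 30)
  expect_lt(abs(tail(tr0$XT, 1) - (p$Xbasal + p$XPbasal)), 1e-6)
})

test_that("protocol preconditions are enforced", {
  p <- frozen_test_params()
  expect_error(make_stimulus(duration = -1), class = "loop_invalid_input")
  expect_error(make_stimulus(amplitude = -2), class = "loop_invalid_input")
  pr <- make_stimulus(duration = 10, amplitude = 10, t_on = 10)
  expect_error(integrate_loop(p, protocol = pr, t_end = 15, level = "full"),
               class = "loop_invalid_input")
})

test_that("condition-I up-state runs converge to the same state at all levels", {
  cfg <- frozen_test_config()
  p <- make_condition("I", cfg)
  pr <- make_stimulus(10, cfg$U_stim, U_baseline = p$U_basal)
  for (lv in c("full", "reduced3", "one_d")) {
    tr <- integrate_loop(p, state0 = up_state_init(p, lv, cfg$prime_margin),
                         protocol = pr, t_end = 60 / p$lambda1, level = lv,
                         n_out = 60)
    fps <- solve_fixed_points(p, lv)
    up <- max(fps$XT[fps$stability == "stable"])
    # terminal state sits on the level's own upper fixed point
    expect_equal(tail(tr$XT, 1), up, tolerance = 1e-4)
    # and all levels land near the published up state of 95 uM
    expect_equal(tail(tr$XT, 1), 95, tolerance = 0.01)
    expect_true(all(tr$XT > -1e-12))
  }
})

test_that("pseudo-steady-state reduction accelerates the approach to the up state", {
  cfg <- frozen_test_config()
  p <- make_condition("I", cfg)
  pr <- make_stimulus(10, cfg$U_stim, U_baseline = p$U_basal)
  half_time <- function(lv) {
    tr <- integrate_loop(p, state0 = up_state_init(p, lv, cfg$prime_margin),
                         protocol = pr, t_end = 60 / p$lambda1, level = lv,
                         n_out = 4000)
    target <- max(tr$XT) / 2
    i <- which(tr$XT >= target)[1]
    tr$t[i - 1] + (target - tr$XT[i - 1]) / (tr$XT[i] - tr$XT[i - 1]) *
      (tr$t[i] - tr$t[i - 1])
  }
  expect_gt(half_time("full"), half_time("reduced3"))
})

test_that("switching thresholds bracket the separatrix and shrink with k5", {
  cfg <- frozen_test_config()
  p <- make_condition("I", cfg)
  th <- switching_threshold(p, level = "reduced3", vary = "xp0")
  expect_true(th$bistable)
  expect_false(is.na(th$threshold))
  sep <- solve_fixed_points(p, "quartic")$XT[2]
  # the bolus threshold sits at the separatrix scale
  expect_gt(th$threshold, 0.5 * sep)
  expect_lt(th$threshold, 2 * sep)

  p_lo <- p; p_lo$k5 <- 1e-4
  th_lo <- switching_threshold(validate_params(p_lo), level = "reduced3",
                               vary = "xp0")
  # weaker CPEB1 activation raises the barrier
  expect_gt(th_lo$threshold, th$threshold)

  # no physiological Ca4CaM pulse can switch the basal pool
  th_u <- switching_threshold(p, level = "reduced3", vary = "U_stim",
                              t_end = 5e4)
  expect_true(is.na(th_u$threshold))

  # mono-stable configuration: no threshold at all
  p_mono <- p; p_mono$lambda1 <- p_mono$lambda2 <- 0.05
  th_m <- switching_threshold(validate_params(p_mono))
  expect_false(th_m$bistable)
})

test_that("protocols compose sequentially across chained integrations", {
  cfg <- frozen_test_config()
  p <- make_condition("I", cfg)
  pr <- make_stimulus(10, cfg$U_stim, t_on = 10, U_baseline = p$U_basal)
  one <- integrate_loop(p, state0 = up_state_init(p, "reduced3"),
                        protocol = pr, t_end = 4e4, level = "reduced3",
                        n_out = 50)
  a <- integrate_loop(p, state0 = up_state_init(p, "reduced3"),
                      protocol = pr, t_end = 2e4, level = "reduced3",
                      n_out = 50)
  b <- integrate_loop(p, state0 = unlist(a[nrow(a), c("XT", "XP", "YP")]),
                      t_end = 2e4, level = "reduced3", n_out = 50)
  expect_equal(tail(b$XT, 1), tail(one$XT, 1), tolerance = 1e-6)
})
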