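test_that("the steady-state polynomial is quartic with zero constant term", {
  p <- frozen_test_params()
  sp <- steady_state_polynomial(p)
  expect_identical(sp$coefficients[1], 0)   # XP = 0 always a steady state
  expect_length(sp$coefficients, 5)
  expect_gt(abs(sp$coefficients[5]), 0)     # degree exactly 4
  expect_identical(sp$provenance, "eliminated")
  # monic normalization is consistent
  expect_equal(sp$z12, sp$coefficients[4] / sp$coefficients[5])
})

test_that("without synthesis the basal state is the only steady state", {
  for (knock in list(c(k9 = 0), c(YT = 0))) {
    p <- frozen_test_params()
    p[names(knock)] <- knock
    p <- validate_params(p)
    fps <- solve_fixed_points(p, "quartic")
    expect_lte(sum(fps$XT > 0.5), 0)
    expect_true(all(fps$stability[fps$XT < 0.5] == "stable"))
  }
})

test_that("quartic roots match a dense scan of the reduced XP balance", {
  p <- frozen_test_params()
  lam <- p$lambda1
  # oracle: along the XP nullcline map, scan the remaining pool balance
  # k9*C3(YP(XP)) - lambda*XT(XP) for sign changes
  balance <- function(XP) {
    C3 <- p$k8 * yp_nullcline(XP, p) * p$T / (p$k88 + p$k9)
    p$k9 * C3 - lam * xt_of_xp(XP, p)
  }
  xs <- 10^seq(-6, log10(200), length.out = 4000)
  v <- balance(xs)
  idx <- which(diff(sign(v)) != 0)
  scan_roots <- sort(vapply(idx, function(i)
    uniroot(balance, c(xs[i], xs[i + 1]), tol = 1e-13)$root, 0))
  fps <- solve_fixed_points(p, "quartic")
  poly_roots <- sort(fps$XP[fps$XP > 0])
  expect_length(scan_roots, length(poly_roots))
  expect_equal(poly_roots, scan_roots, tolerance = 1e-6)
})

test_that("stability labels follow the one-dimensional flow topology", {
  p <- frozen_test_params()
  fps <- solve_fixed_points(p, "quartic")
  expect_equal(nrow(fps), 3)
  expect_equal(fps$stability, c("stable", "unstable", "stable"))
  # basal root is stable whenever degradation beats the synthesis slope
  expect_lt(fps$leading_eigenvalue[1], 0)
  cl <- classify_stability(fps[2, ], p, level = "quartic")
  expect_identical(cl$stability, "unstable")
})

test_that("eigenvalue signs agree with forward-integration fates", {
  base <- frozen_test_params()
  ens <- perturb_ensemble(base, c("k5", "k7", "k9"), decades = 0.4, n = 50,
                          seed = 42)
  checked <- 0
  for (i in seq_len(ens$n)) {
    p <- ensemble_params(ens, i)
    fps <- solve_fixed_points(p, "reduced3")
    if (nrow(fps) < 3) next
    for (k in c(2, 3)) {  # separatrix and upper state
      x0 <- c(fps$XT[k], fps$XP[k], fps$YP[k]) * 1.01
      tr <- integrate_loop(p, state0 = x0, t_end = 3e4, level = "reduced3",
                           n_out = 10)
      moved <- abs(tail(tr$XT, 1) - fps$XT[k])
      start <- abs(x0[1] - fps$XT[k])
      if (fps$stability[k] == "stable") {
        expect_lt(moved, start)
      } else {
        expect_gt(moved, 10 * start)
      }
      checked <- checked + 1
    }
  }
  expect_gte(checked, 80)  # ensemble stays overwhelmingly bistable
})

test_that("model levels agree in condition I and split in condition II", {
  cfg <- frozen_test_config()
  cmpI <- compare_levels(make_condition("I", cfg))
  expect_lt(cmpI$max_discrepancy, 0.15)
  cmpII <- compare_levels(make_condition("II", cfg))
  bII <- cmpII$branches
  # complex trapping: the full model's up state far exceeds the reduced
  # levels', while lower/unstable branches stay close
  expect_gt(bII["full", "upper"] / bII["quartic", "upper"], 1.5)
  expect_lt(max(cmpII$discrepancy$unstable[cmpII$discrepancy$model_level !=
                                             "full"]), 0.15)
})

test_that("overwhelming degradation leaves a single basal state everywhere", {
  p <- frozen_test_params()
  p$lambda1 <- p$lambda2 <- 0.05
  p <- validate_params(p)
  for (lv in c("quartic", "reduced3", "full")) {
    fps <- solve_fixed_points(p, lv)
    expect_equal(sum(fps$stability == "stable"), 1)
    expect_lt(max(fps$XT), 0.5)
  }
})

test_that("printed z-coefficients with undefined F never reproduce the elimination", {
  p <- frozen_test_params()
  dg <- printed_z_diagnostic(p)
  expect_named(dg, c("candidate", "z12", "z13", "z14"))
  expect_gte(nrow(dg), 5)
  # every candidate for the undefined symbol F leaves a reported mismatch
  worst <- apply(dg[, c("z12", "z13", "z14")], 1, max)
  expect_true(all(worst > 0.01))
})
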