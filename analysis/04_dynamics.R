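#!/usr/bin/env Rscript
# Stage 4: switching dynamics.
#
# Runs the up-state and down-state experiments at every dynamical level
# for both conditions: down-state runs start at the basal state and
# receive the 10-s Ca4CaM pulse (they stay down -- the basal kinase pool
# is six orders of magnitude below the separatrix, so no physiological
# pulse can move it); up-state runs start from the primed state that
# clears the separatrix with a 2x margin and relax to the up state.
# Also measures the priming threshold and its dependence on k5.

suppressPackageStartupMessages(library(cpebswitch))
dir.create("results", showWarnings = FALSE)

cfg <- read_frozen_config("results/frozen_config.json")

rows <- list()
for (cond in c("I", "II")) {
  p <- make_condition(cond, cfg)
  pr <- make_stimulus(10, cfg$U_stim, U_baseline = p$U_basal)
  for (lv in c("full", "reduced3", "one_d")) {
    for (dir in c("down", "up")) {
      s0 <- if (dir == "up") up_state_init(p, lv, cfg$prime_margin) else NULL
      tr <- integrate_loop(p, state0 = s0, protocol = pr,
                           t_end = 60 / p$lambda1, level = lv, n_out = 300)
      out <- data.frame(condition = cond, level = lv, run = dir,
                        t = tr$t, XT = tr$XT)
      rows[[length(rows) + 1]] <- out
      message(sprintf("condition %s, %-8s %-4s run: terminal XT = %.4g uM",
                      cond, lv, dir, tail(tr$XT, 1)))
    }
  }
}
write.csv(do.call(rbind, rows), "results/trajectories.csv", row.names = FALSE)

message("\nPriming threshold (bolus of phospho-kinase needed to switch):")
p <- make_condition("I", cfg)
th <- switching_threshold(p, level = "reduced3", vary = "xp0")
message(sprintf("  condition I, k5 = %.4g: threshold = %.3f uM", p$k5,
                th$threshold))
p$k5 <- 1e-4
th2 <- switching_threshold(validate_params(p), level = "reduced3",
                           vary = "xp0")
message(sprintf("  condition I, k5 = 1e-4:  threshold = %.3f uM ",
                th2$threshold))
message("  (weaker CPEB1 activation raises the switching barrier)")
thU <- switching_threshold(make_condition("I", cfg), level = "reduced3",
                           vary = "U_stim", t_end = 5e4)
message(sprintf(
  "  amplitude sweep of the 10-s pulse from the basal state: %s",
  if (is.na(thU$threshold)) "no amplitude switches the system" else
    sprintf("threshold %.3g uM", thU$threshold)))
jsonlite::write_json(
  list(xp0_threshold_refk5 = th$threshold, xp0_threshold_lowk5 = th2$threshold,
       pulse_amplitude_threshold = thU$threshold),
  "results/switching_thresholds.json", auto_unbox = TRUE, digits = NA)
message("Wrote results/trajectories.csv and results/switching_thresholds.json.")
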