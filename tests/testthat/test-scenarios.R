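# Copy-number perturbation experiments and the Alu-free reduced model.

p <- model_parameters()

test_that("copy-number sweeps deepen monotonically with the initial fold", {
  sw <- copy_number_sweep(p, "L1", folds = c(1, 10, 100, 1000),
                          ref = eb_ref_ss())
  expect_identical(sw$T_drop[1], 0)
  expect_false(sw$crossed[1])
  expect_true(all(diff(sw$T_drop) >= 0))
  expect_true(all(diff(sw$a_min) < 0))
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})

test_that("equal 1000-fold boosts: Alu acts faster and deeper, L1 longer", {
  dmL <- eb_boost_metrics("L1")
  dmS <- eb_boost_metrics("Alu")
  expect_true(dmL$crossed && dmS$crossed)
  expect_gt(dmL$T_drop, dmS$T_drop)
  expect_lt(dmS$a_min, dmL$a_min)
})

test_that("threshold folds bracket the crossing monotonically", {
  tf <- eb_threshold_fold("L1")
  ss <- eb_ref_ss()
  thr <- 0.30 * ss$state[["a"]]
  below <- simulate_trajectory(
    p, perturb_initial_state(ss$state, fold_L1 = tf / 1.3), t_end = 1e3)
  above <- simulate_trajectory(
    p, perturb_initial_state(ss$state, fold_L1 = tf * 1.3), t_end = 1e3)
  expect_gt(min(below$a), thr)
  expect_lt(min(above$a), thr)
})

test_that("Alu crosses the threshold at much smaller folds than L1", {
  expect_lt(eb_threshold_fold("Alu"), eb_threshold_fold("L1") / 3)
})

test_that("a threshold just under the unperturbed minimum is crossed at a fold adjacent to 1", {
  ss <- eb_ref_ss()
  # the unperturbed trajectory sits at the steady state, so any fold > 1
  # dips below a threshold placed just under the stationary ATP
  tf <- threshold_fold(p, "L1", threshold_fraction = 0.999, ref = ss)
  expect_lt(tf, 1.5)
})

test_that("removing Alu depletes stationary ATP and de-represses L1", {
  ex <- eb_cached("reduced_experiment",
                  reduced_model_experiment(p, ref = eb_ref_ss()))
  expect_equal(ex$energy_ratio, 2.3, tolerance = 0.10)
  expect_gt(ex$L_ratio, 1)
  expect_true(ex$steady_state$converged)
  expect_true(ex$steady_state$stable)
})

test_that("the reduced-model ORF1p transient far outlasts the full-model one", {
  ex <- eb_cached("reduced_experiment",
                  reduced_model_experiment(p, ref = eb_ref_ss()))
  traj <- ex$trajectory
  o1_final <- ex$steady_state$state[["O1"]]
  settled <- traj$time[abs(traj$O1 - o1_final) <= 0.05 * o1_final]
  # time to come (and stay) within 5% of the final ORF1p level
  t_settle_reduced <- min(settled[vapply(settled, function(t0) {
    all(abs(traj$O1[traj$time >= t0] - o1_final) <= 0.05 * o1_final)
  }, logical(1))])
  # full model relaxing from a doubled ORF1p level
  ss <- eb_ref_ss()
  init <- cell_state(base = unclass(ss$state))
  init[["O1"]] <- 2 * init[["O1"]]
  full <- simulate_trajectory(p, cell_state(base = unclass(init)),
                              t_end = 1e6)
  o1_ref <- ss$state[["O1"]]
  settled_f <- full$time[abs(full$O1 - o1_ref) <= 0.05 * o1_ref]
  t_settle_full <- min(settled_f[vapply(settled_f, function(t0) {
    all(abs(full$O1[full$time >= t0] - o1_ref) <= 0.05 * o1_ref)
  }, logical(1))])
  expect_gt(t_settle_reduced, t_settle_full)
  # and it exceeds a typical cell lifetime (one cell cycle)
  expect_gt(t_settle_reduced, p[["tau"]])
})

test_that("silencing L1 transcription in the reduced model restores the RTE-free energy balance", {
  p_silent <- model_parameters(w_L = 1e-12)
  ss <- find_steady_state(p_silent, eb_ref_ss()$state, reduced = TRUE)
  expect_true(ss$converged)
  expect_lt(ss$state[["L"]], 1e-6)
  expect_gt(ss$state[["a"]], eb_ref_ss()$state[["a"]])
})

test_that("sweep CSV export has the documented columns", {
  sw <- copy_number_sweep(p, "Alu", folds = c(1, 10), ref = eb_ref_ss())
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  expect_identical(readLines(path, n = 1), "fold,T_drop_min,a_min,crossed")
})
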