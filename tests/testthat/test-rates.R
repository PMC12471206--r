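# Elementary rate laws, checked against direct arithmetic and against the
# stationarity of the published reference solution (production = first-order
# loss at the steady state pins each rate law's scaling).

p <- model_parameters()
ref <- reference_state()

test_that("transcription rate follows per-copy Michaelis-Menten kinetics", {
  expect_equal(transcription_rate(3804, 4.64, 3.8e9, 5.32e9),
               3804 * 4.64 * 5.32e9 / (3.8e9 + 5.32e9))
  expect_equal(transcription_rate(3804, 4.64, 3.8e9, 5.32e9), 1.03e4,
               tolerance = 1e-2)
  expect_identical(transcription_rate(1e4, 2, 1e9, 0), 0)
  # saturation: approaches copies * w as ATP -> infinity
  expect_equal(transcription_rate(1064, 1, 3.8e9, 1e18), 1064,
               tolerance = 1e-8)
  expect_error(transcription_rate(-1, 1, 1, 1), "nonnegative")
})

test_that("transcription rate is monotone in ATP and bounded by copies * w", {
  a_grid <- 10^seq(0, 12, length.out = 40)
  r <- transcription_rate(1064, 1, 3.8e9, a_grid)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1064 * 1))
})

test_that("free ribosome pool subtracts complexes and clamps at zero", {
  expect_identical(free_ribosomes(0, 0, 9.5e6), 9.5e6)
  expect_equal(free_ribosomes(2.61e6, 1.8e5, 9.5e6), 9.5e6 - 2.61e6 - 1.8e5)
  expect_identical(free_ribosomes(9e6, 1e6, 9.5e6), 0)
  expect_error(free_ribosomes(-1, 0, 9.5e6), "nonnegative")
})

test_that("translation rate balances protein turnover at the reference", {
  # at stationarity production d_q * q* fixes v_q
  v_q <- translation_rate(2.61e6, 5.32e9, 300, 431, 25900)
  expect_equal(v_q, 5.67e-4 * 3.20e9, tolerance = 0.01)
  expect_identical(translation_rate(0, 5.32e9, 300, 431, 25900), 0)
  # saturation: gamma_max / (NL/3) = 0.15/min per complex
  expect_equal(translation_rate(1e5, 1e18, 300, 2000, 25900), 0.15 * 1e5,
               tolerance = 1e-9)
  expect_error(translation_rate(1, 1, 300, 0, 1), "positive")
})

test_that("insertion rates balance retrotransposon deactivation at the reference", {
  expect_equal(insertion_rate_L1(2.83e3, 2.78e7, 5.32e9, p),
               0.37 * 1.07e3, tolerance = 0.01)
  expect_identical(insertion_rate_L1(0, 2.78e7, 5.32e9, p), 0)
  expect_identical(insertion_rate_L1(2.83e3, 0, 5.32e9, p), 0)
  expect_equal(insertion_rate_Alu(5.64e3, 5.32e9, p),
               1.18 * 1.34e4, tolerance = 0.01)
  expect_identical(insertion_rate_Alu(0, 5.32e9, p), 0)
  # linear in the complex count
  expect_equal(insertion_rate_Alu(2 * 5.64e3, 5.32e9, p),
               2 * insertion_rate_Alu(5.64e3, 5.32e9, p))
})

test_that("replication energy covers the basal genome plus new insertions", {
  expect_equal(replication_energy_rate(5.32e9, 0, 0, 0, p),
               15 * 3.08e9 / 1320)
  oracle <- 15 * (3.08e9 / 1320 +
                    6000 * insertion_rate_L1(2.83e3, 2.78e7, 5.32e9, p) +
                    300 * insertion_rate_Alu(5.64e3, 5.32e9, p))
  expect_equal(replication_energy_rate(5.32e9, 2.83e3, 2.78e7, 5.64e3, p),
               oracle)
  expect_equal(oracle, 1.42e8, tolerance = 0.02)
  p_slow <- model_parameters(tau = 1e15)
  expect_lt(replication_energy_rate(5.32e9, 0, 0, 0, p_slow), 1e-3)
})

test_that("flux vector evaluates every elementary rate once", {
  fl <- reaction_fluxes(ref, p)
  expect_equal(fl[["sub_fwd"]], 5e-8 * 1.22e8 * 2.83e3)
  expect_equal(fl[["sub_fwd"]], 1.73e4, tolerance = 0.01)
  expect_equal(fl[["unbind_q"]], 0.01 * 2.61e6)
  expect_true(all(fl >= 0))
  zero <- cell_state()
  flz <- reaction_fluxes(zero, p)
  expect_true(all(flz[setdiff(names(flz), "v_repl")] == 0))
  expect_equal(flz[["v_repl"]], p[["Nnt"]] * p[["Ng"]] / p[["tau"]])
})

test_that("fluxes are nonnegative at random admissible states", {
  for (st in eb_random_states(8)) {
    expect_true(all(reaction_fluxes(st, p) >= 0))
    expect_true(all(reaction_fluxes(st, p, reduced = TRUE) >= 0))
  }
})

test_that("reduced flux vector zeroes the Alu pathway", {
  fl <- reaction_fluxes(ref, p, reduced = TRUE)
  expect_identical(as.numeric(fl[c("omega_S", "sub_fwd", "sub_rev",
                                   "v_intS")]),
                   rep(0, 4))
  expect_gt(fl[["omega_L"]], 0)
})
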