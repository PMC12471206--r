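# Response coefficients and nonlinear steady-state scans.

p <- model_parameters()

# parameters tied to the retrotransposon life cycle (L1- or Alu-specific)
rte_params <- c("chi_maxL", "chi_maxS", "K_chiL", "K_chiS", "K_L",
                "w_L", "w_S", "theta_L", "theta_S", "gamma_maxL",
                "K_gammaL", "k_bL", "k_uL", "k_subS", "k_subL",
                "d_mL", "d_mS", "d_cL", "d_O1", "d_bL", "d_bS",
                "lambda_L", "lambda_S", "NL", "NS")

test_that("ATP influx and turnover dominate the elasticity ranking", {
  rc <- eb_response()
  expect_true(all(rc$converged))
  ranked <- rc$parameter[order(-abs(rc$elasticity))]
  expect_setequal(ranked[1:2], c("A0", "lambda_a"))
})

test_that("L1 transcription and deactivation dominate among RTE parameters", {
  rc <- eb_response()
  rte <- rc[rc$parameter %in% rte_params, ]
  ranked <- rte$parameter[order(-abs(rte$elasticity))]
  expect_setequal(ranked[1:2], c("w_L", "lambda_L"))
})

test_that("response signs split as expected", {
  rc <- eb_response()
  el <- stats::setNames(rc$elasticity, rc$parameter)
  expect_gt(el[["A0"]], 0)
  expect_lt(el[["lambda_a"]], 0)
  expect_lt(el[["w_L"]], 0)
  expect_gt(el[["lambda_L"]], 0)
})

test_that("parameters absent from the dynamics have zero response", {
  rc <- eb_response()
  el <- stats::setNames(rc$elasticity, rc$parameter)
  expect_identical(as.numeric(el[c("V_cell", "a_wt", "L_wt", "S_wt")]),
                   rep(0, 4))
})

test_that("elasticity of ATP influx agrees with a local scan slope", {
  rc <- eb_response()
  el_A0 <- rc$elasticity[rc$parameter == "A0"]
  folds <- 1 + seq(-2, 2) * 1e-3
  sc <- scan_parameter(p, "A0", folds)
  slope <- stats::coef(stats::lm(log(sc$a_star) ~ log(sc$fold)))[[2]]
  expect_equal(el_A0, slope, tolerance = 0.01)
})

test_that("a unit fold reproduces the reference ATP", {
  sc <- scan_parameter(p, "w_L", c(0.9, 1, 1.1))
  expect_true(all(sc$converged))
  expect_equal(sc$a_percent[sc$fold == 1], 100, tolerance = 1e-4)
})

test_that("stationary ATP decreases monotonically with L1 transcription", {
  sc <- scan_parameter(p, "w_L", 10^seq(0, 0.7, length.out = 8))
  expect_true(all(diff(sc$a_star) < 0))
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})

test_that("the 2D scan reproduces the reference at the unit corner and the 1D scan on its edge", {
  sc2 <- scan_parameter_pair(p, "lambda_L", "w_L",
                             folds1 = c(1, 1.5), folds2 = c(1, 1.5, 2))
  expect_true(all(sc2$converged))
  corner <- sc2$a_percent[sc2$fold1 == 1 & sc2$fold2 == 1]
  expect_equal(corner, 100, tolerance = 1e-4)
  # along the w_L edge ATP is monotone non-increasing
  edge <- sc2[sc2$fold1 == 1, ]
  expect_true(all(diff(edge$a_star[order(edge$fold2)]) < 0))
  sc1 <- scan_parameter(p, "w_L", c(1.5, 2))
  expect_equal(edge$a_star[edge$fold2 == 2], sc1$a_star[sc1$fold == 2],
               tolerance = 1e-6)
  expect_s3_class(ggplot2::autoplot(sc2), "ggplot")
})

test_that("fold searches are consistent with the scans they invert", {
  trivial <- fold_to_reach_fraction(p, "w_L", 1)
  expect_equal(trivial$fold, 1)
  half <- fold_to_reach_fraction(p, "w_L", 0.5)
  sc <- scan_parameter(p, "w_L", half$fold)
  expect_equal(sc$a_percent, 50, tolerance = 0.5)
  # lambda_L responds positively, so the search must divide it
  down <- fold_to_reach_fraction(p, "lambda_L", 0.5)
  expect_identical(down$directions[[1]], -1L)
  expect_lt(down$values[["lambda_L"]], p[["lambda_L"]])
  expect_equal(down$a_fraction, 0.5, tolerance = 2e-3)
})
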