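# The 12-equation right-hand side, its analytic Jacobian and the ATP
# bookkeeping identity that ties the balance equation to the budget module.

p <- model_parameters()
ref <- reference_state()

test_that("the published reference state is stationary relative to gross fluxes", {
  f <- model_rhs(ref, p)
  g <- rtebalance:::.eb_gross_num(unclass(ref), p)
  # 3-significant-figure inputs leave percent-level residuals at most
  expect_true(all(abs(f) / g <= 0.30))
  expect_lt(abs(f[["a"]]) / g[["a"]], 0.05)
  expect_lt(abs(f[["q"]]) / g[["q"]], 0.05)
  expect_lt(abs(f[["L"]]) / g[["L"]], 0.05)
  expect_lt(abs(f[["S"]]) / g[["S"]], 0.05)
})

test_that("with no genes and no RTEs the ATP equation reduces to influx, turnover and basal replication", {
  p0 <- model_parameters(Q = 1e-300)
  st <- cell_state(a = 2e9)
  f <- model_rhs(st, p0)
  expect_equal(f[["a"]],
               p0[["A0"]] - p0[["lambda_a"]] * 2e9 -
                 p0[["Nnt"]] * p0[["Ng"]] / p0[["tau"]])
  expect_identical(as.numeric(f[c("mL", "mS", "cL", "O1", "bL", "bS",
                                  "L", "S")]),
                   rep(0, 8))
})

test_that("reduced model freezes the Alu variables exactly", {
  st <- cell_state(base = unclass(ref))
  st[c("mS", "bS", "S")] <- 0
  f <- model_rhs(cell_state(base = unclass(st)), p, reduced = TRUE)
  expect_identical(as.numeric(f[c("mS", "bS", "S")]), rep(0, 3))
})

test_that("rhs rejects non-finite input", {
  bad <- unclass(ref)
  bad[["a"]] <- NaN
  expect_error(model_rhs(bad, p), "finite")
})

test_that("rhs is linear in most species away from the clamps", {
  # not O1: the ORF1p occupancy factor of the L1 insertion rate saturates
  for (v in c("mq", "mL", "q", "cq", "bS", "L", "S")) {
    x1 <- unclass(ref)
    x2 <- x1
    x2[[v]] <- 2 * x1[[v]]
    xm <- x1
    xm[[v]] <- 1.5 * x1[[v]]
    f_mid <- model_rhs(cell_state(base = xm), p)
    f_lin <- (model_rhs(cell_state(base = x1), p) +
                model_rhs(cell_state(base = x2), p)) / 2
    expect_equal(f_mid, f_lin, tolerance = 1e-12)
  }
})

test_that("ATP bookkeeping: influx minus da/dt equals the energy budget, to 1e-12", {
  states <- c(list(ref), eb_random_states(10))
  for (st in states) {
    b <- energy_budget(st, p)
    dadt <- model_rhs(st, p)[["a"]]
    expect_equal(sum(b$rate) + dadt, p[["A0"]],
                 tolerance = 1e-12)
    expect_true(all(b$rate >= 0))
  }
})

test_that("consumption-free analytic limit: a* = A0 / lambda_a", {
  # no genes, no RTEs, negligible basal replication
  p0 <- model_parameters(Q = 1e-300, tau = 1e12)
  a_star <- p0[["A0"]] / p0[["lambda_a"]]
  expect_equal(a_star, 8.91e9, tolerance = 1e-2)
  ss <- find_steady_state(p0, cell_state(a = 1e8))
  expect_true(ss$converged)
  expect_equal(ss$state[["a"]], a_star, tolerance = 1e-6)
  expect_true(all(unclass(ss$state)[-1] < 1e-6))
})

test_that("analytic Jacobian matches central finite differences at the reference", {
  ss <- eb_ref_ss()
  J <- model_jacobian(ss$state, p)
  fd <- eb_fd_jacobian(ss$state, p)
  den <- pmax(abs(J), abs(fd))
  den[den == 0] <- 1
  expect_lt(max(abs(J - fd) / den), 1e-5)
})

test_that("analytic Jacobian matches finite differences at random states and in the reduced model", {
  for (st in eb_random_states(4, seed = 7)) {
    for (red in c(FALSE, TRUE)) {
      stx <- st
      if (red) stx[c("mS", "bS", "S")] <- 0
      stx <- cell_state(base = unclass(stx))
      J <- model_jacobian(stx, p, reduced = red)
      fd <- eb_fd_jacobian(stx, p, reduced = red)
      # scale columns by the state magnitudes and compare rows relative to
      # their dominant entry (tiny cross-terms drown in FD roundoff)
      sc <- pmax(abs(unclass(stx)), 1)
      Js <- sweep(J, 2L, sc, `*`)
      fds <- sweep(fd, 2L, sc, `*`)
      rowden <- pmax(apply(abs(Js), 1, max), 1e-300)
      expect_lt(max(abs(Js - fds) / rowden), 1e-4)
    }
  }
})

test_that("retrotransposon deactivation shows up as constant diagonal Jacobian entries", {
  for (st in eb_random_states(3, seed = 11)) {
    J <- model_jacobian(st, p)
    expect_equal(J["L", "L"], -p[["lambda_L"]])
    expect_equal(J["S", "S"], -p[["lambda_S"]])
  }
})
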