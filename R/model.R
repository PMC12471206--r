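# Right-hand side, analytic Jacobian and per-equation gross fluxes of the
# 12-variable energy-balance model. The internal .eb_* workers operate on
# plain named numeric vectors with no validation (they sit inside integrator
# and Newton loops); the exported wrappers validate.

# elementary rates at a (clamped-nonnegative) state; returns an environment
# of scalars shared by rhs / jacobian / budget code paths
.eb_rates <- function(x, p, reduced = FALSE) {
  x <- pmax(x, 0)
  a <- x[[1L]]; mq <- x[[2L]]; cq <- x[[3L]]; q <- x[[4L]]
  mL <- x[[5L]]; mS <- x[[6L]]; cL <- x[[7L]]; O1 <- x[[8L]]
  bL <- x[[9L]]; bS <- x[[10L]]; L <- x[[11L]]; S <- x[[12L]]

  mm_q <- a / (p[["theta_q"]] + a)
  mm_L <- a / (p[["theta_L"]] + a)
  mm_S <- a / (p[["theta_S"]] + a)
  mm_gq <- a / (p[["K_gammaq"]] + a)
  mm_gL <- a / (p[["K_gammaL"]] + a)
  mm_xL <- a / (p[["K_chiL"]] + a)
  mm_xS <- a / (p[["K_chiS"]] + a)
  occ <- p[["K_L"]] * O1 / (1 + p[["K_L"]] * O1)

  gq <- p[["gamma_maxq"]] / p[["Nq"]]
  gL <- p[["gamma_maxL"]] / (p[["NL"]] / 3)
  hL <- p[["chi_maxL"]] / p[["NL"]]
  hS <- p[["chi_maxS"]] / p[["NS"]]

  frib <- max(p[["r_tot"]] - cq - cL, 0)

  omega_q <- p[["Q"]] * p[["w_q"]] * mm_q
  omega_L <- L * p[["w_L"]] * mm_L
  omega_S <- S * p[["w_S"]] * mm_S
  v_q <- gq * cq * mm_gq
  v_L <- gL * cL * mm_gL
  v_intL <- hL * bL * mm_xL * occ
  v_intS <- hS * bS * mm_xS
  bind_q <- p[["k_bq"]] * frib * mq
  bind_L <- p[["k_bL"]] * frib * mL
  sub_fwd <- p[["k_subS"]] * mS * bL
  sub_rev <- p[["k_subL"]] * mL * bS
  if (reduced) {
    omega_S <- 0; sub_fwd <- 0; sub_rev <- 0; v_intS <- 0
  }
  v_repl <- p[["Nnt"]] * (p[["Ng"]] / p[["tau"]] +
                            p[["NL"]] * v_intL + p[["NS"]] * v_intS)
  environment()
}

.eb_rhs_num <- function(x, p, reduced = FALSE) {
  e <- .eb_rates(x, p, reduced)
  with(e, {
    da <- p[["A0"]] - p[["lambda_a"]] * a - v_repl -
      p[["Nnt"]] * (p[["NQ"]] * omega_q + p[["NL"]] * omega_L +
                      p[["NS"]] * omega_S) -
      p[["Naa"]] * (p[["Nq"]] * v_q + p[["NL"]] / 3 * v_L) -
      p[["Nnt"]] * (p[["NL"]] * v_intL + p[["NS"]] * v_intS)
    dmq <- omega_q - bind_q + p[["k_uq"]] * cq + v_q - p[["d_mq"]] * mq
    dcq <- bind_q - p[["k_uq"]] * cq - v_q - p[["d_cq"]] * cq
    dq <- v_q - p[["d_q"]] * q
    dmL <- omega_L - bind_L + p[["k_uL"]] * cL + sub_fwd - sub_rev -
      p[["d_mL"]] * mL
    dmS <- omega_S - sub_fwd + sub_rev - p[["d_mS"]] * mS
    dcL <- bind_L - p[["k_uL"]] * cL - v_L - p[["d_cL"]] * cL
    dO1 <- v_L - v_intL - p[["d_O1"]] * O1
    dbL <- v_L - v_intL - sub_fwd + sub_rev - p[["d_bL"]] * bL
    dbS <- sub_fwd - sub_rev - v_intS - p[["d_bS"]] * bS
    dL <- v_intL - p[["lambda_L"]] * L
    dS <- v_intS - p[["lambda_S"]] * S
    if (reduced) {
      dmS <- 0; dbS <- 0; dS <- 0
    }
    c(a = da, mq = dmq, cq = dcq, q = dq, mL = dmL, mS = dmS, cL = dcL,
      O1 = dO1, bL = dbL, bS = dbS, L = dL, S = dS)
  })
}

# per-equation gross flux: sum of magnitudes of all production and
# consumption terms, used to normalize stationarity residuals
.eb_gross_num <- function(x, p, reduced = FALSE) {
  e <- .eb_rates(x, p, reduced)
  with(e, {
    c(a = p[["A0"]] + p[["lambda_a"]] * a + v_repl +
        p[["Nnt"]] * (p[["NQ"]] * omega_q + p[["NL"]] * omega_L +
                        p[["NS"]] * omega_S) +
        p[["Naa"]] * (p[["Nq"]] * v_q + p[["NL"]] / 3 * v_L) +
        p[["Nnt"]] * (p[["NL"]] * v_intL + p[["NS"]] * v_intS),
      mq = omega_q + bind_q + p[["k_uq"]] * cq + v_q + p[["d_mq"]] * mq,
      cq = bind_q + p[["k_uq"]] * cq + v_q + p[["d_cq"]] * cq,
      q = v_q + p[["d_q"]] * q,
      mL = omega_L + bind_L + p[["k_uL"]] * cL + sub_fwd + sub_rev +
        p[["d_mL"]] * mL,
      mS = omega_S + sub_fwd + sub_rev + p[["d_mS"]] * mS,
      cL = bind_L + p[["k_uL"]] * cL + v_L + p[["d_cL"]] * cL,
      O1 = v_L + v_intL + p[["d_O1"]] * O1,
      bL = v_L + v_intL + sub_fwd + sub_rev + p[["d_bL"]] * bL,
      bS = sub_fwd + sub_rev + v_intS + p[["d_bS"]] * bS,
      L = v_intL + p[["lambda_L"]] * L,
      S = v_intS + p[["lambda_S"]] * S)
  })
}

# analytic 12x12 Jacobian d(rhs)/d(state); valid at admissible states away
# from the ribosome clamp (frib > 0) and the nonnegativity clamp
.eb_jac_num <- function(x, p, reduced = FALSE) {
  e <- .eb_rates(x, p, reduced)
  with(e, {
    J <- matrix(0, 12, 12, dimnames = list(.state_names, .state_names))
    # ATP-derivatives of the Michaelis-Menten factors
    dmm_q <- p[["theta_q"]] / (p[["theta_q"]] + a)^2
    dmm_L <- p[["theta_L"]] / (p[["theta_L"]] + a)^2
    dmm_S <- p[["theta_S"]] / (p[["theta_S"]] + a)^2
    dmm_gq <- p[["K_gammaq"]] / (p[["K_gammaq"]] + a)^2
    dmm_gL <- p[["K_gammaL"]] / (p[["K_gammaL"]] + a)^2
    dmm_xL <- p[["K_chiL"]] / (p[["K_chiL"]] + a)^2
    dmm_xS <- p[["K_chiS"]] / (p[["K_chiS"]] + a)^2
    docc <- p[["K_L"]] / (1 + p[["K_L"]] * O1)^2

    # rate partials
    dwq_a <- p[["Q"]] * p[["w_q"]] * dmm_q
    dwL_a <- L * p[["w_L"]] * dmm_L
    dwL_L <- p[["w_L"]] * mm_L
    dwS_a <- S * p[["w_S"]] * dmm_S
    dwS_S <- p[["w_S"]] * mm_S
    dvq_a <- gq * cq * dmm_gq
    dvq_cq <- gq * mm_gq
    dvL_a <- gL * cL * dmm_gL
    dvL_cL <- gL * mm_gL
    diL_a <- hL * bL * dmm_xL * occ
    diL_bL <- hL * mm_xL * occ
    diL_O1 <- hL * bL * mm_xL * docc
    diS_a <- hS * bS * dmm_xS
    diS_bS <- hS * mm_xS
    ind <- as.numeric(frib > 0)   # ribosome clamp indicator
    dbq_mq <- p[["k_bq"]] * frib
    dbq_c <- -p[["k_bq"]] * mq * ind       # wrt cq and cL
    dbb_mL <- p[["k_bL"]] * frib
    dbb_c <- -p[["k_bL"]] * mL * ind
    dsf_mS <- p[["k_subS"]] * bL
    dsf_bL <- p[["k_subS"]] * mS
    dsr_mL <- p[["k_subL"]] * bS
    dsr_bS <- p[["k_subL"]] * mL
    if (reduced) {
      dwS_a <- 0; dwS_S <- 0; diS_a <- 0; diS_bS <- 0
      dsf_mS <- 0; dsf_bL <- 0; dsr_mL <- 0; dsr_bS <- 0
    }

    Nnt <- p[["Nnt"]]; Naa <- p[["Naa"]]
    NQg <- p[["NQ"]]; NLg <- p[["NL"]]; NSg <- p[["NS"]]

    # row a: A0 - lambda_a a - v_repl - transcription - translation -
    # insertion costs (insertion length cost charged in v_repl and again in
    # the final bracket, hence factor 2)
    J["a", "a"] <- -p[["lambda_a"]] - 2 * Nnt * (NLg * diL_a + NSg * diS_a) -
      Nnt * (NQg * dwq_a + NLg * dwL_a + NSg * dwS_a) -
      Naa * (p[["Nq"]] * dvq_a + NLg / 3 * dvL_a)
    J["a", "cq"] <- -Naa * p[["Nq"]] * dvq_cq
    J["a", "cL"] <- -Naa * NLg / 3 * dvL_cL
    J["a", "O1"] <- -2 * Nnt * NLg * diL_O1
    J["a", "bL"] <- -2 * Nnt * NLg * diL_bL
    J["a", "bS"] <- -2 * Nnt * NSg * diS_bS
    J["a", "L"] <- -Nnt * NLg * dwL_L
    J["a", "S"] <- -Nnt * NSg * dwS_S

    J["mq", "a"] <- dwq_a + dvq_a
    J["mq", "mq"] <- -dbq_mq - p[["d_mq"]]
    J["mq", "cq"] <- -dbq_c + p[["k_uq"]] + dvq_cq
    J["mq", "cL"] <- -dbq_c

    J["cq", "a"] <- -dvq_a
    J["cq", "mq"] <- dbq_mq
    J["cq", "cq"] <- dbq_c - p[["k_uq"]] - dvq_cq - p[["d_cq"]]
    J["cq", "cL"] <- dbq_c

    J["q", "a"] <- dvq_a
    J["q", "cq"] <- dvq_cq
    J["q", "q"] <- -p[["d_q"]]

    J["mL", "a"] <- dwL_a
    J["mL", "mL"] <- -dbb_mL - dsr_mL - p[["d_mL"]]
    J["mL", "mS"] <- dsf_mS
    J["mL", "cq"] <- -dbb_c
    J["mL", "cL"] <- -dbb_c + p[["k_uL"]]
    J["mL", "bL"] <- dsf_bL
    J["mL", "bS"] <- -dsr_bS
    J["mL", "L"] <- dwL_L

    J["mS", "a"] <- dwS_a
    J["mS", "mL"] <- dsr_mL
    J["mS", "mS"] <- -dsf_mS - p[["d_mS"]]
    J["mS", "bL"] <- -dsf_bL
    J["mS", "bS"] <- dsr_bS
    J["mS", "S"] <- dwS_S

    J["cL", "a"] <- -dvL_a
    J["cL", "mL"] <- dbb_mL
    J["cL", "cq"] <- dbb_c
    J["cL", "cL"] <- dbb_c - p[["k_uL"]] - dvL_cL - p[["d_cL"]]

    J["O1", "a"] <- dvL_a - diL_a
    J["O1", "cL"] <- dvL_cL
    J["O1", "O1"] <- -diL_O1 - p[["d_O1"]]
    J["O1", "bL"] <- -diL_bL

    J["bL", "a"] <- dvL_a - diL_a
    J["bL", "mL"] <- dsr_mL
    J["bL", "mS"] <- -dsf_mS
    J["bL", "cL"] <- dvL_cL
    J["bL", "O1"] <- -diL_O1
    J["bL", "bL"] <- -diL_bL - dsf_bL - p[["d_bL"]]
    J["bL", "bS"] <- dsr_bS

    J["bS", "a"] <- -diS_a
    J["bS", "mL"] <- -dsr_mL
    J["bS", "mS"] <- dsf_mS
    J["bS", "bL"] <- dsf_bL
    J["bS", "bS"] <- -dsr_bS - diS_bS - p[["d_bS"]]

    J["L", "a"] <- diL_a
    J["L", "O1"] <- diL_O1
    J["L", "bL"] <- diL_bL
    J["L", "L"] <- -p[["lambda_L"]]

    J["S", "a"] <- diS_a
    J["S", "bS"] <- diS_bS
    J["S", "S"] <- -p[["lambda_S"]]

    if (reduced) J[c("mS", "bS", "S"), ] <- 0
    J
  })
}

#' Time derivatives of the model state
#'
#' Assemble the 12 concentration balance equations from the elementary
#' fluxes. ATP (`a`) gains the constant influx `A0` and loses first-order
#' degradation, DNA replication cost, transcription cost, translation cost
#' and the nucleotide cost of retrotransposon insertions. The state is
#' clamped at zero before rate evaluation, so trajectories are evaluated on
#' the admissible orthant.
#'
#' @param state an [cell_state()] vector (or named numeric with the 12
#'   variables).
#' @param p an [model_parameters()] set.
#' @param reduced logical; evaluate the Alu-free reduced model, in which the
#'   Alu transcription, substitution and insertion fluxes and the `mS`, `bS`,
#'   `S` derivatives are identically zero.
#' @return Named numeric vector of time derivatives (m.p.c./min).
#' @export
model_rhs <- function(state, p, reduced = FALSE) {
  x <- unclass(validate_state(state))
  .eb_rhs_num(x, p, reduced)
}

#' Analytic Jacobian of the model
#'
#' Partial derivatives of [model_rhs()] with respect to the 12 state
#' variables, derived in closed form (used by the stiff integrator, the
#' steady-state Newton polish and linear stability analysis). In the reduced
#' model the rows of the frozen variables are zero.
#'
#' @inheritParams model_rhs
#' @return A 12 x 12 numeric matrix with rows/columns in state order.
#' @export
model_jacobian <- function(state, p, reduced = FALSE) {
  x <- unclass(validate_state(state))
  .eb_jac_num(x, p, reduced)
}
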