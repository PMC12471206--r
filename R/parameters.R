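#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn `%||%`
NULL

# canonical state variable order used everywhere (trajectories, Jacobians, CSV)
.state_names <- c("a", "mq", "cq", "q", "mL", "mS", "cL", "O1", "bL", "bS",
                  "L", "S")

# parameters that never enter the right-hand side (metadata / calibration
# targets); their response coefficients are identically zero
.metadata_params <- c("V_cell", "a_wt", "L_wt", "S_wt")

.param_defaults <- c(
  Ng        = 3.08e9,   # genome size (bp)
  Q         = 3804,     # housekeeping gene count (m.p.c.)
  A0        = 1.31e10,  # ATP influx (m.p.c./min)
  tau       = 1320,     # cell-cycle duration (min)
  Nq        = 431,      # median housekeeping protein length (aa)
  NQ        = 1300,     # median housekeeping gene length (bp)
  NL        = 6000,     # LINE-1 length (bp)
  NS        = 300,      # Alu length (bp)
  Naa       = 5,        # ATP per amino acid added
  Nnt       = 15,       # ATP per nucleotide added
  chi_maxL  = 840,      # max single-nt incorporation rate, L1 insertion (1/min)
  chi_maxS  = 840,      # max single-nt incorporation rate, Alu insertion (1/min)
  K_chiL    = 1.1e7,    # Michaelis constant of ATP in L1 insertion (m.p.c.)
  K_chiS    = 1.1e7,    # Michaelis constant of ATP in Alu insertion (m.p.c.)
  K_L       = 2.24e-3,  # L1 mRNA-ORF1p association constant (1/m.p.c.)
  w_q       = 4.64,     # max transcription rate per housekeeping gene (1/min)
  w_L       = 1,        # max transcription rate per active L1 (1/min)
  w_S       = 20,       # max transcription rate per active Alu (1/min)
  theta_q   = 3.8e9,    # Michaelis constant of ATP in hk transcription (m.p.c.)
  theta_L   = 3.8e9,    # Michaelis constant of ATP in L1 transcription (m.p.c.)
  theta_S   = 3.8e9,    # Michaelis constant of ATP in Alu transcription (m.p.c.)
  gamma_maxq = 300,     # max translation rate, hk proteins (aa/min)
  gamma_maxL = 300,     # max translation rate, L1 proteins (aa/min)
  K_gammaq  = 25900,    # Michaelis constant of ATP in hk translation (m.p.c.)
  K_gammaL  = 25900,    # Michaelis constant of ATP in L1 translation (m.p.c.)
  k_bq      = 5e-8,     # hk mRNA-ribosome binding rate constant (1/(m.p.c. min))
  k_bL      = 5e-8,     # L1 mRNA-ribosome binding rate constant (1/(m.p.c. min))
  k_uq      = 0.01,     # hk mRNA-ribosome unbinding rate constant (1/min)
  k_uL      = 0.01,     # L1 mRNA-ribosome unbinding rate constant (1/min)
  k_subS    = 5e-8,     # mL->mS substitution rate constant (1/(m.p.c. min))
  k_subL    = 5e-6,     # mS->mL substitution rate constant (1/(m.p.c. min))
  r_tot     = 9.5e6,    # total ribosome pool (m.p.c.)
  lambda_a  = 1.47,     # ATP degradation rate constant (1/min)
  d_mq      = 1.15e-3,  # hk mRNA degradation (1/min)
  d_mL      = 1.15e-3,  # L1 mRNA degradation (1/min)
  d_mS      = 1.15e-3,  # Alu mRNA degradation (1/min)
  d_cq      = 1.55e-3,  # cq complex degradation (1/min)
  d_cL      = 1.55e-3,  # cL complex degradation (1/min)
  d_q       = 5.67e-4,  # hk protein degradation (1/min)
  d_O1      = 5.67e-4,  # ORF1p degradation (1/min)
  d_bL      = 5.67e-4,  # bL complex degradation (1/min)
  d_bS      = 5.67e-4,  # bS complex degradation (1/min)
  lambda_L  = 0.37,     # L1 deactivation (silencing) rate constant (1/min)
  lambda_S  = 1.18,     # Alu deactivation (silencing) rate constant (1/min)
  V_cell    = 3700,     # cell volume (um^3), metadata only
  a_wt      = 5.33e9,   # wild-type ATP count, calibration target (m.p.c.)
  L_wt      = 1064,     # wild-type active L1 count, calibration target (m.p.c.)
  S_wt      = 13243     # wild-type active Alu count, calibration target (m.p.c.)
)

# free (optimized) rate constants; everything else is literature-anchored
.free_params <- c("k_bq", "k_bL", "k_uq", "k_uL", "k_subS", "k_subL",
                  "lambda_a", "d_cq", "d_cL", "lambda_L", "lambda_S")

#' Model parameter set
#'
#' Construct the full parameter set of the energy-balance model. All values
#' are in molecules-per-cell (m.p.c.) and per-minute units; lengths are in
#' base pairs (bp) or amino acids (aa). Called with no arguments it returns
#' the published defaults; named arguments override individual constants.
#'
#' @param ... named overrides of individual parameters, e.g. `w_L = 3`.
#' @param base parameter set to start from (defaults to the published values).
#' @return A named numeric vector of class `"eb_parameters"`.
#' @examples
#' p <- model_parameters()
#' p3 <- model_parameters(w_L = 3 * p[["w_L"]])
#' @export
model_parameters <- function(..., base = NULL) {
  p <- base %||% .param_defaults
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(.param_defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown parameter name(s): ",
                   paste(bad, collapse = ", ")))
    }
    p[names(over)] <- over
  }
  validate_parameters(p)
}

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

validate_parameters <- function(p) {
  p <- unclass(p)
  missing <- setdiff(names(.param_defaults), names(p))
  if (length(missing)) {
    abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")))
  }
  p <- p[names(.param_defaults)]
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    abort("all parameters must be finite numbers")
  }
  nonpos <- names(p)[p <= 0]
  if (length(nonpos)) {
    abort(paste0("parameters must be strictly positive: ",
                 paste(nonpos, collapse = ", ")))
  }
  structure(p, class = "eb_parameters")
}

#' @export
print.eb_parameters <- function(x, ...) {
  cat("<eb_parameters> ", length(x), " model constants (m.p.c., 1/min)\n",
      sep = "")
  print(tibble(parameter = names(x), value = as.numeric(x)), n = 12)
  invisible(x)
}

#' @method as_tibble eb_parameters
#' @export
as_tibble.eb_parameters <- function(x, ...) {
  tibble(parameter = names(unclass(x)), value = as.numeric(x))
}

#' Cell state
#'
#' Construct a cell state: the 12 dynamical concentrations of the model, in
#' molecules per cell. `a` is free ATP; `mq`, `cq`, `q` are housekeeping
#' mRNA, mRNA-ribosome complexes and protein; `mL`, `mS` are L1 and Alu
#' mRNAs; `cL` is the L1 mRNA-ribosome complex; `O1` is ORF1p; `bL`, `bS`
#' are the mRNA-ORF2p (reverse transcriptase) complexes; `L`, `S` are the
#' counts of actively transcribed L1 and Alu copies in the genome.
#'
#' @param ... named nonnegative concentrations; unnamed fields default to 0.
#' @param base state to start from (defaults to all zeros).
#' @return A named numeric vector of class `"eb_state"`.
#' @examples
#' cell_state(a = 1e9, L = 1000)
#' @export
cell_state <- function(..., base = NULL) {
  x <- base %||% stats::setNames(numeric(length(.state_names)), .state_names)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), .state_names)
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown state variable(s): ", paste(bad, collapse = ", ")))
    }
    x[names(over)] <- over
  }
  validate_state(x)
}

validate_state <- function(x) {
  x <- unclass(x)
  missing <- setdiff(.state_names, names(x))
  if (length(missing)) {
    abort(paste0("missing state variable(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[.state_names]
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("all state variables must be finite numbers")
  }
  if (any(x < 0)) {
    abort(paste0("state variables must be nonnegative: ",
                 paste(names(x)[x < 0], collapse = ", ")))
  }
  structure(x, class = "eb_state")
}

#' Reference steady state
#'
#' The homeostatic stationary solution of the model with default parameters:
#' low retrotransposon activity, ATP near its wild-type count. Values are the
#' published 3-significant-figure stationary solution; use
#' [find_steady_state()] to polish them to solver precision.
#'
#' @return An `"eb_state"` vector.
#' @export
reference_state <- function() {
  cell_state(a = 5.32e9, mq = 5.44e6, cq = 2.61e6, q = 3.20e9, mL = 5.13e4,
             mS = 1.22e8, cL = 1.8e5, O1 = 2.78e7, bL = 2.83e3, bS = 5.64e3,
             L = 1.07e3, S = 1.34e4)
}

#' @export
print.eb_state <- function(x, ...) {
  cat("<eb_state> concentrations (m.p.c.)\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' @method as_tibble eb_state
#' @export
as_tibble.eb_state <- function(x, ...) {
  tibble(variable = names(unclass(x)), value = as.numeric(x))
}

# per-variable absolute tolerance scale used by the integrator and solvers
.state_scale <- function() pmax(unclass(reference_state()), 1)
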