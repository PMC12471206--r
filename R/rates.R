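#' Michaelis-Menten transcription rate
#'
#' Transcription proceeds from each active gene copy at a maximum per-copy
#' rate `w`, damped by the Michaelis-Menten dependence on free ATP:
#' `copies * w * a / (theta + a)`.
#'
#' @param copies number of actively transcribed gene copies (m.p.c.).
#' @param w maximum transcription rate per copy (1/min).
#' @param theta Michaelis constant of the ATP dependence (m.p.c.).
#' @param a free ATP (m.p.c.).
#' @return Transcript production rate (m.p.c./min).
#' @export
transcription_rate <- function(copies, w, theta, a) {
  if (any(c(copies, w, theta, a) < 0)) {
    rlang::abort("transcription_rate: all arguments must be nonnegative")
  }
  copies * w * a / (theta + a)
}

#' Free ribosome pool
#'
#' Ribosomes not sequestered in housekeeping (`cq`) or L1 (`cL`)
#' mRNA-ribosome complexes, clamped at zero so binding fluxes stay
#' nonnegative during extreme transients.
#'
#' @param cq,cL complexed ribosome counts (m.p.c.).
#' @param r_tot total ribosome pool (m.p.c.).
#' @return Free ribosome count (m.p.c.).
#' @export
free_ribosomes <- function(cq, cL, r_tot) {
  if (any(c(cq, cL) < 0)) {
    rlang::abort("free_ribosomes: cq and cL must be nonnegative")
  }
  pmax(r_tot - cq - cL, 0)
}

#' Translation rate
#'
#' Protein production from mRNA-ribosome complexes. The maximum elongation
#' rate `gamma_max` (aa/min) is scaled by the protein length to a per-complex
#' protein production rate, with Michaelis-Menten ATP dependence:
#' `(gamma_max / protein_len) * c * a / (K_gamma + a)`. Housekeeping proteins
#' use the median protein length; the combined L1 protein output uses one
#' third of the L1 nucleotide length.
#'
#' @param c_complex mRNA-ribosome complex count (m.p.c.).
#' @param a free ATP (m.p.c.).
#' @param gamma_max maximum elongation rate (aa/min).
#' @param protein_len protein length (aa), strictly positive.
#' @param K_gamma Michaelis constant of the ATP dependence (m.p.c.).
#' @return Protein production rate (m.p.c./min).
#' @export
translation_rate <- function(c_complex, a, gamma_max, protein_len, K_gamma) {
  if (any(protein_len <= 0)) {
    rlang::abort("translation_rate: protein_len must be positive")
  }
  gamma_max / protein_len * c_complex * a / (K_gamma + a)
}

#' L1 insertion rate
#'
#' Genomic integration of new L1 copies by the mRNA-ORF2p complex `bL`,
#' requiring ORF1p under a limited-binding-occupancy factor:
#' `(chi_maxL/NL) * bL * a/(K_chiL + a) * K_L*O1/(1 + K_L*O1)`.
#'
#' @param bL L1 mRNA-ORF2p complex count (m.p.c.).
#' @param O1 ORF1p count (m.p.c.).
#' @param a free ATP (m.p.c.).
#' @param p an [model_parameters()] set.
#' @return Insertion rate (m.p.c./min).
#' @export
insertion_rate_L1 <- function(bL, O1, a, p) {
  occ <- p[["K_L"]] * O1 / (1 + p[["K_L"]] * O1)
  p[["chi_maxL"]] / p[["NL"]] * bL * a / (p[["K_chiL"]] + a) * occ
}

#' Alu insertion rate
#'
#' Genomic integration of new Alu copies by the hijacked reverse
#' transcriptase complex `bS`: `(chi_maxS/NS) * bS * a/(K_chiS + a)`.
#'
#' @param bS Alu mRNA-ORF2p complex count (m.p.c.).
#' @inheritParams insertion_rate_L1
#' @return Insertion rate (m.p.c./min).
#' @export
insertion_rate_Alu <- function(bS, a, p) {
  p[["chi_maxS"]] / p[["NS"]] * bS * a / (p[["K_chiS"]] + a)
}

#' DNA replication energy rate
#'
#' ATP expenditure for DNA synthesis: the basal genome copy per cell cycle
#' plus the extension of the genome by newly inserted retrotransposon copies,
#' at `Nnt` ATP per nucleotide:
#' `Nnt * (Ng/tau + NL*v_intL + NS*v_intS)`.
#'
#' @param a free ATP (m.p.c.).
#' @param bL,O1,bS complex and protein counts entering the insertion rates.
#' @param p an [model_parameters()] set.
#' @return Energy expenditure rate (ATP m.p.c./min).
#' @export
replication_energy_rate <- function(a, bL, O1, bS, p) {
  p[["Nnt"]] * (p[["Ng"]] / p[["tau"]] +
                  p[["NL"]] * insertion_rate_L1(bL, O1, a, p) +
                  p[["NS"]] * insertion_rate_Alu(bS, a, p))
}

#' Elementary reaction fluxes
#'
#' Evaluate every elementary process rate of the model at a state. In the
#' reduced (Alu-free) variant the Alu transcription, substitution and
#' insertion fluxes are forced to zero.
#'
#' @param state an [cell_state()] vector.
#' @param p an [model_parameters()] set.
#' @param reduced logical; evaluate the Alu-free reduced model.
#' @return A named numeric vector of class `"eb_fluxes"`: transcription
#'   (`omega_q`, `omega_L`, `omega_S`), translation (`v_q`, `v_L`), insertion
#'   (`v_intL`, `v_intS`), replication energy (`v_repl`), ribosome
#'   binding/unbinding (`bind_q`, `bind_L`, `unbind_q`, `unbind_L`),
#'   substitution (`sub_fwd`, `sub_rev`) and one first-order degradation flux
#'   per state variable (`deg_*`). Units m.p.c./min (ATP m.p.c./min for
#'   `v_repl`).
#' @export
reaction_fluxes <- function(state, p, reduced = FALSE) {
  x <- pmax(unclass(validate_state(state)), 0)
  a <- x[["a"]]
  frib <- free_ribosomes(x[["cq"]], x[["cL"]], p[["r_tot"]])
  fl <- c(
    omega_q = transcription_rate(p[["Q"]], p[["w_q"]], p[["theta_q"]], a),
    omega_L = transcription_rate(x[["L"]], p[["w_L"]], p[["theta_L"]], a),
    omega_S = transcription_rate(x[["S"]], p[["w_S"]], p[["theta_S"]], a),
    v_q = translation_rate(x[["cq"]], a, p[["gamma_maxq"]], p[["Nq"]],
                           p[["K_gammaq"]]),
    v_L = translation_rate(x[["cL"]], a, p[["gamma_maxL"]], p[["NL"]] / 3,
                           p[["K_gammaL"]]),
    v_intL = insertion_rate_L1(x[["bL"]], x[["O1"]], a, p),
    v_intS = insertion_rate_Alu(x[["bS"]], a, p),
    bind_q = p[["k_bq"]] * frib * x[["mq"]],
    bind_L = p[["k_bL"]] * frib * x[["mL"]],
    unbind_q = p[["k_uq"]] * x[["cq"]],
    unbind_L = p[["k_uL"]] * x[["cL"]],
    sub_fwd = p[["k_subS"]] * x[["mS"]] * x[["bL"]],
    sub_rev = p[["k_subL"]] * x[["mL"]] * x[["bS"]],
    deg_a = p[["lambda_a"]] * a,
    deg_mq = p[["d_mq"]] * x[["mq"]],
    deg_cq = p[["d_cq"]] * x[["cq"]],
    deg_q = p[["d_q"]] * x[["q"]],
    deg_mL = p[["d_mL"]] * x[["mL"]],
    deg_mS = p[["d_mS"]] * x[["mS"]],
    deg_cL = p[["d_cL"]] * x[["cL"]],
    deg_O1 = p[["d_O1"]] * x[["O1"]],
    deg_bL = p[["d_bL"]] * x[["bL"]],
    deg_bS = p[["d_bS"]] * x[["bS"]],
    deg_L = p[["lambda_L"]] * x[["L"]],
    deg_S = p[["lambda_S"]] * x[["S"]]
  )
  if (reduced) fl[c("omega_S", "sub_fwd", "sub_rev", "v_intS")] <- 0
  fl[["v_repl"]] <- p[["Nnt"]] * (p[["Ng"]] / p[["tau"]] +
                                    p[["NL"]] * fl[["v_intL"]] +
                                    p[["NS"]] * fl[["v_intS"]])
  structure(fl, class = "eb_fluxes")
}

#' @method as_tibble eb_fluxes
#' @export
as_tibble.eb_fluxes <- function(x, ...) {
  tibble::tibble(flux = names(unclass(x)), rate = as.numeric(x))
}
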