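.budget_categories <- c("atp_degradation", "replication_basal",
                        "replication_insertions", "transcription_hk",
                        "transcription_L1", "transcription_Alu",
                        "translation_hk", "translation_L1",
                        "insertion_L1", "insertion_Alu")

#' Instantaneous ATP budget
#'
#' Decomposes the instantaneous ATP consumption at a state into the terms of
#' the ATP balance equation: first-order ATP turnover, basal genome
#' replication, replication of newly inserted retrotransposon copies,
#' transcription of housekeeping genes / L1 / Alu, translation of
#' housekeeping and L1 proteins, and the reverse-transcription cost of L1
#' and Alu insertions. The balance equation charges the nucleotide cost of
#' new insertions both inside the replication term and as a separate
#' insertion term; the two are reported as separate categories, exactly as
#' the model spends them. The terms sum to `A0 - da/dt` identically, which
#' is the conservation oracle used by the test-suite.
#'
#' @param state an [cell_state()] vector.
#' @param p an [model_parameters()] set.
#' @param reduced logical; evaluate the Alu-free reduced model.
#' @return A tibble of class `"eb_budget"` with `category` and `rate`
#'   (ATP m.p.c./min).
#' @export
energy_budget <- function(state, p, reduced = FALSE) {
  x <- unclass(validate_state(state))
  e <- .eb_rates(x, p, reduced)
  rates <- with(e, c(
    atp_degradation = p[["lambda_a"]] * a,
    replication_basal = p[["Nnt"]] * p[["Ng"]] / p[["tau"]],
    replication_insertions = p[["Nnt"]] * (p[["NL"]] * v_intL +
                                             p[["NS"]] * v_intS),
    transcription_hk = p[["Nnt"]] * p[["NQ"]] * omega_q,
    transcription_L1 = p[["Nnt"]] * p[["NL"]] * omega_L,
    transcription_Alu = p[["Nnt"]] * p[["NS"]] * omega_S,
    translation_hk = p[["Naa"]] * p[["Nq"]] * v_q,
    translation_L1 = p[["Naa"]] * p[["NL"]] / 3 * v_L,
    insertion_L1 = p[["Nnt"]] * p[["NL"]] * v_intL,
    insertion_Alu = p[["Nnt"]] * p[["NS"]] * v_intS
  ))
  structure(tibble::tibble(category = .budget_categories,
                           rate = as.numeric(rates)),
            class = c("eb_budget", class(tibble::tibble())))
}

#' Compare ATP budgets at two steady states
#'
#' Solves the steady state under both parameter sets and reports the ATP
#' budget of each side by side, with per-category ratios.
#'
#' @param p reference [model_parameters()] set.
#' @param perturbed_p perturbed parameter set.
#' @return A tibble of class `"eb_budget_comparison"`: `category`,
#'   `reference`, `perturbed`, `ratio`.
#' @export
budget_comparison <- function(p, perturbed_p) {
  ss1 <- find_steady_state(p)
  ss2 <- find_steady_state(validate_parameters(perturbed_p), ss1$state)
  if (!ss1$converged || !ss2$converged) {
    rlang::abort("both parameter sets must yield converged steady states")
  }
  b1 <- energy_budget(ss1$state, p)
  b2 <- energy_budget(ss2$state, perturbed_p)
  out <- tibble::tibble(category = b1$category, reference = b1$rate,
                        perturbed = b2$rate,
                        ratio = b2$rate / b1$rate)
  structure(out, class = c("eb_budget_comparison", class(out)))
}

#' Write a budget report to CSV
#'
#' @param budget an `"eb_budget"` or `"eb_budget_comparison"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_budget <- function(budget, path) {
  readr::write_csv(tibble::as_tibble(budget), path)
  invisible(path)
}
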