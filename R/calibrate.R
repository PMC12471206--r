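# Calibration of the free rate constants by fitting stationary ATP, L1 and
# Alu counts to wild-type targets. The problem is underdetermined (11 free
# parameters, 3 targets), so a mild log-space quadratic penalty toward the
# initial guess keeps the published optimum a fixed point of the fit and
# makes the problem well-posed. Optimization runs in log-parameter space,
# which enforces positivity without explicit constraints.

#' Specify a calibration problem
#'
#' @param free names of the free parameters; default: the optimized rate
#'   constants (ribosome binding/unbinding, substitution, ATP turnover,
#'   complex degradation, retrotransposon deactivation).
#' @param targets named vector with elements `a_wt`, `L_wt`, `S_wt`
#'   (m.p.c.); defaults to the published wild-type counts.
#' @param start named numeric vector of initial guesses for the free
#'   parameters; defaults to their values in `base`.
#' @param base parameter set supplying all non-free values (and default
#'   starts).
#' @param reg_weight weight of the log-space penalty toward `start`.
#' @return A list of class `"eb_calibration_problem"`.
#' @export
calibration_problem <- function(free = .free_params,
                                targets = NULL, start = NULL,
                                base = model_parameters(),
                                reg_weight = 1e-4) {
  base <- validate_parameters(base)
  stopifnot(all(free %in% names(.param_defaults)), reg_weight >= 0)
  targets <- targets %||% c(a_wt = base[["a_wt"]], L_wt = base[["L_wt"]],
                            S_wt = base[["S_wt"]])
  if (!all(c("a_wt", "L_wt", "S_wt") %in% names(targets)) ||
      any(targets <= 0)) {
    rlang::abort("targets must be positive and named a_wt, L_wt, S_wt")
  }
  start <- start %||% stats::setNames(as.numeric(base[free]), free)
  if (!setequal(names(start), free) || any(start <= 0)) {
    rlang::abort("start must give a positive value for every free parameter")
  }
  structure(list(free = free, targets = targets[c("a_wt", "L_wt", "S_wt")],
                 start = start[free], base = base,
                 reg_weight = reg_weight),
            class = "eb_calibration_problem")
}

#' Fit the free parameters to wild-type targets
#'
#' Minimizes the sum of squared relative residuals of the stationary ATP,
#' L1 and Alu counts against their targets, plus the problem's log-space
#' penalty toward the starting values, with the Levenberg-Marquardt
#' algorithm. Residuals are relative because the targets span six orders of
#' magnitude. With zero free parameters the input is returned unchanged.
#'
#' @param problem an [calibration_problem()].
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return An object of class `"eb_fit"`: `params` (full fitted parameter
#'   set), `estimates` (free-parameter values), `residuals` (relative target
#'   residuals at the optimum), `steady_state`, `converged`, `info`
#'   (optimizer diagnostics).
#' @examples
#' \donttest{
#' pr <- calibration_problem(free = c("lambda_L", "lambda_a"))
#' fit <- fit_free_parameters(pr)
#' tidy(fit)
#' }
#' @export
fit_free_parameters <- function(problem, maxiter = 50) {
  stopifnot(inherits(problem, "eb_calibration_problem"))
  base <- problem$base
  tg <- problem$targets
  if (length(problem$free) == 0L) {
    ss <- find_steady_state(base)
    res <- c(ss$state[["a"]] / tg[["a_wt"]], ss$state[["L"]] / tg[["L_wt"]],
             ss$state[["S"]] / tg[["S_wt"]]) - 1
    return(structure(list(params = base, estimates = numeric(0),
                          start = numeric(0),
                          residuals = res, steady_state = ss,
                          converged = ss$converged,
                          info = list(niter = 0L, message = "no free parameters")),
                     class = "eb_fit"))
  }
  warm <- reference_state()
  lpar0 <- log(problem$start)
  resid_fun <- function(lpar) {
    pp <- base
    pp[problem$free] <- exp(lpar)
    pp <- validate_parameters(pp)
    ss <- tryCatch(find_steady_state(pp, warm),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) {
      return(rep(1e3, 3 + length(lpar)))
    }
    warm <<- ss$state
    c((ss$state[["a"]] - tg[["a_wt"]]) / tg[["a_wt"]],
      (ss$state[["L"]] - tg[["L_wt"]]) / tg[["L_wt"]],
      (ss$state[["S"]] - tg[["S_wt"]]) / tg[["S_wt"]],
      sqrt(problem$reg_weight) * (lpar - lpar0))
  }
  fit <- minpack.lm::nls.lm(par = lpar0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12,
                              ptol = 1e-10))
  est <- exp(fit$par)
  pars <- base
  pars[problem$free] <- est
  pars <- validate_parameters(pars)
  ss <- find_steady_state(pars, warm)
  res <- c(a = ss$state[["a"]] / tg[["a_wt"]],
           L = ss$state[["L"]] / tg[["L_wt"]],
           S = ss$state[["S"]] / tg[["S_wt"]]) - 1
  structure(list(params = pars,
                 estimates = stats::setNames(as.numeric(est), problem$free),
                 start = problem$start,
                 residuals = res,
                 steady_state = ss,
                 converged = ss$converged && fit$info %in% 1:4,
                 info = list(niter = fit$niter, message = fit$message,
                             deviance = fit$deviance, status = fit$info)),
            class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat("<eb_fit> ", length(x$estimates), " free parameter(s), converged: ",
      x$converged, "\n  max |relative target residual|: ",
      format(max(abs(x$residuals)), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy eb_fit
#' @export
tidy.eb_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$estimates),
                 estimate = as.numeric(x$estimates),
                 start = as.numeric(x$start[names(x$estimates)]))
}

#' @method glance eb_fit
#' @export
glance.eb_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged,
                 niter = x$info$niter,
                 max_abs_residual = max(abs(x$residuals)),
                 a_star = x$steady_state$state[["a"]],
                 L_star = x$steady_state$state[["L"]],
                 S_star = x$steady_state$state[["S"]])
}
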