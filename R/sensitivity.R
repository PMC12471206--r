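# Local response coefficients and nonlinear steady-state scans of the
# stationary ATP level. All scans re-solve the steady state; successive grid
# points are warm-started (Newton first, with an integrate-then-polish
# fallback) so a 50-point scan costs seconds.

# steady state warm-started from a previous solution; Newton-only first.
# The damped Newton step clamps at zero, which can strand the iteration on
# the invariant retrotransposon-free subspace (a different root), so a
# polished state that moved any significant variable by more than ~30x
# from the warm start is discarded in favor of integrate-then-polish.
.eb_warm_steady <- function(p, warm, reduced = FALSE) {
  pol <- .eb_newton_polish(unclass(warm), p, reduced)
  w <- unclass(warm)
  sig <- w > 1e-6 * .state_scale()
  ratio <- (pol$x[sig] + 1e-300) / (w[sig] + 1e-300)
  if (any(ratio > 30 | ratio < 1 / 30)) pol$residual <- Inf
  if (pol$residual <= 1e-9) {
    state <- validate_state(pmax(pol$x, 0))
    idx <- .eb_active_idx(reduced)
    J <- .eb_jac_num(unclass(state), p, reduced)[idx, idx, drop = FALSE]
    ev <- eigen(J, only.values = TRUE)$values
    return(structure(list(state = state, residual_norm = pol$residual,
                          eigenvalues = ev, stable = all(Re(ev) < 0),
                          converged = TRUE, reduced = reduced, params = p),
                     class = "eb_steady_state"))
  }
  find_steady_state(p, validate_state(pmax(unclass(warm), 0)),
                    reduced = reduced)
}

#' Linear response coefficients of stationary ATP
#'
#' For every parameter, computes the partial derivative of the stationary
#' ATP count with respect to that parameter at the reference steady state by
#' central finite differences (relative step `rel_step`, re-solving the
#' steady state on each side), together with the dimensionless elasticity
#' `(da*/dp) * p/a*`. Elasticities put parameters spanning ~12 orders of
#' magnitude on a common scale, so rankings are asserted on them. Parameters
#' that do not enter the right-hand side (cell volume, calibration targets)
#' get exact zeros.
#'
#' @param p an [model_parameters()] set.
#' @param ref optional converged `"eb_steady_state"` at `p` (computed if
#'   missing).
#' @param rel_step relative finite-difference step.
#' @return A tibble of class `"eb_response"`: `parameter`, `raw_derivative`
#'   (mixed units), `elasticity`, `sign`, `converged` (FALSE flags a probe
#'   point where the steady-state solve failed).
#' @export
response_coefficients <- function(p, ref = NULL, rel_step = 1e-3) {
  ref <- ref %||% find_steady_state(p)
  if (!ref$converged) rlang::abort("reference steady state not converged")
  a_ref <- ref$state[["a"]]
  rows <- purrr::map_dfr(names(.param_defaults), function(nm) {
    if (nm %in% .metadata_params) {
      return(tibble::tibble(parameter = nm, raw_derivative = 0,
                            elasticity = 0, sign = 0L, converged = TRUE))
    }
    p0 <- p[[nm]]
    solve_at <- function(val) {
      pp <- p
      pp[[nm]] <- val
      .eb_warm_steady(validate_parameters(pp), ref$state)
    }
    up <- solve_at(p0 * (1 + rel_step))
    dn <- solve_at(p0 * (1 - rel_step))
    okay <- up$converged && dn$converged
    d <- if (okay) {
      (up$state[["a"]] - dn$state[["a"]]) / (2 * rel_step * p0)
    } else NA_real_
    tibble::tibble(parameter = nm, raw_derivative = d,
                   elasticity = d * p0 / a_ref,
                   sign = sign(d), converged = okay)
  })
  structure(dplyr::arrange(rows, dplyr::desc(abs(.data$elasticity))),
            class = c("eb_response", class(rows)), a_ref = a_ref)
}

#' Steady-state scan over one parameter
#'
#' Recomputes the stationary solution on a grid of fold-changes of one
#' parameter, warm-starting each point from the previous one.
#'
#' @param p an [model_parameters()] set.
#' @param name a parameter name.
#' @param folds positive fold-changes relative to the reference value.
#'   Default: 25 log-spaced folds per decade over \[1/10, 10\].
#' @return A tibble of class `"eb_scan"`: `fold`, `value`, `a_star`,
#'   `a_percent` (of reference), `converged`.
#' @export
scan_parameter <- function(p, name,
                           folds = 10^seq(-1, 1, length.out = 51)) {
  stopifnot(name %in% names(.param_defaults), all(folds > 0))
  ref <- find_steady_state(p)
  a_ref <- ref$state[["a"]]
  ord <- order(abs(log(folds)))   # walk outward from fold = 1
  res <- vector("list", length(folds))
  warm_up <- warm_dn <- ref$state
  for (i in ord) {
    pp <- p
    pp[[name]] <- folds[i] * p[[name]]
    warm <- if (folds[i] >= 1) warm_up else warm_dn
    ss <- .eb_warm_steady(validate_parameters(pp), warm)
    if (ss$converged) {
      if (folds[i] >= 1) warm_up <- ss$state else warm_dn <- ss$state
    }
    res[[i]] <- tibble::tibble(fold = folds[i], value = pp[[name]],
                               a_star = ss$state[["a"]],
                               converged = ss$converged)
  }
  out <- dplyr::arrange(dplyr::bind_rows(res), .data$fold)
  out$a_percent <- 100 * out$a_star / a_ref
  structure(out, class = c("eb_scan", class(out)),
            parameter = name, a_ref = a_ref)
}

#' Steady-state scan over a parameter pair
#'
#' Full-factorial steady-state grid over fold-changes of two parameters,
#' warm-started row-wise.
#'
#' @param p an [model_parameters()] set.
#' @param name1,name2 parameter names.
#' @param folds1,folds2 positive fold grids.
#' @return A long-format tibble of class `"eb_scan2d"`: `fold1`, `fold2`,
#'   `a_star`, `a_percent`, `converged`.
#' @export
scan_parameter_pair <- function(p, name1, name2,
                                folds1 = 10^seq(0, 1, length.out = 11),
                                folds2 = 10^seq(0, 1, length.out = 11)) {
  stopifnot(name1 %in% names(.param_defaults),
            name2 %in% names(.param_defaults),
            all(folds1 > 0), all(folds2 > 0))
  ref <- find_steady_state(p)
  a_ref <- ref$state[["a"]]
  folds1 <- sort(folds1)
  folds2 <- sort(folds2)
  res <- list()
  warm_row <- ref$state
  for (f1 in folds1) {
    warm <- warm_row
    first <- TRUE
    for (f2 in folds2) {
      pp <- p
      pp[[name1]] <- f1 * p[[name1]]
      pp[[name2]] <- f2 * p[[name2]]
      ss <- .eb_warm_steady(validate_parameters(pp), warm)
      if (ss$converged) {
        warm <- ss$state
        if (first) warm_row <- ss$state
      }
      first <- FALSE
      res[[length(res) + 1L]] <- tibble::tibble(
        fold1 = f1, fold2 = f2, a_star = ss$state[["a"]],
        converged = ss$converged)
    }
  }
  out <- dplyr::bind_rows(res)
  out$a_percent <- 100 * out$a_star / a_ref
  structure(out, class = c("eb_scan2d", class(out)),
            parameters = c(name1, name2), a_ref = a_ref)
}

#' Fold-change needed to reach a target ATP fraction
#'
#' Bisects (on the log-fold scale) for the fold-change of one or several
#' parameters that brings the stationary ATP level to `fraction` of its
#' reference value. Each parameter is moved in its ATP-lowering direction,
#' determined from the local response coefficient: positive-response
#' parameters are divided by the fold, negative-response parameters
#' multiplied. With several names, all parameters share one equal fold
#' (applied in each parameter's lowering direction).
#'
#' @param p an [model_parameters()] set.
#' @param name parameter name(s).
#' @param fraction target stationary ATP as a fraction of reference, in
#'   (0, 1\].
#' @param tol convergence tolerance on `|a*/a_ref - fraction|`.
#' @return A list: `fold` (the common fold, >= 1), `directions` (+1 if the
#'   parameter was multiplied by the fold, -1 if divided), `a_fraction`
#'   achieved, `values` (the perturbed parameter values).
#' @export
fold_to_reach_fraction <- function(p, name, fraction, tol = 1e-3) {
  stopifnot(all(name %in% names(.param_defaults)),
            fraction > 0, fraction <= 1)
  ref <- find_steady_state(p)
  a_ref <- ref$state[["a"]]
  if (fraction == 1) {
    return(list(fold = 1, directions = rep(0L, length(name)),
                a_fraction = 1,
                values = stats::setNames(as.numeric(p[name]), name)))
  }
  rc <- response_coefficients(p, ref)
  el <- stats::setNames(rc$elasticity, rc$parameter)[name]
  if (any(el == 0)) {
    rlang::abort(paste0("stationary ATP does not respond to: ",
                        paste(name[el == 0], collapse = ", ")))
  }
  dirs <- ifelse(el < 0, 1L, -1L)  # multiply negative-response params
  warm <- ref$state
  frac_at <- function(fold) {
    pp <- p
    pp[name] <- as.numeric(p[name]) * fold^dirs
    ss <- .eb_warm_steady(validate_parameters(pp), warm)
    if (ss$converged) warm <<- ss$state
    ss$state[["a"]] / a_ref
  }
  lo <- 1
  hi <- 2
  while (frac_at(hi) > fraction) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e3) rlang::abort("target fraction unreachable for fold <= 1e3")
  }
  repeat {
    mid <- sqrt(lo * hi)
    fm <- frac_at(mid)
    if (abs(fm - fraction) < tol || log(hi / lo) < 1e-6) break
    if (fm > fraction) lo <- mid else hi <- mid
  }
  list(fold = mid, directions = dirs, a_fraction = fm,
       values = stats::setNames(as.numeric(p[name]) * mid^dirs, name))
}
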