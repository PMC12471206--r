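#' Simulate a trajectory of the energy-balance model
#'
#' Integrates the stiff 12-ODE system with the Radau method (5th-order
#' implicit Runge-Kutta), using the analytic Jacobian. Default tolerances are
#' a relative tolerance of 1e-8 and per-variable absolute tolerances of 1e-6
#' times the reference scale of each variable.
#'
#' @param p an [model_parameters()] set.
#' @param init initial [cell_state()].
#' @param t_end final time (min), positive.
#' @param reduced logical; simulate the Alu-free reduced model.
#' @param times optional vector of output times (min). The default is a grid
#'   that is dense at early times (where copy-number transients play out) and
#'   logarithmically spaced later.
#' @param rtol,atol_scale integrator tolerances; `atol_scale` multiplies the
#'   per-variable reference scale.
#' @return A tibble of class `"eb_trajectory"` with columns `time` and the 12
#'   state variables, carrying the parameters and the `reduced` flag as
#'   attributes.
#' @examples
#' \donttest{
#' p <- model_parameters()
#' traj <- simulate_trajectory(p, reference_state(), t_end = 100)
#' }
#' @export
simulate_trajectory <- function(p, init, t_end, reduced = FALSE,
                                times = NULL, rtol = 1e-8,
                                atol_scale = 1e-6) {
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    rlang::abort("t_end must be a single positive time (min)")
  }
  x0 <- unclass(validate_state(init))
  if (is.null(times)) {
    times <- unique(c(0, 10^seq(-3, log10(t_end), length.out = 1500)))
  } else {
    times <- sort(unique(as.numeric(times)))
    if (any(diff(times) <= 0) || times[1] < 0 || max(times) > t_end) {
      rlang::abort("times must be strictly increasing and within [0, t_end]")
    }
  }
  out <- .eb_integrate(x0, times, p, reduced, rtol, atol_scale)
  tb <- tibble::as_tibble(as.data.frame(out))
  names(tb)[1] <- "time"
  # post-hoc admissibility: small negative excursions are integrator noise,
  # anything larger voids the run
  scale <- .state_scale()
  low <- vapply(.state_names, function(v) min(tb[[v]]), numeric(1))
  if (any(low < -1e-6 * scale)) {
    rlang::abort(paste0("trajectory left the admissible region: ",
                        paste(.state_names[low < -1e-6 * scale],
                              collapse = ", ")))
  }
  structure(tb, class = c("eb_trajectory", class(tb)),
            params = p, reduced = reduced, rtol = rtol,
            atol_scale = atol_scale)
}

# low-level radau call on a plain numeric initial state
.eb_integrate <- function(x0, times, p, reduced, rtol = 1e-8,
                          atol_scale = 1e-6) {
  func <- function(t, y, parms) {
    dy <- .eb_rhs_num(y, parms, reduced)
    if (any(!is.finite(dy))) stop("non-finite derivative")
    list(dy)
  }
  jac <- function(t, y, parms) .eb_jac_num(y, parms, reduced)
  out <- deSolve::radau(y = x0, times = times, func = func, parms = p,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol_scale * .state_scale(),
                        maxsteps = 1e5)
  if (any(abs(out[, -1]) > 1e30, na.rm = TRUE)) {
    rlang::abort("integration diverged (state exceeded 1e30)")
  }
  if (anyNA(out)) {
    last_t <- max(out[stats::complete.cases(out), 1])
    rlang::abort(paste0("integrator failed at t = ", signif(last_t, 6),
                        " min"))
  }
  out
}

#' Perturb the initial retrotransposon copy numbers
#'
#' Returns a copy of `ref` with the active L1 count multiplied by `fold_L1`
#' and the active Alu count by `fold_Alu`; all other variables keep their
#' reference values. This is the in-silico analogue of inserting (or
#' removing) active retrotransposon copies by genome editing.
#'
#' @param ref an [cell_state()] vector.
#' @param fold_L1,fold_Alu strictly positive multipliers.
#' @return An `"eb_state"` vector.
#' @export
perturb_initial_state <- function(ref, fold_L1 = 1, fold_Alu = 1) {
  if (any(c(fold_L1, fold_Alu) <= 0)) {
    rlang::abort("fold changes must be strictly positive")
  }
  x <- unclass(validate_state(ref))
  x[["L"]] <- fold_L1 * x[["L"]]
  x[["S"]] <- fold_Alu * x[["S"]]
  validate_state(x)
}

#' ATP-drop metrics of a trajectory
#'
#' Measures the total time `T_drop` the ATP trajectory spends below a
#' threshold (a fraction of the reference ATP count) and the global minimum
#' of ATP along the trajectory. A sustained drop below roughly 30% of the
#' homeostatic ATP level is treated as the marker for cell-death initiation,
#' so these two numbers quantify the potency of a perturbation. Crossing
#' times are refined by bisection (re-integrating from the nearest stored
#' state) to 1e-3 min.
#'
#' @param traj an `"eb_trajectory"` from [simulate_trajectory()].
#' @param threshold_fraction fraction of `a_ref` defining the threshold,
#'   in (0, 1).
#' @param a_ref reference ATP count (m.p.c.); defaults to the initial ATP of
#'   the trajectory.
#' @return A one-row tibble of class `"eb_drop_metrics"`: `T_drop` (min),
#'   `a_min` (m.p.c.), `threshold` (m.p.c.), `crossed` (logical).
#' @export
drop_metrics <- function(traj, threshold_fraction = 0.30, a_ref = NULL) {
  stopifnot(inherits(traj, "eb_trajectory"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    rlang::abort("threshold_fraction must lie in (0, 1)")
  }
  a_ref <- a_ref %||% traj$a[1]
  thr <- threshold_fraction * a_ref
  tt <- traj$time
  aa <- traj$a
  below <- aa < thr
  p <- attr(traj, "params")
  reduced <- attr(traj, "reduced")

  # a(t) inside [t_i, t_{i+1}] by re-integration from the stored state
  a_at <- function(i, t) {
    if (t <= tt[i]) return(aa[i])
    x0 <- stats::setNames(as.numeric(unlist(traj[i, .state_names])),
                          .state_names)
    out <- .eb_integrate(pmax(x0, 0), c(tt[i], t), p, reduced,
                         rtol = 1e-10, atol_scale = 1e-8)
    out[nrow(out), "a"]
  }
  refine <- function(i) {
    lo <- tt[i]; hi <- tt[i + 1]
    f_lo <- aa[i] - thr
    while (hi - lo > 1e-3) {
      mid <- (lo + hi) / 2
      f_mid <- a_at(i, mid) - thr
      if (sign(f_mid) == sign(f_lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  T_drop <- 0
  open_since <- if (below[1]) tt[1] else NA_real_
  for (i in seq_len(length(tt) - 1L)) {
    if (below[i] != below[i + 1L]) {
      tc <- refine(i)
      if (below[i + 1L]) {
        open_since <- tc
      } else {
        T_drop <- T_drop + (tc - open_since)
        open_since <- NA_real_
      }
    }
  }
  if (!is.na(open_since)) T_drop <- T_drop + (tt[length(tt)] - open_since)

  tibble::new_tibble(
    tibble::tibble(T_drop = T_drop, a_min = min(aa), threshold = thr,
                   crossed = T_drop > 0),
    class = "eb_drop_metrics")
}

#' Export a trajectory to CSV
#'
#' Writes the trajectory as `time,a,mq,cq,q,mL,mS,cL,O1,bL,bS,L,S`, one row
#' per saved time point.
#'
#' @param traj an `"eb_trajectory"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "eb_trajectory"))
  readr::write_csv(traj[, c("time", .state_names)], path)
  invisible(path)
}
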