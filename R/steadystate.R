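# Steady-state location: integrate-then-polish. Direct root finding from
# cold starts is unreliable for this stiff, scale-spanning system, so the
# trajectory is first relaxed until the state change over a doubling of the
# time horizon is negligible, then a damped Newton iteration on the
# right-hand side (with the analytic Jacobian, column-scaled) polishes the
# result to residuals near machine precision.

.eb_active_idx <- function(reduced) {
  if (reduced) which(!.state_names %in% c("mS", "bS", "S")) else 1:12
}

# relative stationarity residual: max over equations of |d/dt| / gross
# flux. Equations carrying less than 1e-12 of the system's dominant flux
# are numerically stationary at double precision, so the denominator is
# floored there (degenerate limits push whole pathways to denormal scale).
.eb_residual_norm <- function(x, p, reduced) {
  f <- .eb_rhs_num(x, p, reduced)
  g <- .eb_gross_num(x, p, reduced)
  idx <- .eb_active_idx(reduced)
  den <- pmax(g[idx], 1e-12 * max(g[idx]), .Machine$double.xmin)
  max(abs(f[idx]) / den)
}

.eb_newton_polish <- function(x, p, reduced, max_iter = 60L) {
  idx <- .eb_active_idx(reduced)
  scale <- pmax(abs(x), .state_scale() * 1e-9)
  obj <- function(z) .eb_residual_norm(z, p, reduced)
  best <- obj(x)
  for (it in seq_len(max_iter)) {
    f <- .eb_rhs_num(x, p, reduced)[idx]
    J <- .eb_jac_num(x, p, reduced)[idx, idx, drop = FALSE]
    s <- scale[idx]
    Js <- sweep(J, 2L, s, `*`)
    dz <- tryCatch(solve(Js, -f), error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) break
    step <- 1
    improved <- FALSE
    for (k in 1:40) {
      xn <- x
      xn[idx] <- pmax(x[idx] + step * s * dz, 0)
      val <- obj(xn)
      if (is.finite(val) && val < best) {
        x <- xn; best <- val; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved || best < 1e-13) break
  }
  list(x = x, residual = best)
}

#' Find a steady state
#'
#' Locates a stationary solution by integrating from `guess` over doubling
#' time horizons until the relative state change over a doubling falls below
#' 1e-10, then polishing with a damped Newton iteration on the right-hand
#' side. The residual norm is the maximum over equations of the stationarity
#' defect relative to the gross (production + consumption) flux of that
#' equation; convergence requires it to be at most 1e-9.
#'
#' @param p an [model_parameters()] set.
#' @param guess initial [cell_state()]; defaults to [reference_state()].
#' @param reduced logical; solve the Alu-free reduced model (the frozen
#'   variables `mS`, `bS`, `S` keep their values in `guess`).
#' @param t0 initial integration horizon (min).
#' @param t_max divergence guard on the integration horizon (min).
#' @param rtol,atol_scale integrator tolerances for the relaxation phase.
#'   Cold starts far from equilibrium traverse deep transient troughs in the
#'   retrotransposon variables; looser absolute tolerances can truncate such
#'   a trough to exact zero and strand the trajectory on the invariant
#'   retrotransposon-free subspace, so randomized sweeps tighten these.
#' @return An object of class `"eb_steady_state"`: a list with `state`
#'   (an `"eb_state"`), `residual_norm`, `eigenvalues` (of the analytic
#'   Jacobian restricted to the active variables), `stable`, `converged`,
#'   `reduced` and the parameters used.
#' @examples
#' \donttest{
#' ss <- find_steady_state(model_parameters())
#' ss$state[["a"]]
#' }
#' @export
find_steady_state <- function(p, guess = reference_state(), reduced = FALSE,
                              t0 = 64, t_max = 1e9, rtol = 1e-8,
                              atol_scale = 1e-6) {
  x <- unclass(validate_state(guess))
  if (reduced) x[c("mS", "bS", "S")] <- 0
  scale <- .state_scale()
  t_h <- t0
  x_prev <- x
  repeat {
    out <- .eb_integrate(x, c(0, t_h), p, reduced, rtol, atol_scale)
    x_new <- out[2L, -1L]
    if (any(abs(x_new) > 1e30)) rlang::abort("steady-state search diverged")
    rel <- max(abs(x_new - x_prev) / pmax(abs(x_prev), 1e-6 * scale))
    x_prev <- x_new
    x <- pmax(x_new, 0)
    if (rel < 1e-10 || t_h >= t_max) break
    t_h <- t_h * 2
  }
  pol <- .eb_newton_polish(x, p, reduced)
  converged <- pol$residual <= 1e-9
  state <- validate_state(pmax(pol$x, 0))
  idx <- .eb_active_idx(reduced)
  J <- .eb_jac_num(unclass(state), p, reduced)[idx, idx, drop = FALSE]
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = state,
                 residual_norm = pol$residual,
                 eigenvalues = ev,
                 stable = all(Re(ev) < 0),
                 converged = converged,
                 reduced = reduced,
                 params = p),
            class = "eb_steady_state")
}

#' @export
print.eb_steady_state <- function(x, ...) {
  cat("<eb_steady_state>", if (x$reduced) "(Alu-free reduced model)" else "",
      "\n  converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 3),
      "\n  stable:", x$stable,
      " leading eigenvalue:", format(max(Re(x$eigenvalues)), digits = 4),
      "1/min\n  ATP:", format(x$state[["a"]], digits = 4), "m.p.c.\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy eb_steady_state
#' @export
tidy.eb_steady_state <- function(x, ...) {
  tibble::tibble(variable = .state_names,
                 value = as.numeric(unclass(x$state)))
}

#' @method glance eb_steady_state
#' @export
glance.eb_steady_state <- function(x, ...) {
  tibble::tibble(converged = x$converged, stable = x$stable,
                 residual_norm = x$residual_norm,
                 leading_eigenvalue = max(Re(x$eigenvalues)),
                 n_eigenvalues = length(x$eigenvalues),
                 a_star = x$state[["a"]])
}

#' Assess linear stability of a steady state
#'
#' A converged stationary solution is asymptotically stable iff every
#' eigenvalue of the Jacobian (restricted to the active variables in the
#' reduced model) has a negative real part.
#'
#' @param ss an `"eb_steady_state"` from [find_steady_state()].
#' @return A list with `stable` and a tibble `eigenvalues` (columns `re`,
#'   `im`), sorted by descending real part (the first row is the leading,
#'   least-negative mode).
#' @export
assess_stability <- function(ss) {
  stopifnot(inherits(ss, "eb_steady_state"))
  if (!ss$converged) {
    rlang::abort("stability assessment requires a converged steady state")
  }
  ev <- ss$eigenvalues[order(-Re(ss$eigenvalues))]
  list(stable = all(Re(ev) < 0),
       eigenvalues = tibble::tibble(re = Re(ev), im = Im(ev)))
}

#' Probe uniqueness of the steady state
#'
#' Runs [find_steady_state()] from randomized nonnegative initial states
#' (each variable drawn log-uniformly within +/- 2 decades of its reference
#' value, fixed seed) and clusters the converged states at 0.1% relative
#' tolerance per variable.
#'
#' @param p an [model_parameters()] set.
#' @param n_starts number of random starts.
#' @param seed RNG seed for the start states.
#' @param reduced logical; probe the reduced model.
#' @return A tibble with one row per distinct steady state (columns: the 12
#'   variables, `n_converged_to` and `stable`), with the full list of
#'   per-start results in attribute `"runs"`.
#' @export
uniqueness_sweep <- function(p, n_starts = 20, seed = 1, reduced = FALSE) {
  stopifnot(n_starts >= 1)
  ref <- unclass(reference_state())
  runs <- withr::with_seed(seed, {
    purrr::map(seq_len(n_starts), function(i) {
      x0 <- ref * 10^stats::runif(12, -2, 2)
      names(x0) <- .state_names
      find_steady_state(p, validate_state(x0), reduced = reduced,
                        rtol = 1e-10, atol_scale = 1e-10)
    })
  })
  states <- purrr::map(runs, ~ as.numeric(unclass(.x$state)))
  ok <- purrr::map_lgl(runs, "converged")
  reps <- list()   # cluster representatives
  members <- integer(0)
  rep_stable <- logical(0)
  for (i in which(ok)) {
    s <- states[[i]]
    hit <- purrr::detect_index(reps, function(r) {
      all(abs(s - r) / pmax(abs(r), 1) <= 1e-3)
    })
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- s
      members <- c(members, 1L)
      rep_stable <- c(rep_stable, runs[[i]]$stable)
    } else {
      members[hit] <- members[hit] + 1L
    }
  }
  out <- purrr::map_dfr(seq_along(reps), function(k) {
    tibble::as_tibble(stats::setNames(as.list(reps[[k]]), .state_names))
  })
  out$n_converged_to <- members
  out$stable <- rep_stable
  attr(out, "runs") <- runs
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Write a steady-state report to JSON
#'
#' @param ss an `"eb_steady_state"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(ss, path) {
  stopifnot(inherits(ss, "eb_steady_state"))
  jsonlite::write_json(
    list(state = as.list(unclass(ss$state)),
         residual_norm = ss$residual_norm,
         eigenvalues = data.frame(re = Re(ss$eigenvalues),
                                  im = Im(ss$eigenvalues)),
         stable = ss$stable, converged = ss$converged,
         reduced = ss$reduced,
         params = as.list(unclass(ss$params))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
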