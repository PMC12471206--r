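# Shared fixtures, computed once per test run. Everything is built in code;
# the cache only avoids re-solving the same steady states and scenario
# trajectories across test files.

.eb_test_cache <- new.env(parent = emptyenv())

eb_cached <- function(key, expr) {
  if (!exists(key, envir = .eb_test_cache)) {
    assign(key, force(expr), envir = .eb_test_cache)
  }
  get(key, envir = .eb_test_cache)
}

eb_params <- function() model_parameters()

eb_ref_ss <- function() {
  eb_cached("ref_ss", find_steady_state(eb_params()))
}

eb_reduced_ss <- function() {
  eb_cached("reduced_ss",
            find_steady_state(eb_params(), eb_ref_ss()$state, reduced = TRUE))
}

# scenario trajectory + drop metrics for a 1000-fold copy-number boost
eb_boost_metrics <- function(which_rte) {
  key <- paste0("boost_", which_rte)
  eb_cached(key, {
    ss <- eb_ref_ss()
    init <- perturb_initial_state(
      ss$state,
      fold_L1 = if (which_rte == "L1") 1000 else 1,
      fold_Alu = if (which_rte == "Alu") 1000 else 1)
    traj <- simulate_trajectory(eb_params(), init, t_end = 1e4)
    drop_metrics(traj, 0.30, ss$state[["a"]])
  })
}

eb_threshold_fold <- function(which_rte) {
  eb_cached(paste0("tf_", which_rte),
            threshold_fold(eb_params(), which_rte, ref = eb_ref_ss()))
}

eb_response <- function() {
  eb_cached("response", response_coefficients(eb_params(), eb_ref_ss()))
}

# central finite-difference Jacobian, the independent oracle for the
# analytic one (relative step large enough that the ATP row, whose entries
# are differences of ~1e10-scale terms, is not lost to roundoff)
eb_fd_jacobian <- function(state, p, reduced = FALSE, h_rel = 1e-5) {
  x <- unclass(state)
  fd <- matrix(0, 12, 12)
  for (j in 1:12) {
    h <- max(abs(x[j]), 1) * h_rel
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- max(xm[j] - h, 0)
    fd[, j] <- (model_rhs(xp, p, reduced) - model_rhs(xm, p, reduced)) /
      (xp[j] - xm[j])
  }
  dimnames(fd) <- dimnames(model_jacobian(state, p, reduced))
  fd
}

# random admissible states around the reference, fixed seed
eb_random_states <- function(n = 10, seed = 42, decades = 1) {
  ref <- unclass(reference_state())
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      x <- ref * 10^stats::runif(12, -decades, decades)
      names(x) <- names(ref)
      cell_state(base = x)
    })
  })
}
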