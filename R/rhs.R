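#' Time derivatives of the cascade state
#'
#' Right-hand side of the cascade ODE system. The state is the vector of
#' active concentrations `X1..X5` (plus the level-2 phosphatase total `P2` as
#' a sixth component for the transcriptional-feedback variant). Level 1 is
#' receptor-ligand binding (`dX1/dt = k1 S (X1tot - X1) - k1 K_D X1`, so the
#' steady state is the occupancy isotherm); each downstream Michaelis level
#' obeys `dXi/dt = k_i X_{i-1} (Xi_tot - Xi) - p_i P_i Xi`; Hill levels use
#' the input and threshold raised to the Hill coefficient so their steady
#' state is the Hill function. A post-translational feedback multiplies the
#' dephosphorylation rate at its site by `1 + strength * X5^n`; the
#' feedforward branch scales the level-5 input by `1 + strength * X_source`;
#' the transcriptional variant appends
#' `dP2/dt = basal + induced * X5 - degradation * P2`.
#'
#' @param state Numeric state vector (length 5, or 6 for the transcriptional
#'   variant).
#' @param S Stimulus concentration.
#' @param spec A [cascade_spec()].
#' @return Numeric vector of time derivatives, same length as `state`.
#' @export
cascade_rhs <- function(state, S, spec) {
  tfb <- spec$transcriptional_feedback
  n_state <- if (is.null(tfb)) 5L else 6L
  if (length(state) != n_state)
    stop("state dimension must be ", n_state, " for this variant")
  x <- state[1:5]
  fb <- spec$feedback
  ff <- spec$feedforward
  dx <- numeric(n_state)

  lv1 <- spec$levels[[1]]
  if (lv1$mode == "michaelis") {
    dx[1] <- lv1$k * S * (lv1$kinase_total - x[1]) -
      lv1$k * spec$receptor_KD * x[1]
  } else {
    K1 <- level_K(lv1, spec$receptor_KD)
    dx[1] <- lv1$k * S^lv1$hill_n * (lv1$kinase_total - x[1]) -
      lv1$k * K1^lv1$hill_n * x[1]
  }

  for (i in 2:5) {
    lv <- spec$levels[[i]]
    ptot <- lv$phosphatase_total
    if (i == 2L && !is.null(tfb)) ptot <- state[6]
    fbmul <- 1
    if (!is.null(fb) &&
        ((fb$site == "upstream" && i == 2L) ||
         (fb$site == "downstream" && i == 5L)))
      fbmul <- 1 + fb$strength * x[5]^fb$n
    u <- x[i - 1]
    if (i == 5L && !is.null(ff))
      u <- u * (1 + ff$strength * x[ff$source_level])
    if (lv$mode == "michaelis") {
      dx[i] <- lv$k * u * (lv$kinase_total - x[i]) -
        lv$p * ptot * x[i] * fbmul
    } else {
      K <- lv$hill_K %||% (lv$p * ptot / lv$k)
      dx[i] <- lv$k * u^lv$hill_n * (lv$kinase_total - x[i]) -
        lv$k * K^lv$hill_n * x[i]
    }
  }
  if (!is.null(tfb))
    dx[6] <- tfb$basal_synthesis + tfb$induced_rate * x[5] -
      tfb$degradation * state[6]
  dx
}

#' Steady state by numerical integration
#'
#' Integrates [cascade_rhs()] from the fully inactive state (with the
#' level-2 phosphatase at its basal-synthesis level for the transcriptional
#' variant, unless `P2_init` is given) until the largest time derivative
#' falls below `tol`, doubling the integration horizon until convergence or
#' `t_max`. Non-convergence within `t_max` — e.g. a sustained oscillator —
#' is flagged, not raised.
#'
#' @param spec A [cascade_spec()].
#' @param S Stimulus concentration.
#' @param tol Convergence tolerance on `max |dX/dt|`.
#' @param t_max Maximal integration time.
#' @param P2_init Initial level-2 phosphatase total (transcriptional variant).
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @return A `steady_state` object: list with `active_concentrations`
#'   (`X1*..X5*`), `converged`, `residual` (max `|dX/dt|` at termination),
#'   and `P2` (transcriptional variant only).
#' @export
steady_state_by_integration <- function(spec, S, tol = 1e-9, t_max = 1e6,
                                        P2_init = NULL,
                                        rtol = 1e-10, atol = 1e-12) {
  tfb <- spec$transcriptional_feedback
  n_state <- if (is.null(tfb)) 5L else 6L
  state <- numeric(n_state)
  if (!is.null(tfb))
    state[6] <- P2_init %||% (tfb$basal_synthesis / tfb$degradation)
  deriv <- function(t, y, parms) list(cascade_rhs(y, S, spec))
  residual <- max(abs(cascade_rhs(state, S, spec)))
  t_chunk <- 10
  t_done <- 0
  while (residual > tol && t_done < t_max) {
    # a sustained oscillator legitimately exhausts the step budget; the
    # residual check below turns that into a non-convergence flag
    sol <- suppressWarnings(
      deSolve::lsoda(state, c(0, t_chunk), deriv, parms = NULL,
                     rtol = rtol, atol = atol, maxsteps = 50000,
                     verbose = FALSE))
    state <- as.numeric(sol[nrow(sol), -1])
    t_done <- t_done + t_chunk
    t_chunk <- t_chunk * 2
    residual <- max(abs(cascade_rhs(state, S, spec)))
  }
  out <- list(active_concentrations = state[1:5],
              converged = residual <= tol, residual = residual)
  if (!is.null(tfb)) out$P2 <- state[6]
  structure(out, class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(residual %.3g)\n", x$residual))
  print(setNames(x$active_concentrations, paste0("X", 1:5)))
  if (!is.null(x$P2)) cat("P2:", x$P2, "\n")
  invisible(x)
}
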