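# Central-difference Jacobian with per-coordinate step scaled to the state
# magnitude, h_j = rel_step * max(|x_j|, floor).
numeric_jacobian <- function(f, x, rel_step = 1e-6, floor = 1e-8) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), floor)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Jacobian of the cascade at its steady state
#'
#' Locates the fixed point of the cascade at stimulus `S` with the
#' semi-analytic steady-state solver (for sustained oscillators this is the
#' unstable fixed point, which is unique for these monotone cascades), then
#' differentiates [cascade_rhs()] there by central differences with steps
#' scaled to the state magnitude.
#'
#' @param spec A [cascade_spec()].
#' @param S Stimulus concentration.
#' @param rel_step Relative finite-difference step.
#' @return The Jacobian matrix (5x5, or 6x6 for the transcriptional
#'   variant), with the fixed point in `attr(-, "fixed_point")`.
#' @export
jacobian_at_steady_state <- function(spec, S, rel_step = 1e-6) {
  x <- cascade_steady_state(spec, S)
  if (!is.null(spec$transcriptional_feedback))
    x <- c(x, presolve_basal_phosphatase(spec, S_basal = S)$P2)
  res <- max(abs(cascade_rhs(x, S, spec)))
  if (res > 1e-6 * max(1, max(abs(x))))
    stop("fixed-point location failed (residual ", signif(res, 3), ")")
  J <- numeric_jacobian(function(z) cascade_rhs(z, S, spec), x, rel_step)
  attr(J, "fixed_point") <- x
  J
}

# Pure spectrum classifier. Real parts within zero_tol of 0 count as zero
# (boundary of the sustained class).
classify_spectrum <- function(eigenvalues, zero_tol = 1e-8) {
  re <- Re(eigenvalues)
  re[abs(re) < zero_tol] <- 0
  has_complex <- any(abs(Im(eigenvalues)) > zero_tol)
  if (any(re >= 0)) {
    if (has_complex) "sustained-oscillator" else "unstable-other"
  } else {
    if (has_complex) "damped-oscillator" else "stable-node"
  }
}

#' Linear stability of a cascade steady state
#'
#' Computes the eigenvalue spectrum of the Jacobian at the steady state and
#' classifies it: `stable-node` (all real parts negative, no complex pair),
#' `damped-oscillator` (a complex pair, all real parts negative),
#' `sustained-oscillator` (at least one eigenvalue with real part zero or
#' positive, with a complex pair), `unstable-other` (non-negative real part
#' without a complex pair). Real parts within `zero_tol` of zero are treated
#' as zero.
#'
#' @param spec A [cascade_spec()].
#' @param S Stimulus concentration.
#' @param zero_tol Magnitude below which a real part counts as zero.
#' @return A `stability_report`: list with `eigenvalues`, `classification`,
#'   `max_real_part`, `has_complex_pair`, `fixed_point`.
#' @export
classify_stability <- function(spec, S, zero_tol = 1e-8) {
  J <- jacobian_at_steady_state(spec, S)
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    list(eigenvalues = ev,
         classification = classify_spectrum(ev, zero_tol),
         max_real_part = max(Re(ev)),
         has_complex_pair = any(abs(Im(ev)) > zero_tol),
         fixed_point = attr(J, "fixed_point")),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", x$classification,
      sprintf("(max Re %.3g%s)\n", x$max_real_part,
              if (x$has_complex_pair) ", complex pair" else ""))
  invisible(x)
}

#' Stability classification over a (cooperativity, stimulus) grid
#'
#' Scans the linear stability of a feedback cascade across feedback
#' cooperativities and stimulus levels, mirroring the numerical analysis that
#' shows sustained oscillations require an upstream (delayed) negative
#' feedback with high cooperativity and low activation resistances — the
#' feedback-less and downstream-feedback cascades are stable nodes (or damped
#' oscillators) everywhere. Fixed points that cannot be located are marked
#' `"unresolved"`, never dropped.
#'
#' @param spec A [cascade_spec()] (its feedback cooperativity is replaced by
#'   each value of `n_grid`; use `n_grid = NA` to scan a feedback-less spec
#'   as is).
#' @param n_grid Integer vector of feedback cooperativities (ignored for a
#'   spec without feedback).
#' @param S_grid Stimulus grid; defaults to 25 log-spaced points covering the
#'   dynamic range of the variant's dose-response (half-maximal stimulus
#'   times `10^±2.5`).
#' @param zero_tol See [classify_stability()].
#' @return Data.frame with one row per grid point: `n`, `S`, `class`,
#'   `max_real_part`, `has_complex_pair`.
#' @export
stability_scan <- function(spec, n_grid = 1:30, S_grid = NULL,
                           zero_tol = 1e-8) {
  if (is.null(spec$feedback)) n_grid <- NA_integer_
  if (is.null(S_grid)) {
    ref <- spec
    ref$feedback <- NULL
    mid <- lumped_parameters(ref)$K_m5
    S_grid <- 10^seq(log10(mid) - 2.5, log10(mid) + 2.5, length.out = 25)
  }
  rows <- list()
  for (n in n_grid) {
    sp <- spec
    if (!is.na(n) && !is.null(sp$feedback)) sp$feedback$n <- n
    for (S in S_grid) {
      rep_ <- tryCatch(classify_stability(sp, S, zero_tol),
                       error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(rep_)) {
        data.frame(n = n, S = S, class = "unresolved",
                   max_real_part = NA_real_, has_complex_pair = NA)
      } else {
        data.frame(n = n, S = S, class = rep_$classification,
                   max_real_part = rep_$max_real_part,
                   has_complex_pair = rep_$has_complex_pair)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
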