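# Is this a switch-like variant (some level beyond the receptor is a Hill
# switch with n > 1)? Used for the responder criterion.
is_switch_variant <- function(spec) {
  any(vapply(spec$levels[2:5],
             function(l) l$mode == "hill" && l$hill_n > 1, logical(1)))
}

# Build the terminal-response evaluator for a spec: a function of S returning
# X5*, plus the protocol's basal stimulus and basal response. For the
# transcriptional variant the pre-stimulus phosphatase level is solved once
# and frozen (acute protocol).
response_function <- function(spec) {
  tfb <- spec$transcriptional_feedback
  if (is.null(tfb)) {
    f <- function(S) cascade_steady_state(spec, S)[5]
    return(list(f = f, basal_S = 0, basal_response = 0, P2_pre = NULL,
                pre_converged = TRUE))
  }
  pre <- presolve_basal_phosphatase(spec)
  frozen <- spec
  frozen$transcriptional_feedback <- NULL
  f <- function(S) cascade_steady_state(frozen, S, P2_override = pre$P2)[5]
  list(f = f, basal_S = tfb$basal_stimulus,
       basal_response = f(tfb$basal_stimulus), P2_pre = pre$P2,
       pre_converged = pre$converged, pre_residual = pre$residual)
}

#' Steady-state dose-response curve of one cell
#'
#' Evaluates the terminal-kinase steady state on a log-spaced stimulus grid
#' (default `[1e-4, 1e4] * K_D`), using the analytic or semi-analytic
#' evaluator of the variant. For the basal transcriptional feedback variant
#' the two-phase protocol is applied: the full system including the
#' phosphatase balance is solved at the basal stimulus, then the phosphatase
#' is frozen at its pre-stimulus level and the acute dose-response is
#' evaluated.
#'
#' @param spec A [cascade_spec()] (the median cell, or combine with `scales`).
#' @param scales Optional named scale factors for one cell (see
#'   [apply_to_spec()]).
#' @param S_grid Optional explicit stimulus grid (strictly increasing).
#' @param n_grid Number of grid points when `S_grid` is not given.
#' @param span Grid span as multiples of `K_D` when `S_grid` is not given.
#' @return A `dose_response_curve`: data.frame with columns `S`, `response`,
#'   and attributes `basal_response`, `basal_S`, `evaluator` (the continuous
#'   response function, used for root refinement), `spec`, `P2_pre` (basal
#'   feedback only).
#' @export
dose_response <- function(spec, scales = NULL, S_grid = NULL, n_grid = 60,
                          span = c(1e-4, 1e4)) {
  if (!is.null(scales)) spec <- apply_to_spec(spec, scales)
  if (is.null(S_grid))
    S_grid <- 10^seq(log10(span[1] * spec$receptor_KD),
                     log10(span[2] * spec$receptor_KD), length.out = n_grid)
  stopifnot(all(diff(S_grid) > 0), all(S_grid >= 0))
  rf <- response_function(spec)
  resp <- vapply(S_grid, rf$f, numeric(1))
  structure(data.frame(S = S_grid, response = resp),
            basal_response = rf$basal_response, basal_S = rf$basal_S,
            evaluator = rf$f, spec = spec, P2_pre = rf$P2_pre,
            pre_converged = rf$pre_converged,
            class = c("dose_response_curve", "data.frame"))
}

#' Acute dose-response under basal transcriptional feedback
#'
#' Convenience wrapper for the two-phase protocol of the basal feedback
#' variant; identical to [dose_response()] on a spec with transcriptional
#' feedback. Fails if the spec has none.
#'
#' @inheritParams dose_response
#' @return A `dose_response_curve` (see [dose_response()]), with the
#'   pre-stimulus phosphatase level in `attr(-, "P2_pre")`.
#' @export
basal_feedback_dose_response <- function(spec, scales = NULL, S_grid = NULL,
                                         n_grid = 60, span = c(1e-4, 1e4)) {
  if (is.null(spec$transcriptional_feedback))
    stop("spec has no transcriptional feedback")
  dose_response(spec, scales, S_grid, n_grid, span)
}

#' Summarize a dose-response curve
#'
#' Extracts the two features characterizing a cell's dose-response behavior:
#' the maximal pathway activation `X_max5` (the plateau, read off at the top
#' of the grid) and the pathway sensitivity `K_m5`, the stimulus at which the
#' response crosses the midpoint between the basal response and the plateau
#' (the cascade-level EC50 with basal correction). The crossing is bracketed
#' on the grid and refined by root finding with the curve's continuous
#' evaluator. A cell is a responder when the plateau rise exceeds
#' `responder_floor` of the terminal kinase pool and, for switch-like
#' variants, the plateau exceeds half of it (the switch actually fires);
#' `K_m5` is undefined (`NA`) for non-responders.
#'
#' @param curve A `dose_response_curve` from [dose_response()].
#' @param responder_floor Minimal plateau rise, as a fraction of the terminal
#'   kinase total (default 0.01).
#' @return A one-row data.frame: `K_m5`, `X_max5`, `basal`, `responder`,
#'   `oscillatory`.
#' @export
summarize_response <- function(curve, responder_floor = 0.01) {
  spec <- attr(curve, "spec")
  f <- attr(curve, "evaluator")
  basal <- attr(curve, "basal_response")
  basal_S <- attr(curve, "basal_S")
  T5 <- spec$levels[[5]]$kinase_total
  plateau <- curve$response[nrow(curve)]
  responder <- (plateau - basal) >= responder_floor * T5
  if (responder && is_switch_variant(spec))
    responder <- plateau >= 0.5 * T5
  K_m5 <- NA_real_
  if (responder) {
    target <- basal + (plateau - basal) / 2
    above <- which(curve$response >= target)
    hi <- curve$S[above[1]]
    lo <- if (above[1] > 1) curve$S[above[1] - 1] else
      max(basal_S, 1e-16 * spec$receptor_KD)
    if (!is.null(f)) {
      g <- function(ls) f(10^ls) - target
      # the bracketing grid interval can degenerate at machine precision
      if (g(log10(lo)) > 0) lo <- max(basal_S, 1e-16 * spec$receptor_KD)
      K_m5 <- 10^uniroot(g, log10(c(lo, hi)), tol = 1e-10)$root
    } else {
      # log-linear interpolation fallback
      i <- above[1]
      if (i == 1) K_m5 <- curve$S[1]
      else {
        w <- (target - curve$response[i - 1]) /
          (curve$response[i] - curve$response[i - 1])
        K_m5 <- 10^(log10(curve$S[i - 1]) +
                      w * (log10(curve$S[i]) - log10(curve$S[i - 1])))
      }
    }
  }
  data.frame(K_m5 = K_m5, X_max5 = plateau, basal = basal,
             responder = responder, oscillatory = FALSE)
}

#' Characterize every cell of a population
#'
#' Computes the per-cell response summary (`K_m5`, `X_max5`, responder flag)
#' for a model variant across a sampled population. The feedback-less gradual
#' cascade uses the closed-form lumped parameters; every other variant uses
#' the semi-analytic evaluator with root finding for the half-maximal
#' stimulus.
#'
#' @param spec The base (median-cell) [cascade_spec()].
#' @param population A `cell_population` from [sample_population()], or a
#'   scale-factor matrix.
#' @param responder_floor See [summarize_response()].
#' @param S_max Stimulus at which the plateau is read off (default
#'   `1e4 * K_D`).
#' @return A data.frame with one row per cell: `cell`, `K_m5`, `X_max5`,
#'   `basal`, `responder`, `oscillatory`.
#' @export
characterize_population <- function(spec, population, responder_floor = 0.01,
                                    S_max = 1e4 * spec$receptor_KD) {
  m <- if (inherits(population, "cell_population"))
    population$scale_factors else population
  n <- nrow(m)
  plain_gradual <- is.null(spec$feedback) && is.null(spec$feedforward) &&
    is.null(spec$transcriptional_feedback) &&
    all(vapply(spec$levels, function(l) l$mode, "") == "michaelis")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cell_spec <- apply_to_spec(spec, m[i, ])
    if (plain_gradual) {
      lum <- lumped_parameters(cell_spec)
      T5 <- cell_spec$levels[[5]]$kinase_total
      responder <- lum$X_max5 >= responder_floor * T5
      rows[[i]] <- data.frame(
        K_m5 = if (responder) lum$K_m5 else NA_real_,
        X_max5 = lum$X_max5, basal = 0, responder = responder,
        oscillatory = FALSE)
    } else {
      rf <- response_function(cell_spec)
      plateau <- rf$f(S_max)
      curve <- structure(
        data.frame(S = S_max, response = plateau),
        basal_response = rf$basal_response, basal_S = rf$basal_S,
        evaluator = rf$f, spec = cell_spec,
        class = c("dose_response_curve", "data.frame"))
      rows[[i]] <- summarize_response(curve, responder_floor)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(cell = seq_len(n), out)
  rownames(out) <- NULL
  out
}

#' Write dose-response curves / summaries as CSV
#'
#' @param x A `dose_response_curve` or a summary data.frame from
#'   [characterize_population()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
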