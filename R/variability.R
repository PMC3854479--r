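#' Inter-quartile ratio
#'
#' Ratio of the third to the first quartile of a distribution of positive
#' values: a dimensionless fold-difference between high and low cells that is
#' insensitive to outliers. 1 means no variability. Quartiles use linear
#' interpolation of the empirical distribution ([stats::quantile()] type 7,
#' the package-wide convention), under which `iq_ratio(1:5)` is
#' `4 / 2 = 2`.
#'
#' @param values Numeric vector of at least 4 finite positive values
#'   (non-finite entries are dropped first).
#' @return The IQ ratio (>= 1 for any sample).
#' @export
iq_ratio <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("iq_ratio needs at least 4 finite values")
  if (any(values <= 0))
    stop("iq_ratio is defined for positive values only")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] / q[1]
}

#' Coefficient of variation
#'
#' `sd(values) / mean(values)`: a scale-invariant dispersion measure; 0 means
#' no variability.
#'
#' @param values Numeric vector of at least 2 values with non-zero mean.
#' @return The CV (>= 0 for positive data).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("coefficient_of_variation needs at least 2 finite values")
  m <- mean(values)
  if (m == 0) stop("coefficient_of_variation undefined for zero mean")
  sd(values) / m
}

#' Closed-form weak-stimulus variability of the gradual cascade
#'
#' Upon weak stimulation the gradual cascade's output is the product of the
#' five kinase concentrations divided by the four phosphatase concentrations,
#' so its log-variance is the sum of the individual species' log-variances:
#' noise from every species enters additively, with a perfectly correlated
#' kinase-phosphatase pair cancelling exactly (the pair's ratio is constant)
#' and a noise-free species contributing zero. The IQ ratio of a log-normal
#' output with total log-variance `V` is `exp(2 * z_0.75 * sqrt(V))`,
#' `z_0.75 = qnorm(0.75) ~ 0.6745`. With all 9 species at log-sd 0.35 this
#' gives 4.1; eliminating one species' noise gives 3.8; correlating one
#' kinase-phosphatase pair gives 3.5 (2 s.f.).
#'
#' @param log_variances Named numeric vector of the 9 species log-variances
#'   (names [cascade_species()]; default all `0.35^2`).
#' @param correlated_pairs List of kinase-phosphatase pairs whose
#'   fluctuations are perfectly correlated (their contributions cancel).
#' @param fixed_species Species with expression noise eliminated.
#' @return List with `total_log_variance` and `iq_ratio`.
#' @export
analytic_weak_stimulus_variability <- function(
    log_variances = setNames(rep(0.35^2, 9), cascade_species()),
    correlated_pairs = list(), fixed_species = character()) {
  species <- cascade_species()
  if (is.null(names(log_variances)) && length(log_variances) == 9)
    names(log_variances) <- species
  stopifnot(all(species %in% names(log_variances)),
            all(log_variances >= 0))
  drop <- fixed_species
  for (pr in correlated_pairs) {
    stopifnot(length(pr) == 2, all(pr %in% species))
    is_kin <- startsWith(pr, "K")
    if (sum(is_kin) != 1)
      stop("only kinase-phosphatase pairs cancel in the weak-stimulus output")
    if (abs(diff(log_variances[pr])) > 1e-12)
      stop("a perfectly correlated pair must share one log-variance")
    drop <- c(drop, pr)
  }
  keep <- setdiff(species, drop)
  V <- sum(log_variances[keep])
  list(total_log_variance = V,
       iq_ratio = exp(2 * qnorm(0.75) * sqrt(V)))
}

#' Closed-form maximal-activation variance under strong negative feedback
#'
#' Under strong feedback with cooperativity `n` the terminal activity is the
#' (n+1)-th root of a product of concentrations, so the log-variance of the
#' maximal pathway activation is the sum of the species log-variances divided
#' by `(n+1)^2` — cooperative feedback suppresses noise quadratically, and
#' non-cooperative feedback (`n = 1`) already reduces the variance 4-fold.
#'
#' @param log_variances Numeric vector of species log-variances (any length;
#'   default the 9 species at `0.35^2`).
#' @param n Feedback cooperativity (>= 1).
#' @return The total log-variance of `X_max5`.
#' @export
analytic_feedback_variability <- function(
    log_variances = rep(0.35^2, 9), n = 1) {
  stopifnot(n >= 1, all(log_variances >= 0))
  sum(log_variances) / (n + 1)^2
}

#' Variability of a population summary table
#'
#' IQ ratio and CV of the pathway sensitivity (responders only) and of the
#' maximal activation, plus the responder fraction. `K_m5` statistics are
#' `NA` when fewer than 4 cells respond (bimodal regimes remain
#' interpretable through the responder fraction).
#'
#' @param summaries Data.frame from [characterize_population()].
#' @return One-row data.frame: `iq_km`, `cv_km`, `iq_xmax`, `cv_xmax`,
#'   `responder_fraction`, `n_responders`.
#' @export
summary_variability <- function(summaries) {
  km <- summaries$K_m5[summaries$responder & is.finite(summaries$K_m5)]
  xmax <- summaries$X_max5[is.finite(summaries$X_max5) & summaries$X_max5 > 0]
  data.frame(
    iq_km = if (length(km) >= 4) iq_ratio(km) else NA_real_,
    cv_km = if (length(km) >= 4) coefficient_of_variation(km) else NA_real_,
    iq_xmax = if (length(xmax) >= 4) iq_ratio(xmax) else NA_real_,
    cv_xmax = if (length(xmax) >= 4) coefficient_of_variation(xmax)
              else NA_real_,
    responder_fraction = mean(summaries$responder),
    n_responders = sum(summaries$responder))
}

#' Variability across a sweep of phosphatase activity
#'
#' Repeats the cell-to-cell variability simulation of a model variant while
#' tuning the activation resistances: at each sweep point the
#' dephosphorylation rate constants of the swept levels are multiplied by the
#' sweep value, every cell of the population is simulated and summarized, and
#' the IQ ratio and CV of `K_m5` (responders only) and `X_max5` plus the
#' responder fraction are recorded.
#'
#' @param variant_fn Function of one argument (the phosphatase scale)
#'   returning the median-cell [cascade_spec()] at that sweep point —
#'   typically `function(s) cascade_variant("gradual", p_scale = s)`.
#' @param population A `cell_population` (reused, same seed, at every point).
#' @param sweep Numeric vector of phosphatase scales (log-spaced recommended,
#'   e.g. `10^seq(-3, 3, length.out = 13)`).
#' @param ... Passed to [characterize_population()].
#' @return A `variability_table`: data.frame with one row per sweep point
#'   (`p_scale` plus the [summary_variability()] columns).
#' @export
resistance_sweep <- function(variant_fn, population, sweep, ...) {
  rows <- lapply(sweep, function(s) {
    spec <- variant_fn(s)
    sm <- characterize_population(spec, population, ...)
    cbind(p_scale = s, summary_variability(sm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Which species control pathway sensitivity and maximal activation?
#'
#' One-dimensional concentration-sensitivity analysis across a simulated
#' population: for each of the 9 species, the Spearman rank correlation and
#' the log-log regression slope of the per-cell `K_m5` (responders only) and
#' `X_max5` against the cell's scale factor. Upstream kinases control the
#' sensitivity (negative `K_m5` correlation: high-expressing cells respond at
#' lower stimulus), the terminal kinase controls the maximal activation.
#'
#' @param population A `cell_population` (or scale-factor matrix).
#' @param summaries Matched data.frame from [characterize_population()].
#' @return Data.frame with one row per species: `species`, `cor_km`,
#'   `slope_km`, `cor_xmax`, `slope_xmax`.
#' @export
concentration_sensitivity <- function(population, summaries) {
  m <- if (inherits(population, "cell_population"))
    population$scale_factors else population
  stopifnot(nrow(m) == nrow(summaries))
  resp <- summaries$responder & is.finite(summaries$K_m5)
  if (sum(resp) < 4)
    stop("concentration sensitivity undefined: fewer than 4 responders")
  pos_x <- is.finite(summaries$X_max5) & summaries$X_max5 > 0
  rows <- lapply(cascade_species(), function(sp) {
    s <- m[, sp]
    if (sd(s) == 0) {
      return(data.frame(species = sp, cor_km = NA_real_, slope_km = NA_real_,
                        cor_xmax = NA_real_, slope_xmax = NA_real_))
    }
    fit_km <- stats::coef(stats::lm(log(summaries$K_m5[resp]) ~
                                      log(s[resp])))[2]
    fit_xm <- stats::coef(stats::lm(log(summaries$X_max5[pos_x]) ~
                                      log(s[pos_x])))[2]
    data.frame(
      species = sp,
      cor_km = cor(s[resp], summaries$K_m5[resp], method = "spearman"),
      slope_km = unname(fit_km),
      cor_xmax = cor(s[pos_x], summaries$X_max5[pos_x], method = "spearman"),
      slope_xmax = unname(fit_xm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
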