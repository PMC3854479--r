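#' Steady state of a single cascade level
#'
#' Local dose-response of one (de)phosphorylation cycle. For a Michaelis level
#' the active kinase at steady state is `X_tot * u / (u + Q)` with
#' `Q = p * P / k`, the upstream activity at which kinase and phosphatase
#' activities balance (half-maximal activation at `u = Q`). For a Hill level
#' it is `X_tot * u^n / (u^n + K^n)`.
#'
#' @param upstream_active Active concentration of the upstream kinase (>= 0).
#' @param level A [level_kinetics()] object (levels 2-5; must carry a
#'   phosphatase or, for Hill mode, an explicit `hill_K`).
#' @return Active kinase concentration at steady state, in
#'   `[0, kinase_total]`.
#' @export
level_steady_state <- function(upstream_active, level) {
  u <- upstream_active
  if (any(u < 0)) stop("upstream activity must be non-negative")
  if (level$mode == "michaelis") {
    Q <- level_Q(level)
    ifelse(u == 0, 0, level$kinase_total * u / (u + Q))
  } else {
    K <- level_K(level)
    n <- level$hill_n
    if (K == 0 && any(u == 0))
      stop("Hill level with K = 0 is indeterminate at zero input")
    ifelse(u == 0, 0, level$kinase_total * u^n / (u^n + K^n))
  }
}

# Active level-1 species: receptor-ligand occupancy (Michaelis in S with
# half-saturation K_D), or a Hill function of S for a level-1 switch.
receptor_activity <- function(spec, S) {
  lv <- spec$levels[[1]]
  if (lv$mode == "michaelis") {
    ifelse(S == 0, 0, lv$kinase_total * S / (S + spec$receptor_KD))
  } else {
    K <- level_K(lv, spec$receptor_KD)
    n <- lv$hill_n
    ifelse(S == 0, 0, lv$kinase_total * S^n / (S^n + K^n))
  }
}

# Forward iteration of levels 2..5 given level-1 activity, an assumed terminal
# activity x5 (entering any post-translational feedback term), and an optional
# absolute override of the level-2 phosphatase total (transcriptional
# protocol). Returns the 5-vector of active concentrations.
forward_levels <- function(spec, u1, x5_assumed = 0, P2_override = NULL) {
  x <- numeric(5)
  x[1] <- u1
  fb <- spec$feedback
  ff <- spec$feedforward
  u <- u1
  for (i in 2:5) {
    lv <- spec$levels[[i]]
    ptot <- lv$phosphatase_total
    if (i == 2L && !is.null(P2_override)) ptot <- P2_override
    fbmul <- 1
    if (!is.null(fb) &&
        ((fb$site == "upstream" && i == 2L) ||
         (fb$site == "downstream" && i == 5L)))
      fbmul <- 1 + fb$strength * x5_assumed^fb$n
    uin <- u
    if (i == 5L && !is.null(ff))
      uin <- u * (1 + ff$strength * x[ff$source_level])
    if (lv$mode == "michaelis") {
      Q <- lv$p * ptot / lv$k * fbmul
      x[i] <- if (uin == 0) 0 else lv$kinase_total * uin / (uin + Q)
    } else {
      K <- lv$hill_K %||% (lv$p * ptot / lv$k)
      n <- lv$hill_n
      x[i] <- if (uin == 0) 0 else
        lv$kinase_total * uin^n / (uin^n + K^n)
    }
    u <- x[i]
  }
  x
}

#' Steady-state activity profile of a cascade at one stimulus level
#'
#' Semi-analytic steady state of any cascade variant: the five levels are
#' iterated top-down; a post-translational feedback closes a scalar
#' fixed-point equation in the terminal activity, which is solved by
#' root finding (the right-hand side is monotone decreasing in the terminal
#' activity, so the fixed point is unique). For the transcriptional variant
#' the pre-stimulus phosphatase level must either be supplied via
#' `P2_override` (acute protocol) or is solved self-consistently at this `S`.
#'
#' @param spec A [cascade_spec()].
#' @param S Stimulus concentration (scalar, >= 0).
#' @param P2_override Absolute level-2 phosphatase total overriding the spec
#'   (used by the basal transcriptional protocol).
#' @return Numeric 5-vector of active concentrations `X1*..X5*`.
#' @export
cascade_steady_state <- function(spec, S, P2_override = NULL) {
  stopifnot(length(S) == 1L, S >= 0)
  if (!is.null(spec$transcriptional_feedback) && is.null(P2_override))
    P2_override <- presolve_basal_phosphatase(spec, S_basal = S)$P2
  u1 <- receptor_activity(spec, S)
  if (is.null(spec$feedback))
    return(forward_levels(spec, u1, P2_override = P2_override))
  if (u1 == 0) return(numeric(5))
  T5 <- spec$levels[[5]]$kinase_total
  g <- function(z) forward_levels(spec, u1, x5_assumed = z,
                                  P2_override = P2_override)[5] - z
  x0 <- forward_levels(spec, u1, x5_assumed = 0, P2_override = P2_override)
  if (x0[5] <= 0) return(x0)
  root <- uniroot(g, c(0, T5), tol = 1e-13 * max(T5, 1))$root
  x <- forward_levels(spec, u1, x5_assumed = root, P2_override = P2_override)
  x[5] <- root
  x
}

#' Global dose-response of the feedback-less gradual cascade
#'
#' Iterates the per-level Michaelis steady states from receptor occupancy to
#' the terminal kinase. The composite curve is exactly Michaelis-Menten in
#' `S`, with maximal activation and half-maximal stimulus given by
#' [lumped_parameters()].
#'
#' @param spec A feedback-less, all-Michaelis [cascade_spec()].
#' @param S Stimulus concentration(s) (>= 0); may be a vector.
#' @return For scalar `S`, a `steady_state` object (list with
#'   `active_concentrations`, `converged`, `residual`); for vector `S`, a
#'   matrix with one row per stimulus and columns `X1..X5`.
#' @export
gradual_dose_response <- function(spec, S) {
  if (!is.null(spec$feedback) || !is.null(spec$feedforward) ||
      !is.null(spec$transcriptional_feedback))
    stop("gradual_dose_response applies to the plain cascade only")
  if (any(vapply(spec$levels, function(l) l$mode, "") != "michaelis"))
    stop("gradual_dose_response requires Michaelis kinetics at every level")
  stopifnot(all(S >= 0))
  if (length(S) == 1L) {
    x <- forward_levels(spec, receptor_activity(spec, S))
    return(structure(list(active_concentrations = x, converged = TRUE,
                          residual = 0), class = "steady_state"))
  }
  t(vapply(S, function(s) forward_levels(spec, receptor_activity(spec, s)),
           numeric(5), USE.NAMES = FALSE)) |>
    `colnames<-`(paste0("X", 1:5))
}

#' Lumped dose-response parameters of the gradual cascade
#'
#' Closed-form maximal activation `X_max,i` and half-maximal stimulus `K_m,i`
#' of every level of the feedback-less gradual cascade, via the recursion
#' `X_max,i = X_i^tot * X_max,i-1 / (X_max,i-1 + Q_i)`,
#' `K_m,i = K_m,i-1 * Q_i / (X_max,i-1 + Q_i)` with `K_m,1 = K_D`,
#' `X_max,1 = X_1^tot` and `Q_i = p_i * P_i / k_i`. Because the composition of
#' Michaelis functions is again Michaelis, these are exact:
#' `X5*(S) = X_max,5 * S / (S + K_m,5)`.
#'
#' The activation resistance `rho_i = Q_i / X_max,i-1` is the phosphatase
#' activity at level i relative to the maximal kinase activity feeding it:
#' `rho_i << 1` means the level saturates under strong stimulation
#' (`X_max,5 -> X_5^tot` when all `rho -> 0`), `rho_i >> 1` aligns the
#' pathway sensitivity to receptor binding (`K_m,5 -> K_D`).
#'
#' @param spec A feedback-less, all-Michaelis [cascade_spec()].
#' @return List with `X_max5`, `K_m5`, `rho` (levels 2-5), and the per-level
#'   vectors `X_max`, `K_m`.
#' @export
lumped_parameters <- function(spec) {
  if (!is.null(spec$feedback) || !is.null(spec$feedforward))
    stop("lumped parameters are defined for the feedback-less cascade")
  X_max <- K_m <- numeric(5)
  X_max[1] <- spec$levels[[1]]$kinase_total
  K_m[1] <- spec$receptor_KD
  rho <- numeric(4)
  for (i in 2:5) {
    if (X_max[i - 1] == 0)
      stop("upstream maximal activation is zero; resistance undefined")
    Q <- level_Q(spec$levels[[i]])
    rho[i - 1] <- Q / X_max[i - 1]
    X_max[i] <- spec$levels[[i]]$kinase_total * X_max[i - 1] / (X_max[i - 1] + Q)
    K_m[i] <- K_m[i - 1] * Q / (X_max[i - 1] + Q)
  }
  list(X_max5 = X_max[5], K_m5 = K_m[5], rho = rho, X_max = X_max, K_m = K_m)
}

#' Weak-stimulus gain of the gradual cascade
#'
#' Linear response coefficient `X5*(S) / S` in the limit `S << K_m,5`:
#' the product of the five kinase concentrations divided by `K_D` and the four
#' phosphatase activities,
#' `gain = (X1 * prod(k_i X_i)) / (K_D * prod(p_i P_i))`, identical to
#' `X_max,5 / K_m,5`. Doubling any kinase total doubles the gain; doubling any
#' phosphatase total halves it.
#'
#' @param spec A feedback-less, all-Michaelis [cascade_spec()].
#' @return The gain (response per unit stimulus).
#' @export
weak_stimulus_gain <- function(spec) {
  lv <- spec$levels
  for (i in 2:5)
    if (lv[[i]]$phosphatase_total == 0 || lv[[i]]$p == 0)
      stop("zero phosphatase activity: weak-stimulus gain diverges")
  gain <- lv[[1]]$kinase_total / spec$receptor_KD
  for (i in 2:5)
    gain <- gain * lv[[i]]$k * lv[[i]]$kinase_total /
      (lv[[i]]$p * lv[[i]]$phosphatase_total)
  gain
}

#' Asymptotic steady state under strong negative feedback
#'
#' Closed-form terminal activity in the limit of formally infinite feedback
#' gain. For upstream feedback the level-2 balance with a non-saturating
#' downstream cascade gives
#' `X5* = (B * S/(S + K_D))^(1/(n+1))`, so the stimulus enters as the
#' (n+1)-th root only: the dose-response is much shallower than
#' Michaelis-Menten (a 10-to-90 percent rise requires a ~420-fold stimulus
#' increase for n = 1 versus 81-fold without feedback), and the half-maximal
#' stimulus `K_D / (2^(n+1) - 1)` is proportional to `K_D` alone,
#' independent of every kinase and phosphatase concentration. For downstream
#' feedback the terminal level obeys
#' `X5* = (k5 X5tot / (p5 P5 strength) * Xmax4 S/(S + Km4))^(1/(n+1))`:
#' as shallow, but with half-maximal stimulus proportional to `K_m,4`, so
#' variability arising between receptor and level 4 is transmitted.
#'
#' @param spec A gradual [cascade_spec()] with a [feedback_spec()] (its
#'   `strength` is ignored: the asymptotic regime is evaluated).
#' @param S Stimulus concentration(s) (>= 0).
#' @return Terminal activity `X5*` (same length as `S`), with attributes
#'   `X_max5` (plateau) and `K_half` (half-maximal stimulus).
#' @export
strong_feedback_steady_state <- function(spec, S) {
  fb <- spec$feedback
  if (is.null(fb)) stop("spec carries no feedback loop")
  stopifnot(fb$n >= 1, all(S >= 0))
  lv <- spec$levels
  n1 <- fb$n + 1
  if (fb$site == "upstream") {
    B <- lv[[1]]$kinase_total *
      lv[[2]]$k * lv[[2]]$kinase_total /
      (lv[[2]]$p * lv[[2]]$phosphatase_total * fb$strength)
    for (i in 3:5)
      B <- B * lv[[i]]$k * lv[[i]]$kinase_total /
        (lv[[i]]$p * lv[[i]]$phosphatase_total)
    x5 <- (B * S / (S + spec$receptor_KD))^(1 / n1)
    x5[S == 0] <- 0
    K_half <- spec$receptor_KD / (2^n1 - 1)
    X_max <- B^(1 / n1)
  } else {
    spec4 <- spec
    spec4$feedback <- NULL
    lum <- lumped_parameters(spec4)
    u4 <- lum$X_max[4] * S / (S + lum$K_m[4])
    A <- lv[[5]]$k * lv[[5]]$kinase_total /
      (lv[[5]]$p * lv[[5]]$phosphatase_total * fb$strength)
    x5 <- (A * u4)^(1 / n1)
    x5[S == 0] <- 0
    K_half <- lum$K_m[4] / (2^n1 - 1)
    X_max <- (A * lum$X_max[4])^(1 / n1)
  }
  structure(x5, X_max5 = X_max, K_half = K_half)
}

#' Fold-increase in stimulus between two activation fractions
#'
#' Numerically inverts a monotone dose-response function to find the fold
#' change in stimulus needed to move from `lower` to `upper` fractional
#' activation of the plateau (the 10-to-90 percent ratio by default), a
#' standard measure of dose-response steepness (81 for Michaelis-Menten).
#'
#' @param response Function of `S` returning the response.
#' @param lower,upper Fractional activation levels (defaults 0.1 and 0.9).
#' @param S_max Stimulus at which the plateau is read off.
#' @return `S(upper) / S(lower)`.
#' @export
stimulus_fold_change <- function(response, lower = 0.1, upper = 0.9,
                                 S_max = 1e8) {
  plateau <- response(S_max)
  stopifnot(plateau > 0)
  find <- function(frac) {
    g <- function(ls) response(10^ls) - frac * plateau
    10^uniroot(g, c(-14, log10(S_max)), tol = 1e-12)$root
  }
  find(upper) / find(lower)
}

#' Closed-form 10-90 stimulus ratio of a root-Michaelis response
#'
#' For a response proportional to `(S/(S+K))^(1/(n+1))` — the strong-feedback
#' asymptotic form; `n = 0` is plain Michaelis-Menten — the fold increase in
#' stimulus from fraction `lower` to `upper` of maximum is
#' `[u^(n+1)/(1-u^(n+1))] / [l^(n+1)/(1-l^(n+1))]`, e.g. exactly 81 for
#' `n = 0` and about 422 for non-cooperative feedback (`n = 1`).
#'
#' @param n Feedback cooperativity (0 for no feedback).
#' @param lower,upper Fractional activation levels (defaults 0.1, 0.9).
#' @return The stimulus fold change.
#' @export
root_mm_fold_change <- function(n = 0, lower = 0.1, upper = 0.9) {
  r <- function(f) f^(n + 1) / (1 - f^(n + 1))
  r(upper) / r(lower)
}

#' Switching threshold of a two-level ultrasensitive cascade
#'
#' Closed-form threshold of a cascade of two Hill levels (level 1 a Hill
#' function of `S` with half-saturation `K1`, level 2 of `X1` with
#' half-saturation `K2`): the composite switches where the level-1 output
#' crosses the level-2 threshold, at
#' `S_thr = K1 * (r / (1 - r))^(1/n1)`, where the ratio r is
#' `K2 / X1_tot`. The threshold
#' thus depends on the level-2 kinase/phosphatase balance only through the
#' n-th root: doubling the level-2 phosphatase total multiplies it by about
#' `2^(1/n1)`, the origin of the distributed switch's inherent invariance.
#' Undefined (non-responder) when `K2 >= X1_tot`, i.e. the level-1 plateau
#' cannot reach the level-2 threshold.
#'
#' @param spec A [cascade_spec()] whose first two levels are Hill mode.
#' @return The switching threshold stimulus.
#' @export
distributed_threshold <- function(spec) {
  lv1 <- spec$levels[[1]]; lv2 <- spec$levels[[2]]
  if (lv1$mode != "hill" || lv2$mode != "hill")
    stop("distributed_threshold applies to a two-level Hill cascade")
  K1 <- level_K(lv1, spec$receptor_KD)
  K2 <- level_K(lv2)
  r <- K2 / lv1$kinase_total
  if (r >= 1)
    stop("level-2 threshold exceeds the level-1 plateau: non-responder, ",
         "threshold undefined")
  K1 * (r / (1 - r))^(1 / lv1$hill_n)
}

#' Switching threshold of the coherent feedforward switch
#'
#' Closed-form threshold of the single-switch cascade with a receptor-driven
#' feedforward branch, valid in the non-saturating regime (high activation
#' resistances, strong crosstalk): with the upstream cascade linear,
#' `X4 ~ G4 * S` and the branch `X1 ~ (X1_tot/K_D) * S`, the terminal switch
#' fires where `X4 * strength * X1 = K5`, i.e. at
#' `S_thr = sqrt(K5 * K_D / (strength * G4 * X1_tot))`.
#' The stimulus enters both branches, so each branch's variability enters the
#' threshold as a square root only — the basis of feedforward variability
#' suppression. Below threshold the log-log slope of the response is twice
#' that of the branch-less switch.
#'
#' @param spec A single-switch [cascade_spec()] with a [feedforward_spec()]
#'   sourced at level 1.
#' @return The switching threshold stimulus.
#' @export
feedforward_threshold <- function(spec) {
  ff <- spec$feedforward
  if (is.null(ff)) stop("spec carries no feedforward branch")
  if (ff$source_level != 1L)
    stop("closed-form threshold assumes a receptor-proximal branch")
  lv <- spec$levels
  if (lv[[5]]$mode != "hill")
    stop("feedforward threshold applies to the terminal-switch cascade")
  if (ff$strength == 0) stop("zero crosstalk: use the branch-less threshold")
  K5 <- level_K(lv[[5]])
  G4 <- lv[[1]]$kinase_total / spec$receptor_KD
  for (i in 2:4)
    G4 <- G4 * lv[[i]]$k * lv[[i]]$kinase_total /
      (lv[[i]]$p * lv[[i]]$phosphatase_total)
  thr <- sqrt(K5 * spec$receptor_KD /
                (ff$strength * G4 * lv[[1]]$kinase_total))
  if (lv[[4]]$kinase_total * (1 + ff$strength * lv[[1]]$kinase_total) < K5)
    stop("even the fully enhanced level-4 activity stays below the switch ",
         "threshold: non-responder, threshold undefined")
  thr
}

# Pre-stimulus steady state of the transcriptional feedback variant: solves
# P2 = (basal + induced * X5*(S_basal; P2)) / degradation. X5* decreases with
# P2, so the fixed point is unique; bisection on P2.
presolve_basal_phosphatase <- function(spec, S_basal = NULL) {
  tfb <- spec$transcriptional_feedback
  if (is.null(tfb)) stop("spec has no transcriptional feedback")
  S_basal <- S_basal %||% tfb$basal_stimulus
  frozen <- spec
  frozen$transcriptional_feedback <- NULL
  x5_at <- function(P2) cascade_steady_state(frozen, S_basal,
                                             P2_override = P2)[5]
  h <- function(P2) tfb$basal_synthesis + tfb$induced_rate * x5_at(P2) -
    tfb$degradation * P2
  lo <- tfb$basal_synthesis / tfb$degradation
  hi <- (tfb$basal_synthesis +
           tfb$induced_rate * spec$levels[[5]]$kinase_total) /
    tfb$degradation
  if (h(lo) <= 0) {
    P2 <- lo
  } else if (hi <= lo * (1 + 1e-12)) {
    P2 <- lo
  } else {
    P2 <- uniroot(h, c(lo, hi), tol = 1e-12 * max(hi, 1))$root
  }
  list(P2 = P2, residual = abs(h(P2)), converged = TRUE)
}
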