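#' @importFrom stats median qnorm quantile rlnorm sd setNames uniroot cor
#' @importFrom utils modifyList read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinetics of one cascade level
#'
#' Describes a single (de)phosphorylation cycle in a five-step kinase cascade:
#' a kinase pool of total concentration `kinase_total` is activated by the
#' upstream signal (second-order rate constant `k`) and deactivated by a
#' phosphatase of total concentration `phosphatase_total` (rate constant `p`).
#' The steady state of the level is either Michaelis-Menten in the upstream
#' activity (`mode = "michaelis"`, a gradual level) or a Hill function
#' (`mode = "hill"`, an ultrasensitive level abstracting mechanisms such as
#' multisite phosphorylation or zero-order ultrasensitivity).
#'
#' For a Hill level the half-saturation constant defaults to the equivalence
#' point of kinase and phosphatase activities, `Q = p * phosphatase_total / k`,
#' so that the switching threshold is proportional to the phosphatase
#' concentration and `hill_n = 1` reduces exactly to the Michaelis level.
#'
#' @param kinase_total Total kinase concentration at this level (a.u., >= 0).
#' @param phosphatase_total Total phosphatase concentration (a.u., >= 0); `NA`
#'   for level 1, where deactivation is ligand dissociation.
#' @param k Phosphorylation rate constant (per concentration per time, >= 0).
#' @param p Dephosphorylation rate constant (per concentration per time, >= 0);
#'   `NA` for level 1.
#' @param mode `"michaelis"` (gradual) or `"hill"` (ultrasensitive).
#' @param hill_n Hill coefficient (>= 1, Hill mode only).
#' @param hill_K Optional explicit half-saturation constant for Hill mode;
#'   defaults to `p * phosphatase_total / k`.
#' @return An object of class `level_kinetics`.
#' @export
level_kinetics <- function(kinase_total = 1, phosphatase_total = 1, k = 1, p = 1,
                           mode = c("michaelis", "hill"), hill_n = 1,
                           hill_K = NULL) {
  mode <- match.arg(mode)
  stopifnot(kinase_total >= 0, k >= 0)
  if (!is.na(phosphatase_total)) stopifnot(phosphatase_total >= 0)
  if (!is.na(p)) stopifnot(p >= 0)
  if (mode == "hill") {
    stopifnot(hill_n >= 1)
    if (!is.null(hill_K)) stopifnot(hill_K >= 0)
  }
  structure(
    list(kinase_total = kinase_total, phosphatase_total = phosphatase_total,
         k = k, p = p, mode = mode, hill_n = hill_n, hill_K = hill_K),
    class = "level_kinetics")
}

# Equivalence point of kinase and phosphatase activity: upstream input at which
# the Michaelis level is half-activated.
level_Q <- function(level) {
  if (is.na(level$phosphatase_total) || is.na(level$p))
    stop("level has no phosphatase; Q is undefined")
  if (level$k == 0) stop("zero phosphorylation rate constant; Q is undefined")
  level$p * level$phosphatase_total / level$k
}

# Effective Hill half-saturation constant of a level.
level_K <- function(level, receptor_KD = NULL) {
  if (!is.null(level$hill_K)) return(level$hill_K)
  if (is.na(level$phosphatase_total)) {
    if (is.null(receptor_KD)) stop("level-1 Hill threshold needs hill_K or K_D")
    return(receptor_KD)
  }
  level_Q(level)
}

#' Negative feedback specification
#'
#' The active terminal kinase enhances a phosphatase activity: at the second
#' level (`site = "upstream"`, the long loop) or at its own level
#' (`site = "downstream"`, the short loop). The dephosphorylation rate at the
#' target level is multiplied by `1 + strength * X5^n`. `strength = 0`
#' recovers the feedback-less cascade exactly.
#'
#' @param site `"upstream"` (level-2 phosphatase) or `"downstream"` (level-5).
#' @param strength Dimensionless feedback gain (>= 0).
#' @param n Integer cooperativity exponent (>= 1); `n > 1` is cooperative
#'   feedback.
#' @return An object of class `feedback_spec`.
#' @export
feedback_spec <- function(site = c("upstream", "downstream"), strength = 100,
                          n = 1) {
  site <- match.arg(site)
  stopifnot(strength >= 0, n >= 1)
  structure(list(site = site, strength = strength, n = n),
            class = "feedback_spec")
}

#' Basal transcriptional feedback specification
#'
#' The level-2 phosphatase is synthesized at a basal rate plus a rate induced
#' by the active terminal kinase, and degraded first-order:
#' `dP2/dt = basal_synthesis + induced_rate * X5 - degradation * P2`.
#' Under time-scale separation the feedback only operates before acute
#' stimulation: the pre-stimulus steady state of `P2` at `basal_stimulus` is
#' computed first, and `P2` is then frozen at that value while the acute
#' dose-response is evaluated.
#'
#' @param basal_synthesis Basal synthesis rate (concentration/time).
#' @param induced_rate Induced synthesis rate constant
#'   (per concentration per time), multiplying the active terminal kinase.
#' @param degradation First-order degradation rate (per time).
#' @param basal_stimulus Chronic pre-stimulation stimulus level
#'   (concentration).
#' @return An object of class `transcriptional_feedback_spec`.
#' @export
transcriptional_feedback_spec <- function(basal_synthesis = 0.5,
                                          induced_rate = 1,
                                          degradation = 1,
                                          basal_stimulus = 1e-3) {
  stopifnot(basal_synthesis >= 0, induced_rate >= 0, degradation > 0,
            basal_stimulus >= 0)
  structure(list(basal_synthesis = basal_synthesis,
                 induced_rate = induced_rate,
                 degradation = degradation,
                 basal_stimulus = basal_stimulus),
            class = "transcriptional_feedback_spec")
}

#' Coherent feedforward specification
#'
#' A receptor-proximal branch enhances phosphorylation of the terminal kinase:
#' the effective input to level 5 becomes
#' `X4 * (1 + strength * X_source)`, with `source_level = 1` by default (the
#' branch is driven directly by receptor occupancy). `strength = 0` recovers
#' the branch-less cascade exactly.
#'
#' @param strength Dimensionless crosstalk strength (>= 0).
#' @param source_level Cascade level feeding the branch (default 1).
#' @return An object of class `feedforward_spec`.
#' @export
feedforward_spec <- function(strength = 100, source_level = 1) {
  stopifnot(strength >= 0, source_level %in% 1:4)
  structure(list(strength = strength, source_level = source_level),
            class = "feedforward_spec")
}

#' Full parameterization of a five-step cascade variant
#'
#' Bundles the receptor-ligand dissociation constant, the kinetics of the five
#' cascade levels, and at most one regulatory motif of each kind. Level 1 is
#' receptor-ligand binding: its active form is the occupancy
#' `X1_tot * S / (S + receptor_KD)` and it carries no phosphatase. The
#' remaining four levels each carry a phosphatase, giving the 9 fluctuating
#' signaling species (5 kinases K1-K5, 4 phosphatases P2-P5).
#'
#' @param receptor_KD Dissociation constant of receptor-ligand binding.
#' @param levels List of exactly 5 [level_kinetics()] objects; level 1 must
#'   have no phosphatase.
#' @param feedback Optional [feedback_spec()].
#' @param transcriptional_feedback Optional [transcriptional_feedback_spec()];
#'   mutually exclusive with `feedback`.
#' @param feedforward Optional [feedforward_spec()].
#' @param variant Optional variant name (metadata only).
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(receptor_KD = 1, levels, feedback = NULL,
                         transcriptional_feedback = NULL, feedforward = NULL,
                         variant = "custom") {
  stopifnot(receptor_KD > 0, is.list(levels), length(levels) == 5)
  if (!all(vapply(levels, inherits, logical(1), "level_kinetics")))
    stop("all levels must be level_kinetics objects")
  if (!is.na(levels[[1]]$phosphatase_total))
    stop("level 1 has no phosphatase (deactivation is ligand dissociation)")
  for (i in 2:5)
    if (is.na(levels[[i]]$phosphatase_total) || is.na(levels[[i]]$p))
      stop("levels 2-5 each require a phosphatase")
  if (!is.null(feedback) && !is.null(transcriptional_feedback))
    stop("at most one of feedback / transcriptional_feedback may be active")
  if (!is.null(feedback)) {
    stopifnot(inherits(feedback, "feedback_spec"))
    site_level <- if (feedback$site == "upstream") 2L else 5L
    if (levels[[site_level]]$mode != "michaelis")
      stop("post-translational feedback requires a Michaelis level at its site")
  }
  if (!is.null(transcriptional_feedback))
    stopifnot(inherits(transcriptional_feedback,
                       "transcriptional_feedback_spec"))
  if (!is.null(feedforward))
    stopifnot(inherits(feedforward, "feedforward_spec"))
  structure(
    list(receptor_KD = receptor_KD, levels = levels, feedback = feedback,
         transcriptional_feedback = transcriptional_feedback,
         feedforward = feedforward, variant = variant),
    class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("<cascade_spec>", x$variant, "\n")
  cat("  receptor K_D:", x$receptor_KD, "\n")
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    cat(sprintf("  level %d: %s  K=%g  P=%s  k=%g  p=%s%s\n", i, lv$mode,
                lv$kinase_total,
                ifelse(is.na(lv$phosphatase_total), "-",
                       format(lv$phosphatase_total)),
                lv$k, ifelse(is.na(lv$p), "-", format(lv$p)),
                if (lv$mode == "hill") sprintf("  n=%g", lv$hill_n) else ""))
  }
  if (!is.null(x$feedback))
    cat(sprintf("  feedback: %s  strength=%g  n=%g\n", x$feedback$site,
                x$feedback$strength, x$feedback$n))
  if (!is.null(x$transcriptional_feedback))
    cat(sprintf("  transcriptional feedback: basal=%g induced=%g deg=%g S_basal=%g\n",
                x$transcriptional_feedback$basal_synthesis,
                x$transcriptional_feedback$induced_rate,
                x$transcriptional_feedback$degradation,
                x$transcriptional_feedback$basal_stimulus))
  if (!is.null(x$feedforward))
    cat(sprintf("  feedforward: strength=%g  source level %d\n",
                x$feedforward$strength, x$feedforward$source_level))
  invisible(x)
}

#' Preset cascade model variants
#'
#' Builds one of the study's model variants at the baseline parameterization:
#' all median total concentrations and phosphorylation rate constants equal 1
#' a.u., `receptor_KD = 1`, and activation resistance tuned by a common scale
#' factor `p_scale` on the dephosphorylation rate constants of levels 2-5
#' (optionally per-level via a length-4 `p_scale`).
#'
#' Variants:
#' \describe{
#'   \item{gradual}{All levels Michaelis; the minimal gradual cascade.}
#'   \item{upstream_feedback}{Gradual cascade; terminal kinase activates the
#'     level-2 phosphatase.}
#'   \item{downstream_feedback}{Gradual cascade; terminal kinase activates its
#'     own phosphatase.}
#'   \item{distributed_switch}{Levels 2-5 mildly ultrasensitive
#'     (Hill, `n = hill_n_distributed`, default 2).}
#'   \item{single_switch}{Levels 1-4 Michaelis, terminal level a steep Hill
#'     switch (`n = hill_n_switch`, default 10).}
#'   \item{basal_feedback}{Single switch plus basal transcriptional feedback
#'     on the level-2 phosphatase; the induced synthesis rate is calibrated so
#'     the median cell's pre-stimulus P2 equals 1 (see
#'     [calibrate_basal_feedback()]).}
#'   \item{feedforward}{Single switch plus a coherent feedforward branch from
#'     receptor occupancy onto the terminal level.}
#' }
#'
#' @param variant Variant name, see Details.
#' @param p_scale Scale of the dephosphorylation rate constants of levels 2-5
#'   (scalar or length 4); tunes the activation resistances.
#' @param receptor_KD Receptor-ligand dissociation constant.
#' @param feedback_strength,feedback_n Feedback gain and cooperativity for the
#'   feedback variants.
#' @param hill_n_distributed Hill coefficient of each level in the distributed
#'   switch.
#' @param hill_n_switch Hill coefficient of the terminal switch.
#' @param feedforward_strength Crosstalk strength of the feedforward branch.
#' @param basal_stimulus,basal_synthesis,degradation Basal transcriptional
#'   feedback parameters (see [transcriptional_feedback_spec()]).
#' @return A [cascade_spec()].
#' @export
cascade_variant <- function(variant = c("gradual", "upstream_feedback",
                                        "downstream_feedback",
                                        "distributed_switch", "single_switch",
                                        "basal_feedback", "feedforward"),
                            p_scale = 1, receptor_KD = 1,
                            feedback_strength = 100, feedback_n = 1,
                            hill_n_distributed = 2, hill_n_switch = 10,
                            feedforward_strength = 100,
                            basal_stimulus = 1e-3 * receptor_KD,
                            basal_synthesis = 0.5, degradation = 1) {
  variant <- match.arg(variant)
  p_scale <- rep_len(p_scale, 4)
  lvl1 <- level_kinetics(1, NA, 1, NA)
  mk <- function(mode, hill_n = 1)
    lapply(1:4, function(i) level_kinetics(1, 1, 1, p_scale[i], mode = mode,
                                           hill_n = hill_n))
  levels <- switch(
    variant,
    gradual = ,
    upstream_feedback = ,
    downstream_feedback = c(list(lvl1), mk("michaelis")),
    distributed_switch = c(list(lvl1), mk("hill", hill_n_distributed)),
    single_switch = ,
    basal_feedback = ,
    feedforward = c(list(lvl1), mk("michaelis")[1:3],
                    list(level_kinetics(1, 1, 1, p_scale[4], mode = "hill",
                                        hill_n = hill_n_switch))))
  fb <- NULL; tfb <- NULL; ff <- NULL
  if (variant == "upstream_feedback")
    fb <- feedback_spec("upstream", feedback_strength, feedback_n)
  if (variant == "downstream_feedback")
    fb <- feedback_spec("downstream", feedback_strength, feedback_n)
  if (variant == "feedforward")
    ff <- feedforward_spec(feedforward_strength, 1)
  spec <- cascade_spec(receptor_KD, levels, feedback = fb, feedforward = ff,
                       variant = variant)
  if (variant == "basal_feedback") {
    tfb <- transcriptional_feedback_spec(basal_synthesis, induced_rate = 1,
                                         degradation = degradation,
                                         basal_stimulus = basal_stimulus)
    spec$transcriptional_feedback <- tfb
    spec <- calibrate_basal_feedback(spec)
  }
  spec
}

#' Calibrate the induced synthesis rate of basal transcriptional feedback
#'
#' Chooses the induced synthesis rate constant so that the median cell
#' (all scale factors 1) has a pre-stimulus phosphatase level P2 = `P2_target`
#' at its basal-state steady state; i.e. solves
#' `basal_synthesis + induced * X5*(S_basal; P2 = P2_target) =
#' degradation * P2_target`. This keeps the basal feedback variant comparable
#' to the feedback-less single switch, whose median P2 is 1.
#'
#' @param spec A `cascade_spec` with transcriptional feedback.
#' @param P2_target Target median pre-stimulus phosphatase level (default 1).
#' @return The spec with `transcriptional_feedback$induced_rate` set.
#' @export
calibrate_basal_feedback <- function(spec, P2_target = 1) {
  tfb <- spec$transcriptional_feedback
  if (is.null(tfb)) stop("spec has no transcriptional feedback")
  if (tfb$degradation * P2_target <= tfb$basal_synthesis)
    stop("basal synthesis alone already exceeds the target P2")
  x5b <- cascade_steady_state(spec, tfb$basal_stimulus,
                              P2_override = P2_target)[5]
  if (x5b <= 0)
    stop("basal terminal-kinase activity underflows to zero; the basal ",
         "stimulus is too far below threshold for feedback calibration ",
         "at this parameterization")
  spec$transcriptional_feedback$induced_rate <-
    (tfb$degradation * P2_target - tfb$basal_synthesis) / x5b
  spec
}

#' Read a cascade model configuration from a YAML file
#'
#' Declarative plain-text configuration of a model variant: a `variant` key
#' naming a preset plus any of the [cascade_variant()] arguments as overrides,
#' e.g.
#' ```yaml
#' variant: single_switch
#' p_scale: 0.3
#' hill_n_switch: 10
#' ```
#'
#' @param path Path to a YAML file.
#' @return A [cascade_spec()].
#' @export
read_cascade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variant)) stop("config must name a variant")
  allowed <- names(formals(cascade_variant))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(cascade_variant, cfg)
}
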