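test_that("level steady state follows the Michaelis and Hill forms", {
  lv <- level_kinetics(kinase_total = 1, phosphatase_total = 1, k = 2, p = 1)
  expect_identical(level_steady_state(0, lv), 0)
  # half-maximal activation when kinase and phosphatase activities balance
  expect_equal(level_steady_state(0.5, lv), 0.5)   # Q = p*P/k = 0.5
  expect_equal(level_steady_state(2, lv), 1 * 2 / (2 + 0.5))  # = 0.8
  expect_error(level_steady_state(-1, lv), "non-negative")

  hl <- level_kinetics(1, 1, 2, 1, mode = "hill", hill_n = 3)
  expect_equal(level_steady_state(0.5, hl), 0.5)  # K defaults to Q
  expect_equal(level_steady_state(1, hl), 1 / (1 + 0.5^3))
  hl0 <- level_kinetics(1, 0, 1, 1, mode = "hill", hill_n = 2)
  expect_error(level_steady_state(0, hl0), "indeterminate")

  # Hill n = 1 with the default threshold is exactly the Michaelis level
  h1 <- level_kinetics(1, 1, 2, 1, mode = "hill", hill_n = 1)
  u <- c(0.01, 0.3, 1, 7)
  expect_equal(level_steady_state(u, h1), level_steady_state(u, lv))
})

test_that("gradual dose-response is exactly Michaelis-Menten with the lumped parameters", {
  set.seed(42)
  for (rep in 1:20) {
    spec <- random_gradual_spec()
    lum <- lumped_parameters(spec)
    S <- 10^runif(5, -3, 3) * spec$receptor_KD
    x5 <- gradual_dose_response(spec, S)[, "X5"]
    expect_equal(x5, lum$X_max5 * S / (S + lum$K_m5), tolerance = 1e-12)
    # half of the maximum is attained at K_m5
    expect_equal(gradual_dose_response(spec, lum$K_m5)$active_concentrations[5],
                 lum$X_max5 / 2, tolerance = 1e-12)
  }
  spec <- cascade_variant("gradual")
  expect_equal(gradual_dose_response(spec, 0)$active_concentrations,
               numeric(5))
  # monotone non-decreasing in S
  S <- 10^seq(-4, 4, length.out = 40)
  expect_true(all(diff(gradual_dose_response(spec, S)[, "X5"]) >= 0))
})

test_that("lumped parameters approach the stated limits", {
  # high resistance everywhere: pathway sensitivity aligns to receptor binding
  hi <- cascade_variant("gradual", p_scale = 1e4)
  expect_equal(lumped_parameters(hi)$K_m5, hi$receptor_KD, tolerance = 1e-3)
  # vanishing resistance: terminal kinase fully activatable
  lo <- cascade_variant("gradual", p_scale = 1e-4)
  expect_equal(lumped_parameters(lo)$X_max5,
               lo$levels[[5]]$kinase_total, tolerance = 1e-3)
  # numeric half-max root agrees with the closed form K_m5
  set.seed(11)
  spec <- random_gradual_spec()
  lum <- lumped_parameters(spec)
  f <- function(S) gradual_dose_response(spec, S)$active_concentrations[5]
  km_num <- 10^uniroot(function(ls) f(10^ls) - lum$X_max5 / 2,
                       log10(lum$K_m5) + c(-3, 3), tol = 1e-12)$root
  expect_equal(km_num, lum$K_m5, tolerance = 1e-3)
})

test_that("weak-stimulus gain is linear in kinases, inverse in phosphatases", {
  set.seed(3)
  spec <- random_gradual_spec()
  g0 <- weak_stimulus_gain(spec)
  expect_equal(g0, with(lumped_parameters(spec), X_max5 / K_m5),
               tolerance = 1e-12)
  for (i in 1:5) {
    sp2 <- spec
    sp2$levels[[i]]$kinase_total <- 2 * sp2$levels[[i]]$kinase_total
    expect_equal(weak_stimulus_gain(sp2), 2 * g0, tolerance = 1e-12)
  }
  for (i in 2:5) {
    sp2 <- spec
    sp2$levels[[i]]$phosphatase_total <- 2 * sp2$levels[[i]]$phosphatase_total
    expect_equal(weak_stimulus_gain(sp2), g0 / 2, tolerance = 1e-12)
  }
  # the gain is the small-S slope of the full dose-response
  S <- 1e-3 * lumped_parameters(spec)$K_m5
  x5 <- gradual_dose_response(spec, S)$active_concentrations[5]
  expect_equal(x5 / S, g0, tolerance = 5e-3)
  bad <- spec; bad$levels[[3]]$phosphatase_total <- 0
  expect_error(weak_stimulus_gain(bad), "zero phosphatase")
})

test_that("cascade_rhs vanishes at the analytic steady state and reduces correctly", {
  set.seed(5)
  for (rep in 1:5) {
    spec <- random_gradual_spec()
    S <- 10^runif(1, -2, 2)
    x <- gradual_dose_response(spec, S)$active_concentrations
    expect_lt(max(abs(cascade_rhs(x, S, spec))), 1e-10)
  }
  # zero-gain feedback gives identical derivatives to the plain cascade
  spec <- cascade_variant("gradual")
  fb0 <- spec; fb0$feedback <- feedback_spec("upstream", strength = 0)
  state <- c(0.4, 0.3, 0.2, 0.5, 0.1)
  expect_identical(cascade_rhs(state, 1, fb0), cascade_rhs(state, 1, spec))
  # negative feedback sign: raising X5 lowers dX2/dt
  fb <- fb0; fb$feedback$strength <- 10
  d_lo <- cascade_rhs(state, 1, fb)[2]
  state_hi <- state; state_hi[5] <- 0.9
  expect_lt(cascade_rhs(state_hi, 1, fb)[2], d_lo)
  expect_error(cascade_rhs(state[1:4], 1, spec), "dimension")
})

test_that("feedback steepness: 81-fold without feedback, ~422-fold with non-cooperative feedback", {
  expect_equal(root_mm_fold_change(0), 81)
  expect_equal(root_mm_fold_change(1), (0.81 / 0.19) * (0.99 / 0.01))
  expect_equal(root_mm_fold_change(1), 422.05, tolerance = 1e-4)
  # the numeric inversion of the asymptotic curve reproduces both
  fb <- cascade_variant("upstream_feedback", feedback_strength = 1e4)
  expect_equal(stimulus_fold_change(function(S)
    as.numeric(strong_feedback_steady_state(fb, S))), 422.05,
    tolerance = 1e-3)
  gr <- cascade_variant("gradual")
  expect_equal(stimulus_fold_change(function(S)
    gradual_dose_response(gr, S)$active_concentrations[5]), 81,
    tolerance = 1e-3)
})

test_that("strong-feedback asymptotics match the numeric fixed point and are concentration-invariant", {
  # very strong upstream feedback: asymptotic form within 5% across the range
  fb <- cascade_variant("upstream_feedback", feedback_strength = 1e9,
                        feedback_n = 2)
  for (S in 10^seq(-2, 2, length.out = 7)) {
    num <- cascade_steady_state(fb, S)[5]
    asy <- as.numeric(strong_feedback_steady_state(fb, S))
    expect_equal(num, asy, tolerance = 0.05)
  }
  # half-maximal stimulus proportional to K_D and independent of all totals
  K0 <- attr(strong_feedback_steady_state(fb, 1), "K_half")
  expect_equal(K0, fb$receptor_KD / (2^3 - 1))
  scaled <- fb
  set.seed(9)
  for (i in 1:5) scaled$levels[[i]]$kinase_total <- runif(1, 0.1, 10)
  for (i in 2:5) scaled$levels[[i]]$phosphatase_total <- runif(1, 0.1, 10)
  expect_equal(attr(strong_feedback_steady_state(scaled, 1), "K_half"), K0)
  # downstream feedback: half-saturation proportional to the level-4 K_m
  dn <- cascade_variant("downstream_feedback", feedback_strength = 1e9,
                        feedback_n = 1)
  dn4 <- dn; dn4$feedback <- NULL
  expect_equal(attr(strong_feedback_steady_state(dn, 1), "K_half"),
               lumped_parameters(dn4)$K_m[4] / (2^2 - 1))
  expect_error(strong_feedback_steady_state(cascade_variant("gradual"), 1),
               "no feedback")
})

test_that("hill cascades reduce to and amplify the gradual forms as expected", {
  # all-Hill cascade with n = 1 and default thresholds equals the gradual one
  spec <- cascade_variant("distributed_switch", hill_n_distributed = 1,
                          p_scale = 0.5)
  grad <- cascade_variant("gradual", p_scale = 0.5)
  for (S in c(0.01, 0.3, 2, 50))
    expect_equal(cascade_steady_state(spec, S),
                 gradual_dose_response(grad, S)$active_concentrations,
                 tolerance = 1e-12)
  # distributed mild switches: the composite curve is steeper than any level
  dsw <- cascade_variant("distributed_switch", p_scale = 0.01)
  composite <- stimulus_fold_change(function(S) cascade_steady_state(dsw, S)[5])
  single_level <- stimulus_fold_change(function(u) {
    lv <- dsw$levels[[2]]
    K <- lv$p * lv$phosphatase_total / lv$k
    u^2 / (u^2 + K^2)
  })
  expect_lt(composite, single_level)
  expect_equal(single_level, 9, tolerance = 1e-3)  # Hill n=2: 10-90 ratio 9
})

test_that("the single switch fires only when the upstream plateau clears the threshold", {
  # responder: X_max,4 above the level-5 threshold
  lo <- cascade_variant("single_switch", p_scale = 0.3)
  lum <- lumped_parameters(local({s <- lo; s$levels[[5]] <- level_kinetics(1, 1, 1, 0.3); s}))
  K5 <- 0.3  # p_scale * P5 / k5
  expect_gt(lum$X_max[4], K5)
  expect_gt(cascade_steady_state(lo, 1e4)[5], 0.5)
  # non-responder: plateau below threshold keeps X5 under half-maximum
  hi <- cascade_variant("single_switch", p_scale = 2)
  lum_hi <- lumped_parameters(local({s <- hi; s$levels[[5]] <- level_kinetics(1, 1, 1, 2); s}))
  expect_lt(lum_hi$X_max[4], 2)
  expect_lt(max(vapply(10^seq(-4, 6, length.out = 30),
                       function(S) cascade_steady_state(hi, S)[5],
                       numeric(1))), 0.5)
})

test_that("the two-level Hill threshold has the n-th-root concentration dependence", {
  two_hill <- function(P2, n = 4) {
    lv1 <- level_kinetics(1, NA, 1, NA, mode = "hill", hill_n = n,
                          hill_K = 1)
    lv2 <- level_kinetics(1, P2, 1, 0.005, mode = "hill", hill_n = n)
    cascade_spec(1, c(list(lv1), list(lv2),
                      lapply(3:5, function(i) level_kinetics(1, 1, 1, 1e-4,
                                                             mode = "hill",
                                                             hill_n = n))))
  }
  n <- 4
  thr1 <- distributed_threshold(two_hill(1, n))
  thr2 <- distributed_threshold(two_hill(2, n))
  expect_equal(thr2 / thr1, 2^(1 / n), tolerance = 0.01)
  # monotone increasing in the phosphatase total
  thrs <- vapply(c(0.5, 1, 2, 4, 8), function(P)
    distributed_threshold(two_hill(P, n)), numeric(1))
  expect_true(all(diff(thrs) > 0))
  # matches the numeric half-max of the iterated two-level system (rho2 small)
  spec <- two_hill(1, n)
  x2 <- function(S) {
    u1 <- cascadevar:::receptor_activity(spec, S)
    level_steady_state(u1, spec$levels[[2]])
  }
  plateau <- x2(1e6)
  km <- 10^uniroot(function(ls) x2(10^ls) - plateau / 2, c(-6, 6),
                   tol = 1e-12)$root
  expect_equal(thr1, km, tolerance = 0.1)
  # non-responder: threshold above the level-1 plateau
  expect_error(distributed_threshold(two_hill(300, n)), "non-responder")
})

test_that("feedforward regulation reduces to the single switch at zero gain and sharpens below threshold", {
  base <- cascade_variant("single_switch", p_scale = 2)
  ff0 <- base; ff0$feedforward <- feedforward_spec(strength = 0)
  for (S in c(0.05, 0.5, 5))
    expect_equal(cascade_steady_state(ff0, S), cascade_steady_state(base, S),
                 tolerance = 1e-12)
  # closed-form threshold matches the numeric half-max (high rho, strong branch)
  ff <- cascade_variant("feedforward", p_scale = 2,
                        feedforward_strength = 1e4)
  thr <- feedforward_threshold(ff)
  f <- function(S) cascade_steady_state(ff, S)[5]
  plateau <- f(1e4)
  km <- 10^uniroot(function(ls) f(10^ls) - plateau / 2, c(-10, 4),
                   tol = 1e-12)$root
  expect_equal(thr, km, tolerance = 0.1)
  # below threshold the log-log slope doubles relative to the branch-less model
  S_lo <- thr * c(0.01, 0.02)
  slope_ff <- diff(log(vapply(S_lo, f, numeric(1)))) / diff(log(S_lo))
  fb <- function(S) cascade_steady_state(base, S)[5]
  slope_base <- diff(log(vapply(S_lo, fb, numeric(1)))) / diff(log(S_lo))
  expect_gt(slope_ff, slope_base + 5)  # Hill n=10: slopes ~20 vs ~10
})

test_that("basal transcriptional feedback reduces to the frozen single switch when uninduced", {
  bf <- cascade_variant("basal_feedback", p_scale = 0.3)
  bf$transcriptional_feedback$induced_rate <- 0
  # with no induction the pre-stimulus P2 is basal/degradation
  pre <- cascadevar:::presolve_basal_phosphatase(bf)
  expect_equal(pre$P2, 0.5)
  expect_lt(pre$residual, 1e-9)
  sw <- cascade_variant("single_switch", p_scale = 0.3)
  sw$levels[[2]]$phosphatase_total <- 0.5
  curve_bf <- dose_response(bf, n_grid = 20)
  for (i in seq_len(nrow(curve_bf)))
    expect_equal(curve_bf$response[i],
                 cascade_steady_state(sw, curve_bf$S[i])[5],
                 tolerance = 1e-9)
})

test_that("every steady state stays within physical bounds", {
  set.seed(21)
  variants <- list(
    cascade_variant("gradual", p_scale = 0.2),
    cascade_variant("upstream_feedback", p_scale = 0.2),
    cascade_variant("downstream_feedback", p_scale = 3),
    cascade_variant("distributed_switch", p_scale = 0.05),
    cascade_variant("single_switch", p_scale = 0.5),
    cascade_variant("feedforward", p_scale = 0.5))
  for (spec in variants) {
    totals <- vapply(spec$levels, function(l) l$kinase_total, numeric(1))
    for (S in 10^seq(-4, 4, length.out = 9)) {
      x <- cascade_steady_state(spec, S)
      expect_true(all(x >= 0 & x <= totals + 1e-12))
    }
  }
})

test_that("model variants are declarable in a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("variant: single_switch", "p_scale: 0.3",
               "hill_n_switch: 8"), path)
  spec <- read_cascade_config(path)
  expect_identical(spec$variant, "single_switch")
  expect_equal(spec$levels[[5]]$hill_n, 8)
  expect_equal(spec$levels[[2]]$p, 0.3)
  writeLines(c("variant: gradual", "nonsense: 1"), path)
  expect_error(read_cascade_config(path), "unknown config keys")
})
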