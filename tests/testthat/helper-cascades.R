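# Shared fixtures: all built in code.

# A random feedback-less gradual cascade with totals and rate constants drawn
# over about two orders of magnitude.
random_gradual_spec <- function() {
  lv1 <- level_kinetics(runif(1, 0.2, 5), NA, runif(1, 0.2, 5), NA)
  lvs <- lapply(2:5, function(i)
    level_kinetics(runif(1, 0.2, 5), runif(1, 0.2, 5),
                   runif(1, 0.2, 5), runif(1, 0.2, 5)))
  cascade_spec(receptor_KD = runif(1, 0.2, 5), levels = c(list(lv1), lvs),
               variant = "random-gradual")
}

# Small fixed population reused across comparison tests.
test_population <- function(n = 300, seed = 7, ...) {
  sample_population(population_spec(n_cells = n, seed = seed, ...))
}

# A hand-rolled dose-response curve around a known closed form, carrying the
# attributes summarize_response() expects.
analytic_curve <- function(f, spec, S_grid = 10^seq(-4, 4, length.out = 50)) {
  structure(data.frame(S = S_grid, response = vapply(S_grid, f, numeric(1))),
            basal_response = f(0), basal_S = 0, evaluator = f, spec = spec,
            class = c("dose_response_curve", "data.frame"))
}

# Exact Jacobian of the feedback-less gradual cascade, derived by hand from
# the rate equations: bidiagonal lower-triangular.
exact_gradual_jacobian <- function(spec, S, x) {
  lv <- spec$levels
  J <- matrix(0, 5, 5)
  J[1, 1] <- -lv[[1]]$k * (S + spec$receptor_KD)
  for (i in 2:5) {
    J[i, i] <- -(lv[[i]]$k * x[i - 1] +
                   lv[[i]]$p * lv[[i]]$phosphatase_total)
    J[i, i - 1] <- lv[[i]]$k * (lv[[i]]$kinase_total - x[i])
  }
  J
}
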