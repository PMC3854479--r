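#' The nine fluctuating signaling species
#'
#' Column order used throughout: kinases `K1..K5`, phosphatases `P2..P5`.
#' @return Character vector of the 9 species identifiers.
#' @export
cascade_species <- function() c(paste0("K", 1:5), paste0("P", 2:5))

#' Specification of a synthetic cell population
#'
#' Per-cell total protein concentrations are modeled as the median values of
#' a [cascade_spec()] multiplied by scale factors sampled from independent
#' log-normal distributions with log-mean 0 (median 1) and log-standard
#' deviation `log_sd` (default 0.35, matching the cell-to-cell spread of
#' eukaryotic protein expression). Selected kinase-phosphatase pairs can be
#' forced perfectly correlated (proportional: they share one random draw),
#' and selected species can have their expression noise eliminated (fixed at
#' the median).
#'
#' @param n_cells Number of cells (default 1000).
#' @param log_sd Standard deviation of log concentration (>= 0).
#' @param seed Integer seed; the same seed reproduces the same population and
#'   is meant to be reused across model variants.
#' @param correlated_pairs List of 2-element character vectors from
#'   [cascade_species()], each pair forced proportional.
#' @param fixed_species Character vector of species held at their median.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 1000, log_sd = 0.35, seed = 1,
                            correlated_pairs = list(),
                            fixed_species = character()) {
  stopifnot(n_cells >= 1, log_sd >= 0)
  species <- cascade_species()
  stopifnot(all(fixed_species %in% species))
  for (pr in correlated_pairs) {
    if (length(pr) != 2 || !all(pr %in% species))
      stop("correlated_pairs must be pairs of species identifiers")
    if (any(pr %in% fixed_species))
      stop("a species cannot be both fixed and correlated")
  }
  if (anyDuplicated(unlist(correlated_pairs)))
    stop("a species may appear in at most one correlated pair")
  structure(list(n_cells = as.integer(n_cells), log_sd = log_sd,
                 seed = as.integer(seed),
                 correlated_pairs = correlated_pairs,
                 fixed_species = fixed_species),
            class = "population_spec")
}

#' Sample a synthetic cell population
#'
#' Draws the `n_cells` x 9 matrix of positive scale factors described by a
#' [population_spec()]: each column i.i.d. log-normal with log-mean 0 and
#' log-sd `log_sd`, after which correlated pairs share the first member's
#' draw and fixed species are set to 1. Sampling is seeded, so two calls with
#' the same spec are bit-identical, and correlation/fixing settings do not
#' perturb the draws of unaffected species.
#'
#' @param spec A [population_spec()], or arguments forwarded to it.
#' @param ... Passed to [population_spec()] when `spec` is not one already.
#' @return An object of class `cell_population`: list with `scale_factors`
#'   (matrix, columns [cascade_species()]), `seed`, `spec`.
#' @export
sample_population <- function(spec = population_spec(), ...) {
  if (!inherits(spec, "population_spec"))
    spec <- population_spec(spec, ...)
  species <- cascade_species()
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  m <- matrix(rlnorm(spec$n_cells * 9L, meanlog = 0, sdlog = spec$log_sd),
              nrow = spec$n_cells, ncol = 9L,
              dimnames = list(NULL, species))
  for (pr in spec$correlated_pairs) m[, pr[2]] <- m[, pr[1]]
  for (sp in spec$fixed_species) m[, sp] <- 1
  structure(list(scale_factors = m, seed = spec$seed, spec = spec),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells, log-sd %g, seed %d\n",
              nrow(x$scale_factors), x$spec$log_sd, x$seed))
  if (length(x$spec$correlated_pairs))
    cat("  correlated:",
        paste(vapply(x$spec$correlated_pairs, paste, "", collapse = "~"),
              collapse = ", "), "\n")
  if (length(x$spec$fixed_species))
    cat("  fixed:", paste(x$spec$fixed_species, collapse = ", "), "\n")
  invisible(x)
}

#' Apply one cell's scale factors to a cascade specification
#'
#' Returns a per-cell [cascade_spec()] in which the five kinase totals and
#' four phosphatase totals are the base spec's (median) values multiplied by
#' the cell's scale factors. Kinetic rate constants, the receptor dissociation
#' constant, and regulatory parameters are untouched: every cell shares the
#' same kinetics and differs only in protein abundances.
#'
#' @param spec The base (median-cell) [cascade_spec()].
#' @param scales Named numeric vector of 9 scale factors (names
#'   [cascade_species()]), e.g. one row of a `cell_population`.
#' @return A [cascade_spec()] for this cell.
#' @export
apply_to_spec <- function(spec, scales) {
  stopifnot(all(cascade_species() %in% names(scales)))
  for (i in 1:5)
    spec$levels[[i]]$kinase_total <-
      spec$levels[[i]]$kinase_total * scales[[paste0("K", i)]]
  for (i in 2:5)
    spec$levels[[i]]$phosphatase_total <-
      spec$levels[[i]]$phosphatase_total * scales[[paste0("P", i)]]
  spec
}

#' Write / read a cell population as CSV
#'
#' One row per cell, one column per species (header `K1..K5,P2..P5`), values
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param population A `cell_population`.
#' @param path Output (input) CSV path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns the scale-factor matrix.
#' @export
write_population <- function(population, path) {
  m <- population$scale_factors
  df <- as.data.frame(apply(m, 2, function(col) sprintf("%.17g", col)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  stopifnot(identical(colnames(df), cascade_species()))
  m <- vapply(df, as.numeric, numeric(nrow(df)))
  dimnames(m) <- list(NULL, cascade_species())
  m
}
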