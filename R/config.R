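#' Primer-constraint and fitness configuration
#'
#' Bundles every tunable bound, threshold and weight used by the constraint
#' evaluators and the weighted fitness.  Defaults follow the published
#' operating point for PCR with confronting two-pair primers: primer length
#' 16--28 bp, GC proportion 20--80%, melting temperature 45--62 degC with
#' pairwise differences of at most 1 degC, product lengths above 100 bp in
#' electrophoresis ratios 8 : 13 : 20, and fitness weights 3 / 10 / 50 /
#' 60 / 100.
#'
#' @param len_min,len_max Primer length bounds (bases).
#' @param len_diff_max Maximal tolerated primer-pair length difference (bases).
#' @param gc_low,gc_high Inclusive GC proportion bounds (percent).
#' @param tm_low,tm_high Inclusive melting-temperature bounds (degC).
#' @param tm_diff_max Maximal pairwise melting-temperature difference (degC).
#' @param product_min Product-length floor (bases); products must exceed it.
#' @param na_molar Monovalent salt concentration (mol/L) for the
#'   salt-adjusted melting-temperature formula.
#' @param ratios Target product-length ratios `c(ratio1, ratio2, ratio3)`
#'   for the two allele-specific products and the outer product.
#' @param ratio_tolerance Relative half-width within which a product length
#'   is considered to correspond to its ratio.
#' @param dimer_stem_min Complementary run length (bases) flagged as a dimer
#'   anywhere in an antiparallel alignment.
#' @param dimer_3p_min Complementary run length flagged as a dimer when the
#'   run includes either primer's 3'-terminal base.
#' @param hairpin_stem_min,hairpin_loop_min Minimal stem and loop lengths
#'   (bases) of the hairpin screen.
#' @param weights Named numeric vector of the five fitness weights:
#'   `composition` (length difference, GC proportion, GC clamp),
#'   `structure` (dimer, hairpin, specificity), `tm` (Tm range and pairwise
#'   difference), `product` (product-length checks), and `tm_balance`
#'   (average Tm difference, a continuous penalty).
#' @param tm_epsilon Average Tm differences at or below this value (degC)
#'   contribute nothing to the fitness, so exact-equality convergence is not
#'   blocked by floating-point noise.
#' @param extra_snp_strict If `TRUE` (default) chromosomes whose inner
#'   primer windows cover additional polymorphic sites are rejected as well
#'   as the outer ones; set `FALSE` to restrict the exclusion to the outer
#'   primers.
#' @param pl1_range,pl2_range Optional explicit `c(lo, hi)` ranges for the
#'   two product genes, used to restrict the search space (mainly for
#'   small-instance validation against exhaustive search).
#' @return A list of class `ctpp_constraints`.
#' @export
constraint_config <- function(len_min = 16L, len_max = 28L,
                              len_diff_max = 3L,
                              gc_low = 20, gc_high = 80,
                              tm_low = 45, tm_high = 62,
                              tm_diff_max = 1,
                              product_min = 100L,
                              na_molar = 0.05,
                              ratios = c(8, 13, 20),
                              ratio_tolerance = 0.25,
                              dimer_stem_min = 5L,
                              dimer_3p_min = 3L,
                              hairpin_stem_min = 4L,
                              hairpin_loop_min = 3L,
                              weights = c(composition = 3, structure = 10,
                                          tm = 50, product = 60,
                                          tm_balance = 100),
                              tm_epsilon = 1e-9,
                              extra_snp_strict = TRUE,
                              pl1_range = NULL, pl2_range = NULL) {
  stopifnot(len_min >= 1, len_max >= len_min,
            gc_low < gc_high, tm_low < tm_high,
            len_diff_max >= 0, tm_diff_max > 0,
            product_min >= 1, na_molar > 0,
            length(ratios) == 3L, all(ratios > 0),
            ratio_tolerance > 0,
            dimer_stem_min >= 1, dimer_3p_min >= 1,
            hairpin_stem_min >= 1, hairpin_loop_min >= 0,
            tm_epsilon >= 0)
  wnames <- c("composition", "structure", "tm", "product", "tm_balance")
  if (is.null(names(weights))) names(weights) <- wnames
  if (!all(wnames %in% names(weights)) || any(weights < 0))
    stop("weights must be non-negative and named ",
         paste(wnames, collapse = ", "), call. = FALSE)
  for (r in list(pl1_range, pl2_range))
    if (!is.null(r)) stopifnot(length(r) == 2L, r[1L] <= r[2L])
  structure(list(
    len_min = as.integer(len_min), len_max = as.integer(len_max),
    len_diff_max = as.integer(len_diff_max),
    gc_low = gc_low, gc_high = gc_high,
    tm_low = tm_low, tm_high = tm_high,
    tm_diff_max = tm_diff_max,
    product_min = as.integer(product_min),
    na_molar = na_molar,
    ratios = as.numeric(ratios),
    ratio_tolerance = ratio_tolerance,
    dimer_stem_min = as.integer(dimer_stem_min),
    dimer_3p_min = as.integer(dimer_3p_min),
    hairpin_stem_min = as.integer(hairpin_stem_min),
    hairpin_loop_min = as.integer(hairpin_loop_min),
    weights = weights[wnames],
    tm_epsilon = tm_epsilon,
    extra_snp_strict = isTRUE(extra_snp_strict),
    pl1_range = if (is.null(pl1_range)) NULL else as.integer(pl1_range),
    pl2_range = if (is.null(pl2_range)) NULL else as.integer(pl2_range)
  ), class = "ctpp_constraints")
}

#' Genetic-algorithm configuration
#'
#' Defaults follow DeJong-and-Spears-style settings: population 50, up to
#' 1000 generations, crossover probability 0.6 and mutation probability
#' 0.001 (applied per offspring, since the chromosome has six integer genes
#' rather than a bit string).  A population of 1000 is the published
#' higher-accuracy variant.
#'
#' @param population_size Number of chromosomes kept each generation.
#' @param max_generations Iteration cap; each generation breeds one pair.
#' @param crossover_prob Probability that a selected pair is recombined.
#' @param mutation_prob Probability that an offspring undergoes one-point
#'   mutation.
#' @param seed Optional integer seed; fixing it makes a run bit-reproducible.
#' @param repair_budget Attempts allowed when regenerating an infeasible
#'   mutation before the operation is abandoned.
#' @return A list of class `ctpp_ga_config`.
#' @export
ga_config <- function(population_size = 50L, max_generations = 1000L,
                      crossover_prob = 0.6, mutation_prob = 0.001,
                      seed = NULL, repair_budget = 100L) {
  stopifnot(population_size >= 2, max_generations >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            repair_budget >= 1)
  structure(list(
    population_size = as.integer(population_size),
    max_generations = as.integer(max_generations),
    crossover_prob = crossover_prob,
    mutation_prob = mutation_prob,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    repair_budget = as.integer(repair_budget)
  ), class = "ctpp_ga_config")
}
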