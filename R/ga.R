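.gene_names <- c("Fl1", "Pl1", "Rl1", "Fl2", "Pl2", "Rl2")

# sampling ranges for the six genes on a template: primer genes draw from
# [len_min, len_max], product genes from [product_min, delta] intersected
# with any explicit range restriction
.gene_ranges <- function(template, cfg) {
  b <- feasible_bounds(template, cfg)
  clip <- function(user, hi) {
    lo <- cfg$product_min
    if (!is.null(user)) { lo <- max(lo, user[1L]); hi <- min(hi, user[2L]) }
    if (lo > hi) stop("empty product-length range", call. = FALSE)
    c(lo, hi)
  }
  p1 <- clip(cfg$pl1_range, b[["delta1"]])
  p2 <- clip(cfg$pl2_range, b[["delta2"]])
  list(lo = c(cfg$len_min, p1[1L], cfg$len_min, cfg$len_min, p2[1L],
              cfg$len_min),
       hi = c(cfg$len_max, p1[2L], cfg$len_max, cfg$len_max, p2[2L],
              cfg$len_max))
}

#' Random initial population of feasible chromosomes
#'
#' Primer-length genes are drawn uniformly from `[len_min, len_max]` and
#' product genes from `[product_min, delta]`; draws violating hard
#' feasibility (template fit, strict outer-primer placement, extra-SNP
#' exclusion) or duplicating an existing member are regenerated.  Every
#' member is evaluated once and cached.
#'
#' @param template A `ctpp_template`.
#' @param cfg A [constraint_config()].
#' @param ga A [ga_config()].
#' @return An object of class `ctpp_population`: list with `vectors`
#'   (matrix, one chromosome per row), `totals`, `breakdowns`, and
#'   `generation = 0`.
#' @export
initialize_population <- function(template, cfg = constraint_config(),
                                  ga = ga_config()) {
  rng <- .gene_ranges(template, cfg)
  n <- ga$population_size
  vectors <- matrix(NA_integer_, n, 6L, dimnames = list(NULL, .gene_names))
  keys <- character(0L)
  filled <- 0L
  budget <- 1000L * n
  attempts <- 0L
  while (filled < n) {
    attempts <- attempts + 1L
    if (attempts > budget)
      stop("could not fill the population with distinct feasible ",
           "chromosomes (feasible space too small?)", call. = FALSE)
    v <- vapply(1:6, function(g) .runif_int(rng$lo[g], rng$hi[g]),
                integer(1L))
    if (!isTRUE(vector_feasible(template, v, cfg))) next
    key <- paste(v, collapse = ",")
    if (key %in% keys) next
    filled <- filled + 1L
    vectors[filled, ] <- v
    keys <- c(keys, key)
  }
  breakdowns <- lapply(seq_len(n), function(i)
    evaluate_vector(template, vectors[i, ], cfg))
  structure(list(
    vectors = vectors,
    totals = vapply(breakdowns, `[[`, numeric(1L), "total"),
    breakdowns = breakdowns,
    generation = 0L
  ), class = "ctpp_population")
}

#' @export
print.ctpp_population <- function(x, ...) {
  cat(sprintf("CTPP population: %d chromosomes, generation %d, best %.4f\n",
              nrow(x$vectors), x$generation, min(x$totals)))
  invisible(x)
}

#' Select two distinct parents uniformly at random
#'
#' @param pop A `ctpp_population`.
#' @return Integer vector of two distinct member indices.
#' @export
select_pair <- function(pop) {
  sample.int(nrow(pop$vectors), 2L)
}

#' Uniform crossover with a six-bit mask
#'
#' Positions where the mask is 1 are exchanged between the parents.  When
#' a template is supplied the offspring are checked for hard feasibility;
#' while either child is infeasible the exchanged positions are restored
#' (in gene order, jointly on both children, so the position-wise multiset
#' of parental genes is preserved).  Restoring every exchange recovers the
#' parents, so repair always terminates.
#'
#' @param a,b Parent chromosomes (numeric vectors of six genes).
#' @param template Optional `ctpp_template` enabling feasibility repair.
#' @param cfg A [constraint_config()].
#' @param mask Optional six-element 0/1 vector; drawn uniformly when `NULL`.
#' @return List with children `a`, `b` and the `mask` used.
#' @export
uniform_crossover <- function(a, b, template = NULL,
                              cfg = constraint_config(), mask = NULL) {
  stopifnot(length(a) == 6L, length(b) == 6L)
  a <- as.integer(round(a)); b <- as.integer(round(b))
  if (is.null(mask)) mask <- sample.int(2L, 6L, replace = TRUE) - 1L
  mask <- as.integer(mask)
  stopifnot(length(mask) == 6L, all(mask %in% 0:1))
  sw <- mask == 1L
  ca <- a; cb <- b
  ca[sw] <- b[sw]
  cb[sw] <- a[sw]
  if (!is.null(template)) {
    pos <- which(sw)
    k <- 0L
    while ((!isTRUE(vector_feasible(template, ca, cfg)) ||
            !isTRUE(vector_feasible(template, cb, cfg))) &&
           k < length(pos)) {
      k <- k + 1L
      ca[pos[k]] <- a[pos[k]]
      cb[pos[k]] <- b[pos[k]]
    }
  }
  list(a = ca, b = cb, mask = mask)
}

#' One-point mutation of a chromosome
#'
#' A uniformly chosen gene is regenerated within its legal range (primer
#' genes in `[len_min, len_max]`, product genes in `[product_min, delta]`),
#' always to a value different from the current one.  If the mutated
#' chromosome violates hard feasibility, a new point is selected and the
#' value regenerated; after `ga$repair_budget` failed attempts the
#' operation is abandoned and the chromosome returned unchanged, with a
#' warning.
#'
#' @param v Chromosome vector of six genes.
#' @param template A `ctpp_template`.
#' @param cfg A [constraint_config()].
#' @param ga A [ga_config()] (supplies the repair budget).
#' @param point,value Optional fixed mutation point (1--6) and replacement
#'   value, used to reproduce a specific mutation; an infeasible fixed
#'   mutation is an error.
#' @return The mutated chromosome (integer vector of six genes).
#' @export
one_point_mutation <- function(v, template, cfg = constraint_config(),
                               ga = ga_config(), point = NULL,
                               value = NULL) {
  stopifnot(length(v) == 6L)
  v <- as.integer(round(v))
  rng <- .gene_ranges(template, cfg)
  if (!is.null(point)) {
    point <- as.integer(point)
    stopifnot(point >= 1L, point <= 6L)
    cand <- v
    cand[point] <- as.integer(value %||%
                                .runif_int(rng$lo[point], rng$hi[point]))
    if (!isTRUE(vector_feasible(template, cand, cfg)))
      stop("requested mutation violates feasibility: ",
           vector_feasible(template, cand, cfg), call. = FALSE)
    return(cand)
  }
  for (att in seq_len(ga$repair_budget)) {
    pt <- sample.int(6L, 1L)
    choices <- setdiff(seq.int(rng$lo[pt], rng$hi[pt]), v[pt])
    if (length(choices) == 0L) next
    cand <- v
    cand[pt] <- choices[sample.int(length(choices), 1L)]
    if (isTRUE(vector_feasible(template, cand, cfg))) return(cand)
  }
  warning("mutation abandoned after ", ga$repair_budget,
          " attempts; chromosome unchanged", call. = FALSE)
  v
}

#' Replace the two worst population members with offspring
#'
#' The two maximal-fitness members are removed (ties broken by position:
#' earlier members are replaced first) and the two children inserted in
#' their places; the population size is unchanged and the best member
#' always survives for populations of three or more.
#'
#' @param pop A `ctpp_population`.
#' @param children List of two chromosome vectors.
#' @param fits List of two `ctpp_fitness` breakdowns for the children.
#' @return The updated `ctpp_population` (generation incremented).
#' @export
replace_worst_two <- function(pop, children, fits) {
  stopifnot(length(children) == 2L, length(fits) == 2L)
  worst <- order(-pop$totals)[1:2]
  for (k in 1:2) {
    i <- worst[k]
    pop$vectors[i, ] <- as.integer(children[[k]])
    pop$breakdowns[[i]] <- fits[[k]]
    pop$totals[i] <- fits[[k]]$total
  }
  pop$generation <- pop$generation + 1L
  pop
}

#' Run the genetic algorithm on a template
#'
#' Steady-state loop: each generation selects two distinct parents
#' uniformly, recombines them by masked uniform crossover with probability
#' `crossover_prob` (otherwise the parents are copied), applies one-point
#' mutation to each offspring with probability `mutation_prob`, and
#' replaces the two worst members.  Terminates when the best fitness
#' reaches zero or after `max_generations` generations.  With a fixed
#' `ga$seed` the run is bit-reproducible.
#'
#' @param template A `ctpp_template`.
#' @param cfg A [constraint_config()].
#' @param ga A [ga_config()].
#' @param keep_trace Record the per-generation best and mean fitness.
#' @return An object of class `ctpp_ga_result`: `best_vector`, the
#'   realized `primer_set`, its `fitness` breakdown, the `trace` data
#'   frame (`generation`, `best`, `mean`), `generations` actually run,
#'   `converged` (best fitness reached zero), the final `population`, and
#'   the `seed`.
#' @export
run_ga <- function(template, cfg = constraint_config(), ga = ga_config(),
                   keep_trace = TRUE) {
  if (!is.null(ga$seed)) set.seed(ga$seed)
  pop <- initialize_population(template, cfg, ga)
  tr_gen <- 0L
  tr_best <- min(pop$totals)
  tr_mean <- mean(pop$totals)
  gen <- 0L
  while (min(pop$totals) > 0 && gen < ga$max_generations) {
    gen <- gen + 1L
    idx <- select_pair(pop)
    a <- pop$vectors[idx[1L], ]
    b <- pop$vectors[idx[2L], ]
    if (runif(1L) < ga$crossover_prob) {
      cx <- uniform_crossover(a, b, template, cfg)
      ca <- cx$a; cb <- cx$b
    } else {
      ca <- a; cb <- b
    }
    if (runif(1L) < ga$mutation_prob)
      ca <- one_point_mutation(ca, template, cfg, ga)
    if (runif(1L) < ga$mutation_prob)
      cb <- one_point_mutation(cb, template, cfg, ga)
    # reuse cached parental fitness for unchanged offspring
    eval_child <- function(child) {
      if (identical(unname(child), unname(a)))
        return(pop$breakdowns[[idx[1L]]])
      if (identical(unname(child), unname(b)))
        return(pop$breakdowns[[idx[2L]]])
      evaluate_vector(template, child, cfg)
    }
    fa <- eval_child(ca)
    fb <- eval_child(cb)
    pop <- replace_worst_two(pop, list(ca, cb), list(fa, fb))
    if (keep_trace) {
      tr_gen <- c(tr_gen, gen)
      tr_best <- c(tr_best, min(pop$totals))
      tr_mean <- c(tr_mean, mean(pop$totals))
    }
  }
  best_i <- which.min(pop$totals)
  best_v <- pop$vectors[best_i, ]
  structure(list(
    best_vector = best_v,
    primer_set = realize_primer_set(template, best_v, cfg),
    fitness = pop$breakdowns[[best_i]],
    trace = if (keep_trace)
      data.frame(generation = tr_gen, best = tr_best, mean = tr_mean),
    generations = gen,
    converged = min(pop$totals) <= 0,
    population = pop,
    seed = ga$seed
  ), class = "ctpp_ga_result")
}

#' @export
print.ctpp_ga_result <- function(x, ...) {
  cat(sprintf(
    "GA result: best fitness %.4f after %d generation(s)%s\n",
    x$fitness$total, x$generations,
    if (x$converged) " (converged to zero)" else ""))
  print(x$primer_set)
  invisible(x)
}
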