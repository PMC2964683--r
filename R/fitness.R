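#' GC proportion of a primer
#'
#' @param p Primer string (A/C/G/T only).
#' @return Percent of G and C bases, on the 0--100 scale.
#' @examples
#' gc_percent("GATTATTAGTAGTTTCTGCA")  # 30
#' @export
gc_percent <- function(p) {
  stopifnot(is.character(p), length(p) == 1L)
  if (!nzchar(p)) stop("empty primer string", call. = FALSE)
  enc <- .encode_dna(toupper(p))
  100 * sum(enc == 2L | enc == 3L) / length(enc)
}

#' Salt-adjusted (Bolton-McCarthy) melting temperature
#'
#' `Tm = 81.5 + 16.6 log10[Na+] + 0.41 GC% - 675 / |P|`, with GC% on the
#' 0--100 scale.  Strictly increasing in GC proportion, primer length and
#' salt concentration.
#'
#' @param p Primer string (A/C/G/T only).
#' @param na_molar Monovalent salt concentration in mol/L.
#' @return Melting temperature in degC.
#' @examples
#' tm_bm(strrep("GA", 10), na_molar = 1)  # 68.25
#' @export
tm_bm <- function(p, na_molar = 0.05) {
  if (na_molar <= 0) stop("salt concentration must be positive", call. = FALSE)
  81.5 + 16.6 * log10(na_molar) + 0.41 * gc_percent(p) - 675 / nchar(p)
}

.set_primers <- function(set) {
  stopifnot(inherits(set, "ctpp_primer_set"))
  c(pf1 = set$pf1, pr1 = set$pr1, pf2 = set$pf2, pr2 = set$pr2)
}

#' Primer length-difference defect (0--3)
#'
#' One check per primer pairing Fl1/Rl1, Fl2/Rl2 and Fl1/Rl2; a check is
#' satisfied when the absolute length difference is at most
#' `cfg$len_diff_max` (default 3 bases).  The defect is the number of
#' failed checks.
#'
#' @param v Chromosome vector `(Fl1, Pl1, Rl1, Fl2, Pl2, Rl2)`.
#' @param cfg A [constraint_config()].
#' @return Integer defect in 0..3.
#' @export
len_diff_defect <- function(v, cfg = constraint_config()) {
  stopifnot(length(v) == 6L)
  ok <- c(abs(v[1L] - v[3L]) <= cfg$len_diff_max,
          abs(v[4L] - v[6L]) <= cfg$len_diff_max,
          abs(v[1L] - v[6L]) <= cfg$len_diff_max)
  3L - sum(ok)
}

#' GC-proportion defect of a primer set (0--4)
#'
#' One check per primer; satisfied when the GC percent lies inside the
#' inclusive `[gc_low, gc_high]` band.
#'
#' @param set A `ctpp_primer_set`.
#' @param cfg A [constraint_config()].
#' @return Integer defect in 0..4.
#' @export
gc_proportion_defect <- function(set, cfg = constraint_config()) {
  gc <- vapply(.set_primers(set), gc_percent, numeric(1L))
  4L - sum(gc >= cfg$gc_low & gc <= cfg$gc_high)
}

#' GC-clamp defect of a primer set (0--4)
#'
#' One check per primer; satisfied when the 3'-terminal base is G or C.
#'
#' @inheritParams gc_proportion_defect
#' @return Integer defect in 0..4.
#' @export
gc_clamp_defect <- function(set, cfg = constraint_config()) {
  p <- .set_primers(set)
  last <- substr(p, nchar(p), nchar(p))
  4L - sum(last %in% c("G", "C"))
}

#' Melting-temperature range defect of a primer set (0--4)
#'
#' One check per primer; satisfied when the salt-adjusted Tm lies inside
#' the inclusive `[tm_low, tm_high]` band.
#'
#' @inheritParams gc_proportion_defect
#' @return Integer defect in 0..4.
#' @export
tm_range_defect <- function(set, cfg = constraint_config()) {
  tm <- vapply(.set_primers(set), tm_bm, numeric(1L),
               na_molar = cfg$na_molar)
  4L - sum(tm >= cfg$tm_low & tm <= cfg$tm_high)
}

.tm_diffs <- function(set, cfg) {
  tm <- vapply(.set_primers(set), tm_bm, numeric(1L),
               na_molar = cfg$na_molar)
  c(pf1_pr1 = abs(tm[["pf1"]] - tm[["pr1"]]),
    pf2_pr2 = abs(tm[["pf2"]] - tm[["pr2"]]),
    pf1_pr2 = abs(tm[["pf1"]] - tm[["pr2"]]))
}

#' Pairwise melting-temperature difference defect (0--3)
#'
#' One check per primer pairing pf1/pr1, pf2/pr2 and pf1/pr2; satisfied
#' when the absolute Tm difference is at most `cfg$tm_diff_max`
#' (default 1 degC).
#'
#' @inheritParams gc_proportion_defect
#' @return Integer defect in 0..3.
#' @export
tm_diff_defect <- function(set, cfg = constraint_config()) {
  3L - sum(.tm_diffs(set, cfg) <= cfg$tm_diff_max)
}

#' Average pairwise melting-temperature difference
#'
#' Arithmetic mean of the three absolute Tm differences (pf1/pr1, pf2/pr2,
#' pf1/pr2).  Enters the fitness as a continuous penalty.
#'
#' @inheritParams gc_proportion_defect
#' @return Average Tm difference in degC (non-negative).
#' @export
avg_tm_diff <- function(set, cfg = constraint_config()) {
  mean(.tm_diffs(set, cfg))
}

.dimer_checks <- function(set, cfg) {
  p <- .set_primers(set)
  pairs <- list(
    pf1_pr1 = c("pf1", "pr1"), pf2_pr2 = c("pf2", "pr2"),
    pf2_pr1 = c("pf2", "pr1"), pf1_pr2 = c("pf1", "pr2"),
    pf1_pf2 = c("pf1", "pf2"), pr1_pr2 = c("pr1", "pr2"),
    pf1_self = c("pf1", "pf1"), pr1_self = c("pr1", "pr1"),
    pf2_self = c("pf2", "pf2"), pr2_self = c("pr2", "pr2"))
  vapply(pairs, function(pr) {
    dimer_screen(p[[pr[1L]]], p[[pr[2L]]],
                 stem_min = cfg$dimer_stem_min, end_min = cfg$dimer_3p_min)
  }, logical(1L))
}

#' Dimer defect of a primer set (0--10)
#'
#' Ten checks: the six cross-dimer pairings (pf1/pr1, pf2/pr2, pf2/pr1,
#' pf1/pr2, pf1/pf2, pr1/pr2) and the four self-dimers.  The defect is the
#' number of checks in which [dimer_screen()] finds a dimer.
#'
#' @inheritParams gc_proportion_defect
#' @return Integer defect in 0..10.
#' @export
dimer_defect <- function(set, cfg = constraint_config()) {
  sum(.dimer_checks(set, cfg))
}

.hairpin_checks <- function(set, cfg) {
  vapply(.set_primers(set), hairpin_screen, logical(1L),
         stem_min = cfg$hairpin_stem_min, loop_min = cfg$hairpin_loop_min)
}

#' Hairpin defect of a primer set (0--4)
#'
#' One check per primer; the defect is the number of primers in which
#' [hairpin_screen()] finds a hairpin.
#'
#' @inheritParams gc_proportion_defect
#' @return Integer defect in 0..4.
#' @export
hairpin_defect <- function(set, cfg = constraint_config()) {
  sum(.hairpin_checks(set, cfg))
}

# overlap-aware count of a literal site in a sequence string
.count_site <- function(site, subject) {
  m <- gregexpr(paste0("(?=", site, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

# per-primer repetition of binding sites in the template; the SNP position
# is matched under either allele; other ambiguity codes are treated as
# non-matching (template-only specificity)
.specificity_repeats <- function(set, template) {
  sites <- c(pf1 = set$pf1,
             pr1 = reverse_complement(set$pr1),
             pf2 = set$pf2,
             pr2 = reverse_complement(set$pr2))
  subj <- c(template$sequence_major, template$sequence_minor)
  vapply(sites, function(x)
    max(.count_site(x, subj[1L]), .count_site(x, subj[2L])) > 1L,
    logical(1L))
}

#' Template-specificity defect of a primer set (0 or 1)
#'
#' Counts occurrences of each primer's binding site on the template (sense
#' occurrences of forward primers; sense occurrences of the reverse
#' primers' reverse complements), matching the SNP position under either
#' allele.  The defect is 1 if any site occurs more than once, else 0.
#' Specificity is template-only; genome-scale uniqueness is out of scope.
#'
#' @param set A `ctpp_primer_set`.
#' @param template The `ctpp_template` the set was realized on.
#' @return Integer 0 or 1.
#' @export
specificity_defect <- function(set, template) {
  as.integer(any(.specificity_repeats(set, template)))
}

.pcr_len_checks <- function(products, cfg) {
  stopifnot(length(products) == 3L)
  r <- cfg$ratios
  u <- sum(products) / sum(r)
  corresponds <- abs(products - r * u) <= cfg$ratio_tolerance * r * u
  c(pl1_gt_min = products[[1L]] > cfg$product_min,
    pl2_gt_min = products[[2L]] > cfg$product_min,
    pl3_gt_min = products[[3L]] > cfg$product_min,
    pl1_ratio = corresponds[[1L]],
    pl2_ratio = corresponds[[2L]],
    pl3_ratio = corresponds[[3L]],
    all_ratios = all(corresponds))
}

#' PCR product-length defect (0--7)
#'
#' Seven checks on the product lengths `(Pl1, Pl2, Pl3)`: each strictly
#' above the product floor (default 100 bp), each corresponding to its
#' electrophoresis ratio, and all three ratios simultaneously.  A product
#' corresponds to its ratio when `|Pl_i - r_i u| <= tol * r_i u` with
#' `u = (Pl1+Pl2+Pl3)/(r1+r2+r3)`.
#'
#' @param x A `ctpp_primer_set`, or a numeric vector of the three product
#'   lengths.
#' @param cfg A [constraint_config()].
#' @return Integer defect in 0..7.
#' @export
pcr_len_defect <- function(x, cfg = constraint_config()) {
  products <- if (inherits(x, "ctpp_primer_set")) x$products else x
  7L - sum(.pcr_len_checks(as.numeric(products), cfg))
}

#' Recombine a fitness breakdown into the weighted total
#'
#' `total = w_composition (len_diff + gc_proportion + gc_clamp) +
#' w_structure (dimer + hairpin + specificity) + w_tm (tm + tm_diff) +
#' w_tm_balance * avg_tm_diff + w_product * pcr_len`, with default weights
#' 3, 10, 50, 100 and 60.  Average Tm differences at or below
#' `cfg$tm_epsilon` contribute nothing, so a defect-free set with equal
#' melting temperatures scores exactly zero.
#'
#' @param bd A list (or `ctpp_fitness`) with the ten component fields.
#' @param cfg A [constraint_config()] supplying weights and `tm_epsilon`.
#' @return The weighted total (non-negative scalar).
#' @export
fitness_total <- function(bd, cfg = constraint_config()) {
  w <- cfg$weights
  avg <- if (bd$avg_tm_diff <= cfg$tm_epsilon) 0 else bd$avg_tm_diff
  unname(
    w[["composition"]] * (bd$len_diff + bd$gc_proportion + bd$gc_clamp) +
    w[["structure"]] * (bd$dimer + bd$hairpin + bd$specificity) +
    w[["tm"]] * (bd$tm + bd$tm_diff) +
    w[["tm_balance"]] * avg +
    w[["product"]] * bd$pcr_len)
}

#' Full fitness breakdown of a realized primer set
#'
#' Evaluates every constraint defect, the continuous average-Tm penalty and
#' the weighted total to be minimized.  Deterministic for fixed inputs.
#'
#' @param set A `ctpp_primer_set` realized from `v` on `template`.
#' @param v The chromosome vector the set was realized from.
#' @param template The `ctpp_template`.
#' @param cfg A [constraint_config()].
#' @return An object of class `ctpp_fitness`: the ten component values,
#'   `total`, and a `detail` list (per-primer GC and Tm, pairwise Tm
#'   differences, per-check dimer/hairpin/specificity/product outcomes).
#' @export
fitness <- function(set, v, template, cfg = constraint_config()) {
  p <- .set_primers(set)
  gc <- vapply(p, gc_percent, numeric(1L))
  tm <- vapply(p, tm_bm, numeric(1L), na_molar = cfg$na_molar)
  tmd <- .tm_diffs(set, cfg)
  dimer_hits <- .dimer_checks(set, cfg)
  hairpin_hits <- .hairpin_checks(set, cfg)
  spec_rep <- .specificity_repeats(set, template)
  pcr_checks <- .pcr_len_checks(as.numeric(set$products), cfg)

  bd <- list(
    len_diff = len_diff_defect(v, cfg),
    gc_proportion = 4L - sum(gc >= cfg$gc_low & gc <= cfg$gc_high),
    gc_clamp = gc_clamp_defect(set, cfg),
    tm = 4L - sum(tm >= cfg$tm_low & tm <= cfg$tm_high),
    tm_diff = 3L - sum(tmd <= cfg$tm_diff_max),
    avg_tm_diff = mean(tmd),
    dimer = sum(dimer_hits),
    hairpin = sum(hairpin_hits),
    specificity = as.integer(any(spec_rep)),
    pcr_len = 7L - sum(pcr_checks)
  )
  bd$total <- fitness_total(bd, cfg)
  bd$detail <- list(gc = gc, tm = tm, tm_diffs = tmd,
                    dimer_hits = dimer_hits, hairpin_hits = hairpin_hits,
                    specificity_repeats = spec_rep,
                    pcr_checks = pcr_checks,
                    product_ok = unname(pcr_checks[1:3] & pcr_checks[4:6]))
  structure(bd, class = "ctpp_fitness")
}

#' Realize and evaluate a chromosome in one step
#'
#' @inheritParams vector_feasible
#' @return A `ctpp_fitness` breakdown (see [fitness()]).
#' @export
evaluate_vector <- function(template, v, cfg = constraint_config()) {
  set <- realize_primer_set(template, v, cfg)
  fitness(set, v, template, cfg)
}

#' @export
print.ctpp_fitness <- function(x, ...) {
  cat("CTPP fitness breakdown\n")
  comp <- c("len_diff", "gc_proportion", "gc_clamp", "tm", "tm_diff",
            "dimer", "hairpin", "specificity", "pcr_len")
  for (k in comp) cat(sprintf("  %-14s %d\n", k, x[[k]]))
  cat(sprintf("  %-14s %.4f\n", "avg_tm_diff", x$avg_tm_diff))
  cat(sprintf("  total          %.4f\n", x$total))
  invisible(x)
}
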