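---
title: "Designing confronting two-pair primer sets with ctppdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing confronting two-pair primer sets with ctppdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The genotyping problem

PCR with confronting two-pair primers (PCR-CTPP) genotypes a biallelic
SNP with nothing but a PCR and a gel.  Four primers run in one tube: two
inner primers terminate with their 3' base exactly on the SNP, on opposite
strands — `Pr1` carries the complement of the minor allele, `Pf2` the
major allele — so each inner primer only extends on templates carrying
its allele.  Together with the two outer primers (`Pf1` upstream, `Pr2`
downstream) the reaction yields an allele-1-specific band (`Pf1`/`Pr1`,
length `Pl1`), an allele-2-specific band (`Pf2`/`Pr2`, length `Pl2`), and
an allele-independent outer band (`Pf1`/`Pr2`, length `Pl3`), which acts
as a built-in positive control.  A homozygote shows two bands, a
heterozygote three; no restriction enzyme or probe is needed.

Because the two inner primers overlap on the SNP, the outer product obeys

```
Pl3 = Pl1 + Pl2 - Rl1 - Fl2 + 1
```

where `Rl1` and `Fl2` are the inner primer lengths.  The whole design is
therefore determined by six integers — the chromosome vector

```
Pv = (Fl1, Pl1, Rl1, Fl2, Pl2, Rl2)
```

(two primer lengths and one product length per pair) plus the SNP
position on the template.  `ctppdesign` searches this space with a
genetic algorithm against a weighted constraint fitness.

## The fitness model

All constraints are scored as *defect values*: the number of failed
checks, zero when every check passes.  The total to minimize is

```
total = 3  * (len_diff + gc_proportion + gc_clamp)
      + 10 * (dimer + hairpin + specificity)
      + 50 * (tm + tm_diff)
      + 100 * avg_tm_diff
      + 60 * pcr_len
```

The weights order the experimental stakes for this assay family: a
melting-temperature imbalance between the four primers is the dominant
failure mode of PCR-CTPP (the inner primers compete in one tube), so the
continuous average Tm difference carries the largest weight; product
geometry comes next (bands must separate on a gel); structure defects
(dimers, hairpins, non-unique binding sites) and composition defects
follow.  The weights are configurable (`constraint_config(weights = ...)`).

Component by component (all range checks are inclusive; the
product-length floor is strict):

* **Primer length difference** (0–3): `|Fl1-Rl1|`, `|Fl2-Rl2|`,
  `|Fl1-Rl2|` each at most 3 bases.
* **GC proportion** (0–4): each primer within 20–80%.  The band is wider
  than the conventional 40–60% because the inner primers are pinned to
  the SNP and cannot be slid to tune composition.
* **GC clamp** (0–4): each primer 3'-terminal base G or C.  Note the
  inner 3' bases are dictated by the alleles, so for an A/T SNP two
  clamp checks are structurally unattainable — the GA then minimizes the
  remaining defects.
* **Melting temperature** (0–4): the salt-adjusted estimate
  `Tm = 81.5 + 16.6 log10[Na+] + 0.41 GC% - 675/|P|` (GC% on the 0–100
  scale), each primer within 45–62 °C.  This formula, rather than the
  rough `2(A+T) + 4(G+C)` rule, is used throughout.  The salt
  concentration defaults to 0.05 M — a standard assumption for
  salt-adjusted primer Tm calculators — and is always echoed in reports
  (`na_molar`), never silently assumed.
* **Tm difference** (0–3) and **average Tm difference** (continuous,
  °C): over the pairings `Pf1/Pr1`, `Pf2/Pr2`, `Pf1/Pr2`; the defect
  uses a 1 °C tolerance, the average enters the fitness unrounded.
* **Dimer** (0–10): six cross pairings plus four self-dimers.
* **Hairpin** (0–4): one check per primer.
* **Specificity** (0 or 1): 1 if any primer binding site occurs more
  than once on the template (see below).
* **Product length** (0–7): each of `Pl1, Pl2, Pl3` strictly above
  100 bp; each corresponding to its electrophoresis ratio; and all three
  ratios at once.

## Screens and other choices the model leaves open

Several checks are named by the model but not operationalized; the
package's choices are:

**Dimer screen.**  The two 5'→3' primers are slid over every antiparallel
ungapped alignment.  A dimer is flagged when the longest run of
Watson–Crick complementary pairs reaches `dimer_stem_min` (default 5)
anywhere, or `dimer_3p_min` (default 3) when the run includes either
primer's 3'-terminal base — a 3'-anchored duplex is extensible by the
polymerase, so a shorter clamp already matters there.  This is the
standard alignment-heuristic family used by primer tools that do not
compute duplex free energies; both thresholds are exposed because
different laboratories draw the line differently.

**Hairpin screen.**  A hairpin is flagged when some window of
`hairpin_stem_min` bases (default 4) is the antiparallel complement of a
downstream window separated by at least `hairpin_loop_min` unpaired bases
(default 3).  Only stems of exactly the minimum length need to be
scanned: any longer stem contains a minimum-length sub-stem adjacent to
the same loop.  Both screens are mirrored by deliberately naive
brute-force oracles (`dimer_bruteforce()`, `hairpin_bruteforce()`) and
the two implementations are compared by full enumeration over short
primers in the test suite.

**Ratio correspondence.**  The three products should separate cleanly on
a gel; the target ratios default to 8 : 13 : 20.  "Corresponds" is read
proportionally: with unit `u = (Pl1+Pl2+Pl3)/(r1+r2+r3)`, product `i`
corresponds to ratio `r_i` iff `|Pl_i - r_i u| <= ratio_tolerance * r_i u`.
The default tolerance of 0.25 is deliberately loose: published working
assays of this family (e.g. 228/105/294 bp) deviate substantially from
the nominal ratios, so an exact-proportion reading would reject known
good designs.

**Specificity.**  Template-only: each primer's binding site (forward
primers on the sense strand, reverse primers' reverse complements) is
counted on the template with the SNP resolved to either allele; more
than one occurrence scores the defect.  Counting is overlap-aware.
Ambiguity codes other than the defined SNP are treated as non-matching.
Genome-scale uniqueness is explicitly out of scope — users with
repeat-rich targets should BLAST the reported primers.

**Extra polymorphic sites.**  Templates may carry additional ambiguity
codes.  Chromosomes whose outer primer windows cover such a site are
hard-rejected (a hidden polymorphism under a primer destabilizes Tm
unpredictably).  By default the exclusion also applies to the inner
primer windows, since the argument applies with equal force there; set
`extra_snp_strict = FALSE` to restrict it to the outer primers.

**Zero-fitness termination.**  The average Tm difference is continuous,
so "fitness equals zero" would require exact floating-point equality of
melting temperatures.  Averages at or below `tm_epsilon` (default 1e-9
°C, i.e. only exact ties up to float noise) contribute nothing, which
lets a defect-free design with equal Tm terminate the search exactly.

## The genetic algorithm

The search is a steady-state GA:

1. **Initialization** — `population_size` distinct feasible chromosomes;
   primer genes uniform on `[16, 28]`, product genes uniform on
   `[100, delta]`, where `delta1`/`delta2` are the largest product
   lengths that fit the template on each side of the SNP
   (`feasible_bounds()`).  Infeasible or duplicate draws are regenerated.
2. **Selection** — two distinct parents drawn uniformly (no fitness bias;
   selection pressure comes entirely from replacement).
3. **Uniform crossover** with probability 0.6: a six-bit mask marks the
   exchanged genes; if an offspring violates hard feasibility, the
   exchanged genes are restored one by one (jointly on both children, so
   the position-wise multiset of parental genes is preserved) until both
   children are feasible — restoring every exchange recovers the parents.
4. **One-point mutation** with probability 0.001 per offspring: one gene
   regenerated within its legal range, always to a different value;
   infeasible results trigger point re-selection, up to `repair_budget`
   (default 100) attempts, after which the operation is abandoned with a
   warning.  The canonical 0.001 rate is defined per bit on bit-string
   chromosomes; with six integer genes, per-offspring application is the
   closest consistent reading.
5. **Replacement** — the two worst members are replaced by the offspring
   (ties broken by position, earliest first), so the best-so-far fitness
   is non-increasing by construction.
6. **Termination** — fitness zero or `max_generations` (default 1000)
   generations, where one generation breeds one pair.  "Iterations" is
   counted in generations, not fitness evaluations; the cap is
   configurable.

Hard feasibility (length bounds, template fit, strict outer-primer
placement, extra-SNP exclusion) is repaired during the operators; soft
constraints are priced only through the fitness.  All randomness flows
through R's RNG; `ga_config(seed = )` makes a run bit-reproducible, and
batch runs seed record `i` with `seed + i - 1` so any single record can
be reproduced standalone.

## Synthetic templates and validation strategy

`generate_template()` emulates a flank export: a random background of
configurable GC fraction (default 0.5) with the SNP centered between
flanks of 500 bp by default — the flank length this assay family
typically retrieves.  It can plant verifiable features:

* a **zero-fitness chromosome** (`plant_zero`): four 20-mers with
  identical length and GC count (hence identical Tm by construction),
  G/C 3' clamps, screen-clean individually and pairwise, embedded at
  windows giving products 160/260/381 bp — above the floor and inside
  the ratio tolerance.  The construction works backwards from the
  constraints and is re-verified with the package's own evaluators
  before the template is returned; the allele pair is forced to C/G so
  both inner primers can carry a clamp.
* a **repeated site** (`plant_repeat`): the outer-forward 20-mer
  duplicated elsewhere, tripping exactly the specificity check (on a
  planted-zero template the set then scores exactly the structure
  weight, 10).
* a **stem-loop motif** (`plant_palindrome`) for exercising the hairpin
  screen.

What the generator does *not* emulate: real flanking sequence
composition (repeats, homopolymer runs, CpG structure), nearby common
variants, or paralogy — so a green test suite demonstrates the
correctness of the evaluators and the search dynamics, not wet-lab
performance on any particular locus.

Validation is dual-route throughout: the C++ screens against R
brute-force enumerators (exact agreement over all primers up to length
8); the realized-set site counting against `Biostrings` pattern
matching; the reverse complement against `Biostrings`; and the GA
against `exhaustive_search()`, which enumerates and evaluates a
restricted chromosome space completely.  For the GA-versus-exhaustive
experiment the package uses a planted-zero template (301-bp flanks
shortened to keep evaluation cheap) with the space restricted to 2025
chromosomes around the optimum, and a population of 400: a steady-state
GA with uniform parent selection draws its selection pressure only from
replacement, so its effective sampling is governed by population size —
the evaluation budget (population plus two offspring per generation)
must be commensurate with the space for near-certain convergence, which
matches the published observation that raising the population from 50
to 1000 is what lifts constraint satisfaction on full-size templates.
With that sizing the GA reaches the exhaustive minimum in ≥ 95 of 100
seeded runs.  Batch statistics are exercised at n = 288 records with
reduced GA settings (population 5, 2 generations), since the
denominators under test — 4, 3 and 10 checks per set — do not depend on
search quality.

## Numerical and convention choices

* Internally all window arithmetic is 0-based half-open in spirit but
  implemented directly in 1-based inclusive coordinates matching reports;
  reverse-primer coordinates are reported primer-oriented (`start` = 5'
  template position, `end` = 3', so `end` of `Pr1` is the SNP itself).
* For multi-SNP inputs the first ambiguity position is the defined SNP;
  the rest become `extra_snp_indices`.  Bracket tokens with more than two
  alleles map to the corresponding multi-way IUPAC code, and the design
  uses the two user-designated alleles.
* Flank exports carry no frequency information, so major/minor must be
  supplied (`alleles = c(major, minor)`); omitting it falls back to
  alphabetical order with a warning.
* Insertion/deletion and multi-nucleotide polymorphisms are rejected:
  the confronting geometry is defined for single-base substitutions.
* The minimal gap between `Pf1` and `Pr1` windows is zero (abutting
  windows are legal); no minimum is imposed because none is implied by
  the geometry.
* Report numbers are printed with fixed decimal formatting (GC and Tm to
  2 decimals) and every report echoes the full configuration, making
  reports self-verifying; with a fixed seed they are byte-identical
  across runs.

## Known limitations

* Thermodynamics: the salt-adjusted formula ignores nearest-neighbor
  stacking and divalent cations; the dimer/hairpin screens count
  complementary runs, not free energies.  Designs destined for the bench
  should be double-checked with a thermodynamic tool.
* Specificity is template-local, not genome-wide.
* An A/T SNP caps the attainable GC-clamp score, and templates with
  extreme composition may admit no zero-fitness design; the GA then
  returns the best-effort set with its full breakdown, and `design_one()`
  flags non-convergence.
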