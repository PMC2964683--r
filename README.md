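# ctppdesign

Design of **confronting two-pair primer (CTPP) sets** for enzyme-free SNP
genotyping, driven by a genetic algorithm.

PCR with confronting two-pair primers (PCR-CTPP) genotypes a biallelic
SNP by electrophoresis alone: four primers run in one tube, the two inner
primers terminating 3' on the SNP on opposite strands (`Pr1` carries the
complement of the minor allele, `Pf2` the major allele), so each allele
amplifies a different-length band plus one common outer band.  Two bands
mean homozygote, three mean heterozygote — no restriction enzyme, no
probe.  Finding four primers that simultaneously satisfy the composition,
melting-temperature, structure and band-separation constraints is the
hard part; this package searches for them.

## The model

A design is a six-integer chromosome

```
Pv = (Fl1, Pl1, Rl1, Fl2, Pl2, Rl2)
```

— the two primer lengths and the product length of each pair; together
with the SNP position these determine all four primers and the three
product lengths, with the outer product following the overlap identity
`Pl3 = Pl1 + Pl2 - Rl1 - Fl2 + 1`.  Every constraint is scored as a
defect value (number of failed checks) and combined into the weighted
fitness that the GA minimizes:

```
total = 3  * (len_diff + gc_proportion + gc_clamp)
      + 10 * (dimer + hairpin + specificity)
      + 50 * (tm + tm_diff)
      + 100 * avg_tm_diff
      + 60 * pcr_len
```

Melting temperatures use the salt-adjusted estimate
`Tm = 81.5 + 16.6 log10[Na+] + 0.41 GC% − 675/|P|`.  The search is a
steady-state GA: uniform random parent selection, masked uniform
crossover (p = 0.6), one-point mutation (p = 0.001), worst-two
replacement, with hard-infeasible offspring repaired by restoring
exchanges or regenerating the mutated gene.  Defaults: primer length
16–28 bp, GC 20–80 %, Tm 45–62 °C with pairwise differences ≤ 1 °C,
products > 100 bp in electrophoresis ratios 8 : 13 : 20, population 50,
1000 generations.  See the methods vignette
(`vignettes/ctpp-design.Rmd`) for every choice and its rationale.

## Worked example

A synthetic 1001-bp template with a centered C/G SNP and a planted
all-constraints-satisfied primer set; the GA is run with the
higher-accuracy population of 1000:

```r
library(ctppdesign)

g <- generate_template(flank_length = 500, plant_zero = TRUE, seed = 42)
r <- design_one(g$template, constraint_config(),
                ga_config(population_size = 1000, seed = 1))
print(r)
```

```
CTPP primer design report -- synthetic_42
template 1001 bp, SNP at 501 [C/G], Na+ 0.05 M, seed 1
fitness 122.3095 after 1000 generation(s)

     sequence (5'->3')                 len     GC%      Tm   start     end strand
Pf1  GTTTCAGTCTGGGTACACCATTCTGAAT       28   42.86   53.37     372     399      +
Pr1  TGAAGTTTGCAATCGAATATCCCCAAGC       28   42.86   53.37     528     501      -
Pf2  ACACGTCTCGTTATTGGTTTCCGC           24   50.00   52.28     478     501      +
Pr2  CGGCTTGCTTAACTGTCAGTTCATCA         26   46.15   52.86     753     728      -

products: Pf1/Pr1 157 bp, Pf2/Pr2 276 bp, Pf1/Pr2 382 bp
Tm differences: Pf1/Pr1 0.0000, Pf2/Pr2 0.5865, Pf1/Pr2 0.5027 degC
```

Reading it: `Pr1` ends on position 501 — the SNP — carrying the
complement of the minor allele (G→C), and `Pf2` ends there carrying the
major allele; the three products (157, 276, 382 bp) separate cleanly on
a gel, and 382 = 157 + 276 − 28 − 24 + 1 by the overlap identity.  The
four melting temperatures sit within 1.1 °C of each other.  This run is
a best effort (`r$converged` is `FALSE`): its breakdown
(`print(r$fitness)`) shows the residue is dominated by dimer screen hits
and two missing GC clamps.  The planted perfect set is still there —
`evaluate_vector(g$template, g$manifest$zero_vector)$total` returns `0`
— it is just a needle in a ~10^9-chromosome space.

`write_report(r, "design.tsv")` writes a lossless, self-verifying report
(every number is recomputable from the printed sequences and the echoed
configuration); `design_batch()` runs a multi-record FASTA and
aggregates per-constraint satisfaction statistics.  A command-line
wrapper lives at `inst/cli/ctpp.R`:

```sh
Rscript inst/cli/ctpp.R design --input flanks.fa --alleles A,C --seed 1 \
    --out design.tsv --format tsv
```

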