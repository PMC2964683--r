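# published example primers (inner primers carry the SNP allele 3')
PF1_EX <- "GATTATTAGTAGTTTCTGCA"
PR1_EX <- "TTCTTTATGAATACCAGACG"
PF2_EX <- "AGAAAGTTACAGACTAGCAA"
PR2_EX <- "ATGTTTAATCTCTGAGAAGA"

# 20-mers with a prescribed GC count (G-run then A-run), last base free
gc20 <- function(ngc, last = "A") {
  paste0(strrep("G", ngc), strrep("A", 19 - ngc), last)
}

test_that("GC percent counts G and C on the 0-100 scale", {
  expect_equal(gc_percent(PF1_EX), 30)
  expect_equal(gc_percent(PR1_EX), 35)
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_error(gc_percent(""), "empty")
  expect_error(gc_percent("ACGN"), "other than")
})

test_that("salt-adjusted Tm follows the Bolton-McCarthy formula", {
  p50 <- strrep("GA", 10)  # 20-mer, 50% GC
  expect_equal(tm_bm(p50, na_molar = 1), 68.25)
  expect_equal(tm_bm(p50, na_molar = 0.05),
               81.5 + 16.6 * log10(0.05) + 0.41 * 50 - 675 / 20)
  expect_equal(round(tm_bm(p50, na_molar = 0.05), 2), 46.65)
  expect_error(tm_bm(p50, na_molar = 0), "positive")

  # one G -> A substitution on a 20-mer shifts GC% by 5 points: 2.05 degC
  expect_equal(tm_bm(gc20(10)) - tm_bm(gc20(9)), 0.41 * 5)

  # strictly increasing in GC%, length, and salt
  expect_true(all(diff(vapply(4:16, function(g) tm_bm(gc20(g)),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(c(16, 20, 24, 28), function(L)
    tm_bm(strrep("GA", L / 2)), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.2, 1), function(na)
    tm_bm(gc20(10), na), numeric(1))) > 0))
})

test_that("length-difference defect counts failed pairings", {
  cfg <- constraint_config()
  expect_equal(len_diff_defect(c(20, 150, 20, 20, 150, 20), cfg), 0L)
  # all three pairings differ by 12 > 3
  expect_equal(len_diff_defect(c(16, 150, 28, 16, 150, 28), cfg), 3L)
  # only the Fl2/Rl2 pairing fails (|28-18| = 10; the two others differ
  # by 0 and 2)
  expect_equal(len_diff_defect(c(20, 150, 20, 28, 150, 18), cfg), 1L)
  # boundary: a difference of exactly 3 passes (inclusive)
  expect_equal(len_diff_defect(c(20, 150, 23, 20, 150, 20), cfg), 0L)
})

test_that("GC-proportion defect uses inclusive 20-80 bounds", {
  cfg <- constraint_config()
  # published set: 30 / 35 / 30 / 35 percent, all inside
  expect_equal(gc_proportion_defect(
    fake_set(PF1_EX, PR1_EX, PF2_EX, PR2_EX), cfg), 0L)
  polyA <- strrep("A", 20)
  expect_equal(gc_proportion_defect(fake_set(polyA, polyA, polyA, polyA),
                                    cfg), 4L)
  # exactly 20% passes the inclusive bound
  p20 <- gc20(4)
  expect_equal(gc_percent(p20), 20)
  expect_equal(gc_proportion_defect(fake_set(p20, polyA, polyA, polyA),
                                    cfg), 3L)
})

test_that("GC-clamp defect checks the 3'-terminal base", {
  cfg <- constraint_config()
  # published primers end A, G, A, A: only Pr1 carries a clamp
  expect_equal(gc_clamp_defect(
    fake_set(PF1_EX, PR1_EX, PF2_EX, PR2_EX), cfg), 3L)
  allc <- gc20(9, "C")
  expect_equal(gc_clamp_defect(fake_set(allc, allc, allc, allc), cfg), 0L)
})

test_that("Tm-range defect uses inclusive bounds", {
  p <- gc20(10)
  s <- fake_set(p, p, p, p)
  expect_equal(tm_range_defect(s, constraint_config()), 0L)  # 46.65 degC
  expect_equal(tm_range_defect(s, constraint_config(na_molar = 1e-4)), 4L)
  # a primer sitting exactly on the lower bound passes
  cfg_edge <- constraint_config(tm_low = tm_bm(p, 0.05), tm_high = 62)
  expect_equal(tm_range_defect(s, cfg_edge), 0L)
})

test_that("pairwise Tm differences drive tm_diff_defect and avg_tm_diff", {
  cfg <- constraint_config()
  p10 <- gc20(10)
  s_same <- fake_set(p10, p10, p10, p10)
  expect_equal(tm_diff_defect(s_same, cfg), 0L)
  expect_equal(avg_tm_diff(s_same, cfg), 0)

  # pf2 differs by 25 GC percentage points (10.25 degC): only the
  # pf2/pr2 check fails
  s_one <- fake_set(p10, p10, gc20(15), p10)
  expect_equal(tm_diff_defect(s_one, cfg), 1L)
  expect_equal(avg_tm_diff(s_one, cfg), 0.41 * 25 / 3)

  # every pairing differs by >= 2 degC
  s_all <- fake_set(gc20(5), gc20(10), gc20(5), gc20(15))
  expect_equal(tm_diff_defect(s_all, cfg), 3L)
  expect_equal(avg_tm_diff(s_all, cfg),
               mean(0.41 * c(25, 50, 50)))
})

test_that("dimer defect counts the ten pair checks", {
  cfg <- constraint_config()
  # mutually non-complementary purine-only primers: no check can pair
  pur <- function(seed) {
    set.seed(seed)
    random_dna(20, c("A", "G"))
  }
  s_clean <- fake_set(pur(1), pur(2), pur(3), pur(4))
  expect_equal(dimer_defect(s_clean, cfg), 0L)

  # a primer paired with its exact reverse complement: full-length duplex
  p <- pur(5)
  s_rc <- fake_set(p, reverse_complement(p), pur(3), pur(4))
  expect_gte(dimer_defect(s_rc, cfg), 1L)
  expect_true(dimer_screen(p, reverse_complement(p)))

  # palindromic motif carrier self-dimerizes (GGATCC is its own
  # reverse complement)
  expect_true(dimer_screen("AAAGGATCCAAA", "AAAGGATCCAAA",
                           stem_min = 5, end_min = 3))
})

test_that("hairpin defect flags stem-loop structures per primer", {
  cfg <- constraint_config()
  hp <- paste0("GGGGAAAACCCC", strrep("A", 8))  # 4-stem, 4-loop
  pur <- strrep("AG", 10)                        # purine-only: no stem
  s <- fake_set(hp, pur, pur, pur)
  expect_equal(hairpin_defect(s, cfg), 1L)
  expect_false(hairpin_screen("AAAAAAAAAAAA"))
  # stem of 3 is below the default threshold of 4
  expect_false(hairpin_screen("GGGAAAACCC"))
  expect_true(hairpin_screen("GGGAAAACCC", stem_min = 3))
})

test_that("specificity flags repeated binding sites in the template", {
  zr <- zero_repeat_fixture()
  v0 <- zr$manifest$zero_vector
  set <- realize_primer_set(zr$template, v0)
  expect_equal(specificity_defect(set, zr$template), 1L)

  z <- zero_fixture()
  set0 <- realize_primer_set(z$template, z$manifest$zero_vector)
  expect_equal(specificity_defect(set0, z$template), 0L)

  # cross-check the site counting against Biostrings (overlap-aware)
  for (site in c(set0$pf1, reverse_complement(set0$pr1), "AAA")) {
    expect_equal(
      ctppdesign:::.count_site(site, z$template$sequence_major),
      Biostrings::countPattern(site,
        Biostrings::DNAString(z$template$sequence_major)))
  }
})

test_that("product-length defect combines floor and ratio checks", {
  cfg <- constraint_config()
  # exactly proportional to 8:13:20 and all above 100 bp
  expect_equal(pcr_len_defect(c(160, 260, 400), cfg), 0L)
  # 100 bp fails the strict floor even though ratios fit (u ~ 12.49)
  expect_equal(pcr_len_defect(c(100, 162, 250), cfg), 1L)
  # short products: three floor checks fail, plus ratio1 and the
  # all-ratios check (unit u = 180/41, only ratios 2 and 3 fit)
  expect_equal(pcr_len_defect(c(50, 50, 80), cfg), 5L)
  expect_gte(pcr_len_defect(c(50, 50, 80), cfg), 4L)
})

test_that("weighted total recombines the breakdown exactly", {
  cfg <- constraint_config()
  base <- list(len_diff = 0L, gc_proportion = 0L, gc_clamp = 0L, tm = 0L,
               tm_diff = 0L, avg_tm_diff = 0, dimer = 0L, hairpin = 0L,
               specificity = 0L, pcr_len = 0L)
  expect_equal(fitness_total(base, cfg), 0)
  only_spec <- modifyList(base, list(specificity = 1L))
  expect_equal(fitness_total(only_spec, cfg), 10)
  one_pcr <- modifyList(base, list(pcr_len = 1L))
  expect_equal(fitness_total(one_pcr, cfg), 60)

  # random breakdowns: total equals the independently computed weighted
  # sum, and increasing any component never decreases the total
  set.seed(21)
  for (i in 1:50) {
    bd <- list(len_diff = sample(0:3, 1), gc_proportion = sample(0:4, 1),
               gc_clamp = sample(0:4, 1), tm = sample(0:4, 1),
               tm_diff = sample(0:3, 1), avg_tm_diff = runif(1, 0, 5),
               dimer = sample(0:10, 1), hairpin = sample(0:4, 1),
               specificity = sample(0:1, 1), pcr_len = sample(0:7, 1))
    manual <- 3 * (bd$len_diff + bd$gc_proportion + bd$gc_clamp) +
      10 * (bd$dimer + bd$hairpin + bd$specificity) +
      50 * (bd$tm + bd$tm_diff) + 100 * bd$avg_tm_diff + 60 * bd$pcr_len
    expect_equal(fitness_total(bd, cfg), manual)
    for (comp in c("len_diff", "dimer", "tm", "pcr_len", "avg_tm_diff")) {
      bumped <- bd
      bumped[[comp]] <- bumped[[comp]] + 1
      expect_gte(fitness_total(bumped, cfg), fitness_total(bd, cfg))
    }
  }
})

test_that("a defect-free set with equal Tm scores exactly zero", {
  z <- zero_fixture()
  bd <- evaluate_vector(z$template, z$manifest$zero_vector)
  for (k in c("len_diff", "gc_proportion", "gc_clamp", "tm", "tm_diff",
              "dimer", "hairpin", "specificity", "pcr_len"))
    expect_equal(as.integer(bd[[k]]), 0L, label = k)
  expect_equal(bd$avg_tm_diff, 0)
  expect_identical(bd$total, 0)

  # a single violated specificity check prices the set at exactly the
  # structure weight
  zr <- zero_repeat_fixture()
  bd2 <- evaluate_vector(zr$template, zr$manifest$zero_vector)
  expect_equal(bd2$specificity, 1L)
  expect_equal(bd2$total, 10)
})

test_that("all defects stay in their declared ranges under fuzzing", {
  set.seed(31)
  for (seed in c(101, 202)) {
    g <- generate_template(flank_length = 150, seed = seed,
                           alleles = c("A", "C"))
    pop <- initialize_population(g$template, constraint_config(),
                                 ga_config(population_size = 15,
                                           max_generations = 0))
    for (i in seq_len(nrow(pop$vectors))) {
      bd <- pop$breakdowns[[i]]
      expect_true(bd$len_diff %in% 0:3)
      expect_true(bd$gc_proportion %in% 0:4)
      expect_true(bd$gc_clamp %in% 0:4)
      expect_true(bd$tm %in% 0:4)
      expect_true(bd$tm_diff %in% 0:3)
      expect_gte(bd$avg_tm_diff, 0)
      expect_true(bd$dimer %in% 0:10)
      expect_true(bd$hairpin %in% 0:4)
      expect_true(bd$specificity %in% 0:1)
      expect_true(bd$pcr_len %in% 0:7)
      expect_equal(bd$total, fitness_total(bd, constraint_config()))
    }
  }
})
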