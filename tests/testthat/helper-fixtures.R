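# shared fixtures, built in code and memoized across test files

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# 30-base toy template, SNP (A/C) at position 15, for manual index checks
toy_template <- function() {
  parse_template(paste0("ACGTACGGTTCAGT", "M", "GGATCCAATGCGTAC"),
                 dialect = "iupac", alleles = c("A", "C"))
}

# relaxed bounds so short toy chromosomes are admissible
toy_cfg <- function(...) {
  constraint_config(len_min = 5L, len_max = 8L, product_min = 10L, ...)
}

# 601-bp synthetic template with an embedded all-constraints-satisfied set
zero_fixture <- function(seed = 7) {
  .memo(paste0("zero", seed),
        generate_template(flank_length = 300, plant_zero = TRUE,
                          seed = seed))
}

# same, plus a duplicated outer-forward site that trips only specificity
zero_repeat_fixture <- function(seed = 7) {
  .memo(paste0("zrep", seed),
        generate_template(flank_length = 300, plant_zero = TRUE,
                          plant_repeat = TRUE, seed = seed))
}

# search-space restriction around the planted chromosome: 3^4 length
# combinations x 5 x 5 product values = 2025 states
tiny_cfg <- function(...) {
  constraint_config(len_min = 19L, len_max = 21L,
                    pl1_range = c(158L, 162L), pl2_range = c(258L, 262L),
                    ...)
}

# a primer set object with given primers, bypassing realization, for
# unit-testing the per-set constraint evaluators in isolation
fake_set <- function(pf1, pr1, pf2, pr2, products = c(150L, 250L, 360L)) {
  structure(list(pf1 = pf1, pr1 = pr1, pf2 = pf2, pr2 = pr2,
                 products = products),
            class = "ctpp_primer_set")
}

# every DNA string of the given length, lexicographic
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
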