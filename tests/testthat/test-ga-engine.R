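test_that("initialization is feasible, duplicate-free and reproducible", {
  z <- zero_fixture()
  cfg <- tiny_cfg()
  ga <- ga_config(population_size = 25)
  set.seed(1)
  pop1 <- initialize_population(z$template, cfg, ga)
  set.seed(1)
  pop2 <- initialize_population(z$template, cfg, ga)
  expect_identical(pop1$vectors, pop2$vectors)
  expect_equal(nrow(pop1$vectors), 25L)
  keys <- apply(pop1$vectors, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  for (i in seq_len(nrow(pop1$vectors)))
    expect_true(isTRUE(vector_feasible(z$template, pop1$vectors[i, ],
                                       cfg)))
})

test_that("a population the size of the feasible space enumerates it", {
  z <- zero_fixture()
  cfg <- constraint_config(len_min = 20L, len_max = 20L,
                           pl1_range = c(158L, 162L),
                           pl2_range = c(259L, 261L))
  ex <- exhaustive_search(z$template, cfg)
  expect_equal(ex$n_feasible, 15L)
  set.seed(2)
  pop <- initialize_population(z$template, cfg,
                               ga_config(population_size = 15L))
  grid <- expand.grid(20L, 158:162, 20L, 20L, 259:261, 20L)
  expect_setequal(apply(pop$vectors, 1, paste, collapse = ","),
                  apply(grid, 1, paste, collapse = ","))
})

test_that("parent selection is distinct and roughly uniform", {
  z <- zero_fixture()
  set.seed(3)
  pop <- initialize_population(z$template, tiny_cfg(),
                               ga_config(population_size = 5L))
  counts <- integer(5)
  set.seed(4)
  for (i in 1:2000) {
    idx <- select_pair(pop)
    expect_length(unique(idx), 2L)
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)

  pop2 <- pop
  pop2$vectors <- pop$vectors[1:2, ]
  pop2$totals <- pop$totals[1:2]
  expect_setequal(select_pair(pop2), c(1L, 2L))
})

test_that("uniform crossover reproduces the published worked example", {
  a <- c(25, 118, 23, 24, 256, 25)
  b <- c(23, 212, 26, 25, 119, 22)
  cx <- uniform_crossover(a, b, mask = c(0, 1, 1, 0, 0, 1))
  expect_equal(cx$a, c(25L, 212L, 26L, 24L, 256L, 22L))
  expect_equal(cx$b, c(23L, 118L, 23L, 25L, 119L, 25L))

  id <- uniform_crossover(a, b, mask = rep(0, 6))
  expect_equal(id$a, as.integer(a))
  expect_equal(id$b, as.integer(b))
})

test_that("crossover preserves the position-wise multiset of genes", {
  z <- zero_fixture()
  cfg <- tiny_cfg()
  set.seed(5)
  pop <- initialize_population(z$template, cfg,
                               ga_config(population_size = 12L))
  for (i in 1:40) {
    idx <- select_pair(pop)
    a <- pop$vectors[idx[1], ]
    b <- pop$vectors[idx[2], ]
    cx <- uniform_crossover(a, b, z$template, cfg)
    for (g in 1:6)
      expect_setequal(c(cx$a[g], cx$b[g]), c(a[[g]], b[[g]]))
    expect_true(isTRUE(vector_feasible(z$template, cx$a, cfg)))
    expect_true(isTRUE(vector_feasible(z$template, cx$b, cfg)))
  }
})

test_that("infeasible exchanges are restored", {
  t <- toy_template()
  cfg <- toy_cfg()
  a <- c(5L, 12L, 5L, 5L, 12L, 5L)
  b <- c(8L, 16L, 8L, 8L, 16L, 8L)
  # swapping Fl1 and Rl1 alone leaves product 1 too short for b's lengths
  # in child a (12 < 8 + 8); both exchanges are restored
  cx <- uniform_crossover(a, b, t, cfg, mask = c(1, 0, 1, 0, 0, 0))
  expect_equal(cx$a, a)
  expect_equal(cx$b, b)
})

test_that("one-point mutation reproduces the published worked example", {
  g <- generate_template(flank_length = 500, seed = 3,
                         alleles = c("A", "C"))
  v <- c(25, 118, 23, 24, 256, 25)
  mut <- one_point_mutation(v, g$template, point = 4, value = 25)
  expect_equal(mut, c(25L, 118L, 23L, 25L, 256L, 25L))
})

test_that("random mutations change one gene within its legal range", {
  z <- zero_fixture()
  cfg <- tiny_cfg()
  set.seed(6)
  pop <- initialize_population(z$template, cfg,
                               ga_config(population_size = 10L))
  b <- feasible_bounds(z$template, cfg)
  for (i in 1:60) {
    v <- pop$vectors[sample.int(10, 1), ]
    mut <- one_point_mutation(v, z$template, cfg)
    expect_equal(sum(mut != v), 1L)
    expect_true(isTRUE(vector_feasible(z$template, mut, cfg)))
    g <- which(mut != v)
    if (g %in% c(1, 3, 4, 6)) {
      expect_gte(mut[g], cfg$len_min); expect_lte(mut[g], cfg$len_max)
    } else if (g == 2) {
      expect_gte(mut[g], cfg$pl1_range[1]); expect_lte(mut[g],
                                                       cfg$pl1_range[2])
    } else {
      expect_gte(mut[g], cfg$pl2_range[1]); expect_lte(mut[g],
                                                       cfg$pl2_range[2])
    }
  }
})

test_that("replacement removes the two worst, ties broken by position", {
  z <- zero_fixture()
  set.seed(7)
  pop <- initialize_population(z$template, tiny_cfg(),
                               ga_config(population_size = 6L))
  pop$totals <- c(5, 9, 9, 1, 9, 3)
  child <- list(pop$vectors[1, ], pop$vectors[4, ])
  fits <- list(pop$breakdowns[[1]], pop$breakdowns[[4]])
  fits[[1]]$total <- 2; fits[[2]]$total <- 7
  old <- pop$vectors
  new <- replace_worst_two(pop, child, fits)
  # the three members tied at 9 sit at positions 2, 3, 5; the two earliest
  # are replaced
  expect_equal(unname(new$vectors[2, ]), as.integer(child[[1]]))
  expect_equal(unname(new$vectors[3, ]), as.integer(child[[2]]))
  expect_equal(new$vectors[5, ], old[5, ])
  expect_equal(new$totals[c(2, 3)], c(2, 7))
  # the best member (position 4) survives
  expect_equal(new$vectors[4, ], old[4, ])
  expect_equal(nrow(new$vectors), 6L)
})

test_that("the GA run contract holds: trace, termination, determinism", {
  z <- zero_fixture()
  cfg <- tiny_cfg()

  # max_generations 0 returns the best of the initial population
  res0 <- run_ga(z$template, cfg, ga_config(population_size = 10L,
                                            max_generations = 0L,
                                            seed = 8))
  set.seed(8)
  pop0 <- initialize_population(z$template, cfg,
                                ga_config(population_size = 10L))
  expect_equal(res0$fitness$total, min(pop0$totals))
  expect_equal(res0$generations, 0L)

  # best-so-far fitness is non-increasing and the returned best is the
  # population minimum, for several seeds
  for (s in 1:4) {
    res <- run_ga(z$template, cfg,
                  ga_config(population_size = 20L, max_generations = 150L,
                            seed = s))
    expect_true(all(diff(res$trace$best) <= 0))
    expect_equal(res$fitness$total, min(res$population$totals))
    expect_true(isTRUE(vector_feasible(z$template, res$best_vector, cfg)))
    expect_equal(nrow(res$population$vectors), 20L)
  }

  # bitwise reproducibility for a fixed seed
  r1 <- run_ga(z$template, cfg, ga_config(population_size = 15L,
                                          max_generations = 80L, seed = 9))
  r2 <- run_ga(z$template, cfg, ga_config(population_size = 15L,
                                          max_generations = 80L, seed = 9))
  expect_identical(r1$best_vector, r2$best_vector)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$primer_set$pf1, r2$primer_set$pf1)
})

test_that("GA best never beats the exhaustive minimum", {
  z <- zero_fixture()
  cfg <- constraint_config(len_min = 20L, len_max = 20L,
                           pl1_range = c(158L, 162L),
                           pl2_range = c(259L, 261L))
  ex <- exhaustive_search(z$template, cfg)
  for (s in 1:5) {
    res <- run_ga(z$template, cfg,
                  ga_config(population_size = 10L, max_generations = 100L,
                            seed = s))
    expect_gte(res$fitness$total, ex$min_total)
  }
})
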