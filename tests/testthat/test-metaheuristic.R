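test_that("gene_range matches the forced and enumerated bounds", {
  h1 <- read_newick("((A,B),C);")
  ab1 <- h1$parent[cophycollapse:::leaf_ids(h1)[["A"]]]
  expect_identical(gene_range(h1, ab1), c(1L, 1L))

  h2 <- read_newick("(((A,B),C),D);")
  ab2 <- h2$parent[cophycollapse:::leaf_ids(h2)[["A"]]]
  expect_identical(gene_range(h2, ab2), c(2L, 2L))

  h3 <- read_newick("((A,B),(C,D));")
  ab3 <- h3$parent[cophycollapse:::leaf_ids(h3)[["A"]]]
  expect_identical(gene_range(h3, ab3), c(1L, 2L))

  expect_error(gene_range(h1, h1$root), "root")
  expect_error(gene_range(h1, cophycollapse:::leaf_ids(h1)[["A"]]), "leaf")
})

test_that("random chromosomes decode to valid orderings, covering the space", {
  h1 <- read_newick("((A,B),C);")
  set.seed(1)
  expect_identical(random_chromosome(h1), 1L)   # the unique valid chromosome

  h <- read_newick("((A,B),(C,D));")
  set.seed(2)
  seenk <- character(0)
  for (i in 1:100) {
    g <- random_chromosome(h)
    ord <- cophycollapse:::decode_chromosome(h, g)
    expect_true(validate_ordering(h, ord))
    seenk <- union(seenk, paste(g, collapse = ","))
  }
  expect_length(seenk, 2L)                      # both valid orderings occur

  set.seed(99); a <- random_chromosome(h)
  set.seed(99); b <- random_chromosome(h)
  expect_identical(a, b)
})

test_that("fitness is the pushed collapse cost and is deterministic", {
  tg <- fx_congruent3()
  g <- random_chromosome(tg$host)
  expect_equal(ga_fitness(tg, g), 0)
  tg2 <- fx_loss3()
  g2 <- cophycollapse:::ga_nodes(tg2$host)
  genes2 <- default_ordering(tg2$host)$depth[g2]
  expect_equal(ga_fitness(tg2, genes2), 1)
  expect_identical(ga_fitness(tg2, genes2), ga_fitness(tg2, genes2))
})

test_that("run_ga is reproducible, monotone, and finds known optima", {
  tg <- fx_congruent3()
  res <- run_ga(tg, ga_config(population_size = 6, generations = 3,
                              rng_seed = 5))
  expect_equal(res$best_cost, 0)
  expect_equal(res$history[1L], 0)              # already optimal at init

  tg5 <- fx_switch5()
  cfg <- ga_config(population_size = 8, generations = 4, rng_seed = 7)
  r1 <- run_ga(tg5, cfg)
  r2 <- run_ga(tg5, cfg)
  expect_identical(r1$best_cost, r2$best_cost)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 0))
  expect_equal(r1$best_cost, 2)                 # DP optimum over orderings
  expect_true(audit_time_consistency(r1$best_mapping))
  expect_true(validate_ordering(tg5$host, r1$best_ordering))
})

test_that("GA search space is consistent with enumerating orderings", {
  # on a 4-leaf host both orderings exist; the best greedy cost over them
  # equals the best achieved by the GA
  tg <- read_tanglegram("((A,B),(C,D));", "((a,b),(c,d));",
                        "a\tA\nb\tC\nc\tB\nd\tD")
  h <- tg$host
  costs <- c()
  for (g1 in 1:2) {
    genes <- c(g1, 3L - g1)
    ord <- cophycollapse:::decode_chromosome(h, genes)
    if (!validate_ordering(h, ord)) next
    costs <- c(costs, ga_fitness(tg, genes))
  }
  res <- run_ga(tg, ga_config(population_size = 6, generations = 4,
                              rng_seed = 3))
  expect_equal(res$best_cost, min(costs))
})
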