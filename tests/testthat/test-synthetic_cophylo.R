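test_that("sim_params validates its inputs", {
  expect_s3_class(sim_params(8), "cophy_sim_params")
  expect_error(sim_params(8, 0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(sim_params(1), ">= 2")
})

test_that("yule_tree produces valid trees deterministically", {
  set.seed(1)
  t2 <- yule_tree(2)
  expect_identical(t2$n_leaves, 2L)
  expect_identical(t2$n_internal, 1L)
  set.seed(42); a <- write_newick(yule_tree(20))
  set.seed(42); b <- write_newick(yule_tree(20))
  expect_identical(a, b)
  expect_error(yule_tree(1), ">= 2")
})

test_that("4-tip Yule trees are balanced about 1/3 of the time", {
  set.seed(2024)
  reps <- 10000
  balanced <- 0L
  for (i in seq_len(reps)) {
    tr <- yule_tree(4)
    kids <- c(tr$left[tr$root], tr$right[tr$root])
    if (!any(tr$is_leaf[kids])) balanced <- balanced + 1L
  }
  expect_lt(abs(balanced / reps - 1 / 3), 0.02)
})

test_that("evolve_parasite honours the degenerate parameter corners", {
  set.seed(3)
  host <- yule_tree(12)
  iso <- evolve_parasite(host, sim_params(12, 1, 0, 0, 0))
  expect_identical(iso$parasite$n_leaves, host$n_leaves)
  expect_identical(anyDuplicated(iso$phi), 0L)     # leaf bijection
  expect_setequal(unname(iso$phi), host$label[host$is_leaf])

  lost <- evolve_parasite(host, sim_params(12, 0, 0, 0, 1))
  expect_identical(lost$parasite$n_leaves, 1L)
})

test_that("generated instances are valid, seeded, and round-trip", {
  p <- sim_params(8, rng_seed = 11)
  a <- generate_instance(p)
  b <- generate_instance(p)
  expect_identical(write_tanglegram(a), write_tanglegram(b))
  parts <- write_tanglegram(a)
  back <- read_tanglegram(parts$host, parts$parasite, parts$assoc)
  # node ids may be renumbered on re-read; compare at the label level
  label_map <- function(tg) {
    pl <- which(tg$parasite$is_leaf)
    stats::setNames(tg$host$label[tg$phi[pl]], tg$parasite$label[pl])
  }
  expect_identical(sort(names(label_map(back))), sort(names(label_map(a))))
  expect_identical(label_map(back)[names(label_map(a))], label_map(a))
  expect_s3_class(attr(a, "truth_log"), "data.frame")
})

test_that("a full-corpus-sized batch generates and validates", {
  set.seed(953)
  for (i in 1:953) {
    tg <- generate_instance(sim_params(6))
    expect_gte(tg$parasite$n_leaves, 2L)
    expect_true(all(tg$host$is_leaf[tg$phi[which(tg$parasite$is_leaf)]]))
  }
})

test_that("forced congruence collapses to cost zero end to end", {
  for (n in c(4, 16, 64)) {
    tg <- generate_instance(sim_params(n, 1, 0, 0, 0, rng_seed = n))
    expect_equal(mapping_cost(tree_collapse(tg)), 0)
  }
})
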