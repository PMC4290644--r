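test_that("level-ancestor queries honour the ordering depths", {
  h <- read_newick("((A,B),C);")
  ord <- default_ordering(h)              # root 0, AB 1, leaves 2
  la <- build_la_index(h, ord)
  ids <- cophycollapse:::leaf_ids(h)
  ab <- h$parent[ids[["A"]]]
  expect_identical(la_query(la, ids[["A"]], 0L), h$root)
  expect_identical(la_query(la, ids[["A"]], 1L), ab)
  expect_identical(la_query(la, h$root, 0L), h$root)
  expect_identical(la_edge(la, ids[["A"]], 1L), ids[["A"]])
  expect_error(la_edge(la, h$root, 0L), "no edge")
  # property: la_query returns the deepest ancestor at-or-above depth q
  set.seed(13)
  for (i in 1:20) {
    hh <- yule_tree(sample(4:32, 1))
    oo <- rand_ordering(hh)
    ll <- build_la_index(hh, oo)
    for (r in 1:10) {
      node <- sample(hh$n_nodes, 1)
      q <- sample(0:oo$n_internal, 1)
      a <- la_query(ll, node, q)
      expect_true(cophycollapse:::is_ancestor(hh, a, node))
      expect_lte(oo$depth[a], q)
      if (a != node) {
        expect_gt(oo$depth[cophycollapse:::la_edge(ll, node, q)], q)
      }
    }
  }
})

test_that("the 4-leaf relocation fixture goes from cost 3 to cost 2", {
  m0 <- rp4_initial_mapping()
  expect_true(audit_time_consistency(m0))
  expect_equal(mapping_cost(m0), 3)       # switch (2) + one loss at AB
  expect_equal(count_events(m0)$n_loss, 1)
  la <- build_la_index(m0$tanglegram$host, m0$ordering)
  opt <- optimal_switch_edges(m0, m0$tanglegram$parasite$root, la)
  ids <- cophycollapse:::leaf_ids(m0$tanglegram$host)
  expect_identical(opt$landing, ids[["A"]])  # relocated onto edge AB -> A
  expect_equal(opt$loss_count, 0)
  expect_equal(opt$loss_count,
               exhaustive_switch_min(m0, m0$tanglegram$parasite$root))
  m1 <- right_push(m0)
  expect_equal(mapping_cost(m1), 2)
  expect_equal(count_events(m1)$n_loss, 0)
  expect_true(audit_time_consistency(m1))
  # idempotence and error on non-switch nodes
  expect_equal(mapping_cost(right_push(m1)), 2)
  leafp <- which(m0$tanglegram$parasite$is_leaf)[1L]
  expect_error(optimal_switch_edges(m0, leafp, la), "host switch")
})

test_that("a switch between sibling leaves relocates to the pendant edges", {
  tg <- read_tanglegram("((A,B),(C,D));", "(x,y);", "x\tA\ny\tB")
  ord <- default_ordering(tg$host)        # root 0, AB 1, CD 2, leaves 3
  H <- tg$host
  ids <- cophycollapse:::leaf_ids(H)
  pl <- cophycollapse:::leaf_ids(tg$parasite)
  ev <- data.frame(node = tg$parasite$root, kind = "host_switch",
                   host = ids[["A"]], time = 1L, landing = ids[["B"]],
                   takeoff_child = pl[["x"]], landing_child = pl[["y"]],
                   pre_root = FALSE)
  m <- new_cophy_mapping(tg, ord, ev)
  la <- build_la_index(H, ord)
  opt <- optimal_switch_edges(m, tg$parasite$root, la)
  expect_identical(opt$takeoff, ids[["A"]])
  expect_identical(opt$landing, ids[["B"]])
  expect_equal(opt$loss_count, 0)
  expect_equal(opt$time, 2L)              # pushed into the final interval
})

test_that("right_push is monotone, loss-only, audit-preserving, idempotent", {
  set.seed(71)
  for (i in 1:40) {
    tg <- rand_instance(sample(4:12, 1))
    ord <- rand_ordering(tg$host)
    m0 <- tree_collapse(tg, ord)
    m1 <- right_push(m0)
    c0 <- count_events(m0); c1 <- count_events(m1)
    expect_lte(mapping_cost(m1), mapping_cost(m0))
    expect_identical(c0$n_codivergence, c1$n_codivergence)
    expect_identical(c0$n_duplication, c1$n_duplication)
    expect_identical(c0$n_host_switch, c1$n_host_switch)
    expect_lte(c1$n_loss, c0$n_loss)
    expect_true(audit_time_consistency(m1))
    m2 <- right_push(m1)
    expect_identical(m2$events, m1$events)
  }
  # zero-switch mappings come back unchanged
  m <- tree_collapse(fx_congruent3())
  expect_identical(right_push(m)$events, m$events)
})

test_that("per-switch relocation equals the exhaustive edge-pair minimum", {
  set.seed(81)
  checked <- 0
  for (i in 1:30) {
    tg <- rand_instance(sample(5:8, 1))
    ord <- rand_ordering(tg$host)
    m <- tree_collapse(tg, ord)
    sw <- m$events$node[m$events$kind == "host_switch"]
    if (!length(sw)) next
    la <- build_la_index(tg$host, ord)
    pushed <- right_push(m)
    for (p in sw) {
      opt <- optimal_switch_edges(pushed, p, la)
      expect_equal(opt$loss_count, exhaustive_switch_min(pushed, p))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})
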