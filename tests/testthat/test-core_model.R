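test_that("default_ordering matches the forced assignments on small shapes", {
  h <- read_newick("((A,B),C);")
  ord <- default_ordering(h)
  expect_identical(ord$depth[h$root], 0L)
  ab <- h$parent[cophycollapse:::leaf_ids(h)[["A"]]]
  expect_identical(ord$depth[ab], 1L)
  expect_true(all(ord$depth[h$is_leaf] == 2L))

  h2 <- read_newick("(A,B);")
  ord2 <- default_ordering(h2)
  expect_identical(ord2$depth[h2$root], 0L)
  expect_true(all(ord2$depth[h2$is_leaf] == 1L))

  h4 <- read_newick("((A,B),(C,D));")
  ord4 <- default_ordering(h4)
  ints <- setdiff(which(!h4$is_leaf), h4$root)
  expect_setequal(ord4$depth[ints], c(1L, 2L))
})

test_that("default_ordering always validates (random Yule trees)", {
  set.seed(101)
  for (i in 1:500) {
    h <- yule_tree(sample(4:128, 1))
    expect_true(validate_ordering(h, default_ordering(h)))
  }
})

test_that("validate_ordering rejects broken orderings but errors on bad input", {
  h <- read_newick("((A,B),(C,D));")
  ord <- default_ordering(h)
  expect_true(validate_ordering(h, ord))
  bad <- ord
  ints <- setdiff(which(!h$is_leaf), h$root)
  bad$depth[ints[1L]] <- 0L          # duplicates the root depth
  expect_false(validate_ordering(h, bad))
  h3 <- read_newick("((A,B),C);")
  ord3 <- default_ordering(h3)
  flip <- ord3
  ab <- h3$parent[cophycollapse:::leaf_ids(h3)[["A"]]]
  flip$depth[ab] <- 0L; flip$depth[h3$root] <- 1L  # child above parent
  expect_false(validate_ordering(h3, flip))
  short <- ord3; short$depth <- short$depth[-1]
  expect_error(validate_ordering(h3, short), "every host node")
})

test_that("schedule_cherries is depth-descending, complete, and bucketed", {
  h <- read_newick("((A,B),(C,D));")
  ord <- default_ordering(h)
  sch <- schedule_cherries(h, ord)
  expect_length(sch, h$n_internal)
  expect_true(all(diff(ord$depth[sch]) < 0))
  expect_identical(sch[length(sch)], h$root)
  expect_identical(schedule_cherries(read_newick("(A,B);"),
                                     default_ordering(read_newick("(A,B);"))),
                   read_newick("(A,B);")$root)
  set.seed(7)
  for (i in 1:25) {
    hh <- yule_tree(sample(4:40, 1))
    oo <- rand_ordering(hh)
    ss <- schedule_cherries(hh, oo)
    expect_length(ss, hh$n_internal)
    expect_true(all(diff(oo$depth[ss]) < 0))
  }
})

test_that("total_cost follows the Jungle weights and is linear in counts", {
  j <- jungle_scheme()
  expect_equal(total_cost(list(n_codivergence = 2, n_duplication = 0,
                               n_host_switch = 0, n_loss = 0), j), 0)
  expect_equal(total_cost(list(n_codivergence = 0, n_duplication = 1,
                               n_host_switch = 1, n_loss = 1), j), 4)
  expect_equal(total_cost(list(n_codivergence = 3, n_duplication = 2,
                               n_host_switch = 1, n_loss = 4), j), 8)
  expect_error(total_cost(list(n_codivergence = -1, n_duplication = 0,
                               n_host_switch = 0, n_loss = 0), j),
               "non-negative")
  set.seed(5)
  for (i in 1:20) {
    a <- as.list(stats::setNames(sample(0:9, 4, TRUE),
          c("n_codivergence", "n_duplication", "n_host_switch", "n_loss")))
    b <- as.list(stats::setNames(sample(0:9, 4, TRUE), names(a)))
    ab <- Map(`+`, a, b)
    expect_equal(total_cost(ab, j), total_cost(a, j) + total_cost(b, j))
  }
})

test_that("audit rejects hand-built violations and passes engine output", {
  tg <- fx_switch5()
  ord <- default_ordering(tg$host)
  m <- tree_collapse(tg, ord)
  expect_true(audit_time_consistency(m))

  # switch landing on an edge whose span ends before the take-off span begins
  H <- tg$host; P <- tg$parasite
  hl <- cophycollapse:::leaf_ids(H)
  pl <- cophycollapse:::leaf_ids(P)
  ab <- H$parent[hl[["A"]]]
  bad <- data.frame(node = P$root, kind = "host_switch", host = hl[["A"]],
                    time = 0L, landing = hl[["E"]],
                    takeoff_child = pl[["a"]], landing_child = pl[["e"]],
                    pre_root = FALSE)
  mbad <- new_cophy_mapping(tg, ord, bad)
  expect_false(audit_time_consistency(mbad))  # take-off edge dead at t=0

  # a child event placed before its parent's event
  tg2 <- fx_congruent3()
  ord2 <- default_ordering(tg2$host)
  H2 <- tg2$host; P2 <- tg2$parasite
  ab2 <- H2$parent[cophycollapse:::leaf_ids(H2)[["A"]]]
  ev <- data.frame(node = c(P2$root, setdiff(which(!P2$is_leaf), P2$root)),
                   kind = "codivergence",
                   host = c(ab2, H2$root),        # parent deeper than child
                   time = c(1L, 0L),
                   landing = NA_integer_, takeoff_child = NA_integer_,
                   landing_child = NA_integer_, pre_root = FALSE)
  expect_false(audit_time_consistency(new_cophy_mapping(tg2, ord2, ev)))
})

test_that("tanglegram construction enforces phi invariants", {
  h <- read_newick("((A,B),C);"); p <- read_newick("((a,b),c);")
  expect_error(tanglegram(h, p, c(a = "A", b = "B", c = "Z")), "unknown host leaf")
  expect_error(tanglegram(h, p, c(a = "A", b = "B")), "no host association")
  expect_error(tanglegram(h, p, c(a = "A", a = "B", b = "B", c = "C")),
               "more than once")
  tg <- tanglegram(h, p, c(a = "A", b = "A", c = "A"))  # shared host allowed
  expect_s3_class(tg, "cophy_tanglegram")
})
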