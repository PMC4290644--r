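# Shared fixtures: tiny tanglegrams with known optima, plus generators.

fx_congruent3 <- function() {
  read_tanglegram("((A,B),C);", "((a,b),c);", "a\tA\nb\tB\nc\tC")
}

# optimum 1: codivergence at the root + one loss
fx_loss3 <- function() {
  read_tanglegram("((A,B),C);", "(a,c);", "a\tA\nc\tC")
}

# caterpillar host, optimum 2: one host switch beats three losses
fx_switch5 <- function() {
  read_tanglegram("((((A,B),C),D),E);", "(a,e);", "a\tA\ne\tE")
}

# optimum 2 (dup + codiv + loss); the ordering is forced
fx_dup2 <- function() {
  read_tanglegram("(A,B);", "((x,y),z);", "x\tA\ny\tB\nz\tB")
}

# 4-leaf relocation fixture for right_push (forced ordering: root 0, ABC 1, AB 2)
fx_rp4 <- function() {
  read_tanglegram("(((A,B),C),D);", "(a,d);", "a\tA\nd\tD")
}

rand_instance <- function(n_leaves, seed = NULL, ...) {
  p <- sim_params(n_leaves, ..., rng_seed = seed)
  generate_instance(p)
}

rand_ordering <- function(host) {
  ch <- random_chromosome(host)
  ord <- cophycollapse:::decode_chromosome(host, ch)
  stopifnot(validate_ordering(host, ord))
  ord
}

# hand-built mapping on fx_rp4 reproducing the pre-push state with the
# switch landing one edge too high: cost 3 (switch + 1 loss)
rp4_initial_mapping <- function() {
  tg <- fx_rp4()
  ord <- default_ordering(tg$host)     # root 0, ABC 1, AB 2 (preorder ranks)
  H <- tg$host; P <- tg$parasite
  hl <- cophycollapse:::leaf_ids(H)
  pl <- cophycollapse:::leaf_ids(P)
  ab <- H$parent[hl[["A"]]]
  d_leaf <- hl[["D"]]
  proot <- P$root
  # take-off on the pendant D edge, landing on edge ABC -> AB (one loss: AB)
  ev <- data.frame(node = proot, kind = "host_switch", host = d_leaf,
                   time = 1L, landing = ab,
                   takeoff_child = pl[["d"]], landing_child = pl[["a"]],
                   pre_root = FALSE, stringsAsFactors = FALSE)
  new_cophy_mapping(tg, ord, ev)
}

# exhaustive relocation oracle: minimum losses over every valid
# (take-off edge, landing edge, time) triple for one switch event
exhaustive_switch_min <- function(m, p) {
  H <- m$tanglegram$host
  d <- m$ordering$depth
  idx <- cophycollapse:::mapping_index(m)
  s <- idx$host[idx$tko[p]]; t <- idx$host[idx$lnd[p]]
  ts <- idx$time[idx$tko[p]]; tt <- idx$time[idx$lnd[p]]
  span_lo <- ifelse(is.na(H$parent), -1L, d[H$parent])
  best <- Inf
  for (tau in 0:(m$ordering$n_internal - 1L)) {
    if (tau > ts || tau > tt) next
    if (tau < m$events$time[m$events$node == p]) next  # push only rightward
    for (ei in seq_len(H$n_nodes)) {
      if (!cophycollapse:::is_ancestor(H, ei, s) || span_lo[ei] > tau ||
          tau >= d[ei]) next
      for (ej in seq_len(H$n_nodes)) {
        if (ej == ei || !cophycollapse:::is_ancestor(H, ej, t) ||
            span_lo[ej] > tau || tau >= d[ej]) next
        loss <- cophycollapse:::path_crossings(H, ei, s) +
          cophycollapse:::path_crossings(H, ej, t)
        if (loss < best) best <- loss
      }
    }
  }
  best
}
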