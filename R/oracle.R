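#' Exact fixed-ordering reconciliation by dynamic programming (test oracle)
#'
#' Computes the minimum-cost time-consistent mapping for a *fixed* node
#' ordering, all four events allowed, by dynamic programming over
#' (parasite node, host edge, time interval) with switch transitions
#' restricted to pairs of edges alive in the same interval.  The parasite
#' root enters the host free of charge (no losses are counted above the
#' root's placement), matching the mapping accounting used everywhere in
#' the package.  This is a small-instance correctness oracle, guarded to
#' hosts of at most `size_guard` leaves.
#'
#' @param tg a [tanglegram()].
#' @param ordering a `cophy_ordering` (default [default_ordering()]).
#' @param scheme a [cost_scheme()].
#' @param size_guard refuse hosts with more leaves than this.
#' @return list with `cost` (numeric) and `mapping` (a witness
#'   `cophy_mapping` attaining it).
#' @export
exact_dp <- function(tg, ordering = NULL, scheme = jungle_scheme(),
                     size_guard = 12L) {
  H <- tg$host; P <- tg$parasite
  check_host(H)
  if (H$n_leaves > size_guard) {
    stop(structure(class = c("cophy_guard_error", "error", "condition"),
                   list(message = paste0("exact_dp refused: host has ",
                        H$n_leaves, " leaves (> guard ", size_guard, ")"),
                        call = sys.call())))
  }
  if (is.null(ordering)) ordering <- default_ordering(H)
  if (!validate_ordering(H, ordering)) stop("invalid ordering")
  d <- ordering$depth
  n_int <- ordering$n_internal
  m <- H$n_nodes; k <- P$n_nodes
  INF <- 1e15
  span_lo <- ifelse(is.na(H$parent), -1L, d[H$parent])
  span_hi <- ifelse(H$is_leaf, n_int, d)
  taus <- -1:(n_int - 1L)
  ti <- function(tau) tau + 2L
  alive <- lapply(taus, function(tau) which(span_lo <= tau & tau < span_hi))
  post <- tree_postorder(P)
  # C[p, w, ti(tau)]
  C <- array(INF, dim = c(k, m, n_int + 1L))
  for (p in which(P$is_leaf)) {
    target <- tg$phi[p]
    for (w in seq_len(m)) {
      if (is_ancestor(H, w, target)) {
        base <- scheme$w_loss * path_crossings(H, w, target)
        ok <- taus[span_lo[w] <= taus & taus < span_hi[w]]
        C[p, w, ti(ok)] <- base
      }
    }
  }
  pint <- post[!P$is_leaf[post]]
  for (tau in rev(taus)) {
    aw <- alive[[ti(tau)]]
    for (p in pint) {
      c1 <- P$left[p]; c2 <- P$right[p]
      v1 <- C[c1, , ti(tau)]; v2 <- C[c2, , ti(tau)]
      # cheapest landing over alive edges, with an exclusion slot
      a1 <- v1[aw]; a2 <- v2[aw]
      o1 <- order(a1)[seq_len(min(2L, length(a1)))]
      o2 <- order(a2)[seq_len(min(2L, length(a2)))]
      for (w in aw) {
        best <- INF
        # duplication in this interval
        cand <- scheme$w_duplication + v1[w] + v2[w]
        if (cand < best) best <- cand
        # host switch: one child stays on w, the other lands elsewhere
        land2 <- if (aw[o2[1L]] != w) a2[o2[1L]] else
          if (length(o2) > 1L) a2[o2[2L]] else INF
        land1 <- if (aw[o1[1L]] != w) a1[o1[1L]] else
          if (length(o1) > 1L) a1[o1[2L]] else INF
        cand <- scheme$w_host_switch + min(v1[w] + land2, v2[w] + land1)
        if (cand < best) best <- cand
        # continue to the next boundary on this edge
        nxt <- tau + 1L
        if (nxt < span_hi[w]) {
          cand <- C[p, w, ti(nxt)]
          if (cand < best) best <- cand
        } else if (!H$is_leaf[w]) {  # nxt == d(w): the divergence at w
          wl <- H$left[w]; wr <- H$right[w]
          cand <- scheme$w_codivergence +
            min(C[c1, wl, ti(nxt)] + C[c2, wr, ti(nxt)],
                C[c1, wr, ti(nxt)] + C[c2, wl, ti(nxt)])
          if (cand < best) best <- cand
          cand <- scheme$w_loss + min(C[p, wl, ti(nxt)], C[p, wr, ti(nxt)])
          if (cand < best) best <- cand
        }
        C[p, w, ti(tau)] <- best
      }
    }
  }
  proot <- P$root
  sheet <- C[proot, , , drop = FALSE]
  bestval <- min(sheet)
  hit <- which(sheet == bestval, arr.ind = TRUE)[1L, ]
  w0 <- hit[[2L]]; t0 <- taus[hit[[3L]]]
  # ---- witness reconstruction --------------------------------------------
  ev <- new.env(parent = emptyenv())
  ev$rows <- list()
  emit <- function(node, kind, host, time, landing = NA_integer_,
                   tko = NA_integer_, lnd = NA_integer_, preroot = FALSE) {
    ev$rows[[length(ev$rows) + 1L]] <- data.frame(
      node = node, kind = kind, host = host, time = time, landing = landing,
      takeoff_child = tko, landing_child = lnd, pre_root = preroot,
      stringsAsFactors = FALSE)
  }
  eps <- 1e-9
  rec <- function(p, w, tau) {
    if (P$is_leaf[p]) return(invisible())
    val <- C[p, w, ti(tau)]
    c1 <- P$left[p]; c2 <- P$right[p]
    nxt <- tau + 1L
    if (nxt < span_hi[w] && abs(C[p, w, ti(nxt)] - val) < eps) {
      return(rec(p, w, nxt))
    }
    if (nxt == span_hi[w] && !H$is_leaf[w]) {
      wl <- H$left[w]; wr <- H$right[w]
      for (pr in list(c(wl, wr), c(wr, wl))) {
        cand <- scheme$w_codivergence +
          C[c1, pr[1L], ti(nxt)] + C[c2, pr[2L], ti(nxt)]
        if (abs(cand - val) < eps) {
          emit(p, "codivergence", w, d[w])
          rec(c1, pr[1L], nxt); rec(c2, pr[2L], nxt)
          return(invisible())
        }
      }
      for (ch in c(wl, wr)) {
        cand <- scheme$w_loss + C[p, ch, ti(nxt)]
        if (abs(cand - val) < eps) return(rec(p, ch, nxt))
      }
    }
    cand <- scheme$w_duplication + C[c1, w, ti(tau)] + C[c2, w, ti(tau)]
    if (abs(cand - val) < eps) {
      emit(p, "duplication", w, max(tau, 0L), preroot = is.na(H$parent[w]))
      rec(c1, w, tau); rec(c2, w, tau)
      return(invisible())
    }
    for (w2 in alive[[ti(tau)]]) {
      if (w2 == w) next
      if (abs(scheme$w_host_switch + C[c1, w, ti(tau)] + C[c2, w2, ti(tau)] -
              val) < eps) {
        emit(p, "host_switch", w, tau, landing = w2, tko = c1, lnd = c2)
        rec(c1, w, tau); rec(c2, w2, tau)
        return(invisible())
      }
      if (abs(scheme$w_host_switch + C[c2, w, ti(tau)] + C[c1, w2, ti(tau)] -
              val) < eps) {
        emit(p, "host_switch", w, tau, landing = w2, tko = c2, lnd = c1)
        rec(c2, w, tau); rec(c1, w2, tau)
        return(invisible())
      }
    }
    stop("internal: DP witness reconstruction failed at node ", p)
  }
  rec(proot, w0, t0)
  events <- do.call(rbind, ev$rows)
  mp <- new_cophy_mapping(tg, ordering, events)
  list(cost = bestval, mapping = mp)
}

#' Switch-free reconciliation (Page-style reconciled tree analysis)
#'
#' Classical LCA reconciliation using codivergence, duplication and loss
#' only: every parasite internal node maps to the least common ancestor of
#' its children's images; a duplication is declared whenever a child shares
#' its parent's image.  Runs in time linear in the input (up to the depth
#' of the LCA walks) and is optimal among switch-free mappings; the result
#' does not depend on the node ordering.
#'
#' @param tg a [tanglegram()].
#' @param ordering a `cophy_ordering` used only to timestamp events for the
#'   audit (default [default_ordering()]).
#' @return a `cophy_mapping`.
#' @export
page_reconcile <- function(tg, ordering = NULL) {
  H <- tg$host; P <- tg$parasite
  check_host(H)
  if (is.null(ordering)) ordering <- default_ordering(H)
  d <- ordering$depth
  M <- integer(P$n_nodes)
  lca <- function(a, b) {
    while (!is_ancestor(H, a, b)) a <- H$parent[a]
    a
  }
  rows <- list()
  for (p in tree_postorder(P)) {
    if (P$is_leaf[p]) { M[p] <- tg$phi[p]; next }
    c1 <- P$left[p]; c2 <- P$right[p]
    M[p] <- lca(M[c1], M[c2])
    if (M[p] == M[c1] || M[p] == M[c2]) {
      pre <- is.na(H$parent[M[p]])
      tm <- if (pre) 0L else d[H$parent[M[p]]]
      rows[[length(rows) + 1L]] <- data.frame(
        node = p, kind = "duplication", host = M[p], time = tm,
        landing = NA_integer_, takeoff_child = NA_integer_,
        landing_child = NA_integer_, pre_root = pre,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        node = p, kind = "codivergence", host = M[p], time = d[M[p]],
        landing = NA_integer_, takeoff_child = NA_integer_,
        landing_child = NA_integer_, pre_root = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  new_cophy_mapping(tg, ordering, do.call(rbind, rows))
}

#' Edge-only mapping baseline (duplication and host switch only)
#'
#' Reconstructs the minimum-cost mapping restricted to duplication and
#' host-switch events placed in the final timing interval (the edge set
#' adjacent to the host leaves).  Realised, as in its original description,
#' by running the fixed-ordering dynamic program with the codivergence and
#' loss weights set to a prohibitive penalty; any ordering gives the same
#' cost.  An all-events optimum can never be more expensive than this
#' mapping, so it is an upper-bound certificate for greedy methods.
#'
#' @inheritParams exact_dp
#' @return list with `cost` (under the *real* `scheme`) and `mapping`.
#' @export
edge_only_map <- function(tg, ordering = NULL, scheme = jungle_scheme(),
                          size_guard = 12L) {
  big <- 1e7
  banned <- cost_scheme(codivergence = big,
                        duplication = scheme$w_duplication,
                        host_switch = scheme$w_host_switch, loss = big)
  res <- exact_dp(tg, ordering, banned, size_guard)
  list(cost = mapping_cost(res$mapping, scheme), mapping = res$mapping)
}

# Second, deliberately dumb oracle: plain recursive enumeration over event
# times and landing edges, no memoisation, no wait-compression.  Used in the
# test-suite to cross-validate exact_dp on tiny instances.
#' @keywords internal
dumb_enumerate_cost <- function(tg, ordering = NULL,
                                scheme = jungle_scheme()) {
  H <- tg$host; P <- tg$parasite
  if (is.null(ordering)) ordering <- default_ordering(H)
  d <- ordering$depth
  n_int <- ordering$n_internal
  span_lo <- ifelse(is.na(H$parent), -1L, d[H$parent])
  span_hi <- ifelse(H$is_leaf, n_int, d)
  INF <- 1e15
  go <- function(p, w, tau) {
    if (tau < span_lo[w] || tau >= span_hi[w]) return(INF)
    if (P$is_leaf[p]) {
      t <- tg$phi[p]
      if (!is_ancestor(H, w, t)) return(INF)
      return(scheme$w_loss * path_crossings(H, w, t))
    }
    c1 <- P$left[p]; c2 <- P$right[p]
    best <- INF
    for (t2 in tau:(span_hi[w] - 1L)) {
      best <- min(best, scheme$w_duplication + go(c1, w, t2) + go(c2, w, t2))
      for (w2 in seq_len(H$n_nodes)) {
        if (w2 == w || span_lo[w2] > t2 || t2 >= span_hi[w2]) next
        best <- min(best,
                    scheme$w_host_switch + go(c1, w, t2) + go(c2, w2, t2),
                    scheme$w_host_switch + go(c2, w, t2) + go(c1, w2, t2))
      }
    }
    if (!H$is_leaf[w]) {
      b <- d[w]
      for (pr in list(c(H$left[w], H$right[w]), c(H$right[w], H$left[w]))) {
        best <- min(best, scheme$w_codivergence +
                      go(c1, pr[1L], b) + go(c2, pr[2L], b))
      }
      for (ch in c(H$left[w], H$right[w])) {
        best <- min(best, scheme$w_loss + go(p, ch, b))
      }
    }
    best
  }
  best <- INF
  for (w in seq_len(H$n_nodes)) {
    for (tau in span_lo[w]:(span_hi[w] - 1L)) {
      best <- min(best, go(P$root, w, tau))
    }
  }
  best
}
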