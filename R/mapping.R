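#' Cophylogeny mappings
#'
#' A `cophy_mapping` places every parasite internal node in the host with
#' exactly one non-loss event and an integer time index under the node
#' ordering:
#'
#' * codivergence: anchored AT a host internal node `h`, time `d(h)`;
#' * duplication: anchored ON the edge above host node `w` (lower end `w`),
#'   at a time inside that edge's interval `[d(parent(w)), d(w))`; leftover
#'   parasite nodes appended above the host root carry `pre_root = TRUE`;
#' * host switch: a take-off edge (lower end `host`) and a landing edge
#'   (lower end `landing`) that are both alive at the event time; the
#'   take-off child stays below the take-off edge, the landing child below
#'   the landing edge.
#'
#' Parasite leaves are placed at `phi(leaf)` at the common leaf time.
#' Loss events are *derived*, not stored: each parasite lineage is charged
#' one loss per host divergence it crosses between its parent's event and
#' its own anchor (nothing is charged above the parasite root, matching the
#' "ignore the remaining host" terminal rule).  This derivation makes the
#' Jungle decomposition of the total cost an identity and makes switch-edge
#' relocation provably cost-monotone.
#'
#' @param tg a [tanglegram()].
#' @param ordering a `cophy_ordering` for the host.
#' @param events data.frame with one row per parasite internal node:
#'   columns `node`, `kind`, `host`, `time`, `landing`, `takeoff_child`,
#'   `landing_child`, `pre_root`.
#' @param op_count elementary operation counter (engine bookkeeping).
#' @return an object of class `cophy_mapping`.
#' @export
new_cophy_mapping <- function(tg, ordering, events, op_count = NA_real_) {
  P <- tg$parasite
  ints <- which(!P$is_leaf)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(node = integer(0), kind = character(0),
                         host = integer(0), time = integer(0),
                         landing = integer(0), takeoff_child = integer(0),
                         landing_child = integer(0), pre_root = logical(0),
                         stringsAsFactors = FALSE)
  }
  if (nrow(events) != length(ints) ||
      !setequal(events$node, ints)) {
    stop("events must contain exactly one row per parasite internal node")
  }
  events <- events[order(match(events$node, ints)), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(tanglegram = tg, ordering = ordering, events = events,
                 op_count = op_count),
            class = "cophy_mapping")
}

#' @export
print.cophy_mapping <- function(x, ...) {
  ct <- count_events(x)
  cat("<cophy_mapping> ", ct$n_codivergence, " codivergence, ",
      ct$n_duplication, " duplication, ", ct$n_host_switch, " host switch, ",
      ct$n_loss, " loss; Jungle cost ",
      total_cost(ct, jungle_scheme()), "\n", sep = "")
  invisible(x)
}

# fast per-node lookup vectors for a mapping
#' @keywords internal
mapping_index <- function(m) {
  P <- m$tanglegram$parasite
  n <- P$n_nodes
  kind <- rep(NA_character_, n); host <- rep(NA_integer_, n)
  time <- rep(NA_integer_, n); landing <- rep(NA_integer_, n)
  tko <- rep(NA_integer_, n); lnd <- rep(NA_integer_, n)
  prer <- rep(FALSE, n)
  ev <- m$events
  kind[ev$node] <- ev$kind; host[ev$node] <- ev$host
  time[ev$node] <- ev$time; landing[ev$node] <- ev$landing
  tko[ev$node] <- ev$takeoff_child; lnd[ev$node] <- ev$landing_child
  prer[ev$node] <- ev$pre_root
  leaves <- P$is_leaf
  host[leaves] <- m$tanglegram$phi[leaves]
  time[leaves] <- m$ordering$n_internal
  kind[leaves] <- "leaf"
  list(kind = kind, host = host, time = time, landing = landing,
       tko = tko, lnd = lnd, pre_root = prer)
}

# start node b of the lineage leading to child `c` of internal parasite `p`
#' @keywords internal
lineage_start <- function(m, idx, p, c) {
  H <- m$tanglegram$host
  switch(idx$kind[p],
    codivergence = {
      h <- idx$host[p]
      tc <- idx$host[c]  # child anchor (target)
      lf <- H$left[h]
      if (is_ancestor(H, lf, tc)) lf else H$right[h]
    },
    duplication = idx$host[p],
    host_switch = if (!is.na(idx$lnd[p]) && idx$lnd[p] == c) idx$landing[p]
                  else idx$host[p],
    stop("internal: unknown event kind ", idx$kind[p]))
}

#' Tally events of a mapping (losses derived)
#'
#' @param m a `cophy_mapping`.
#' @return list with `n_codivergence`, `n_duplication`, `n_host_switch`,
#'   `n_loss`.
#' @export
count_events <- function(m) {
  idx <- mapping_index(m)
  H <- m$tanglegram$host
  P <- m$tanglegram$parasite
  n_loss <- 0L
  for (p in m$events$node) {
    for (c in c(P$left[p], P$right[p])) {
      b <- lineage_start(m, idx, p, c)
      n_loss <- n_loss + path_crossings(H, b, idx$host[c])
    }
  }
  kinds <- m$events$kind
  list(n_codivergence = sum(kinds == "codivergence"),
       n_duplication = sum(kinds == "duplication"),
       n_host_switch = sum(kinds == "host_switch"),
       n_loss = n_loss)
}

#' Cost of a mapping under a cost scheme
#' @param m a `cophy_mapping`.
#' @param scheme a [cost_scheme()].
#' @return numeric scalar.
#' @export
mapping_cost <- function(m, scheme = jungle_scheme()) {
  total_cost(count_events(m), scheme)
}

#' Materialised loss events of a mapping
#'
#' One row per crossed host divergence: the parasite lineage (identified by
#' the child node it leads to), the host node whose divergence it failed to
#' track, and the time index of that divergence.
#'
#' @param m a `cophy_mapping`.
#' @return data.frame with columns `lineage`, `host_node`, `time`.
#' @export
mapping_losses <- function(m) {
  idx <- mapping_index(m)
  H <- m$tanglegram$host
  P <- m$tanglegram$parasite
  lineage <- integer(0); host_node <- integer(0)
  for (p in m$events$node) {
    for (c in c(P$left[p], P$right[p])) {
      b <- lineage_start(m, idx, p, c)
      z <- path_crossed_nodes(H, b, idx$host[c])
      lineage <- c(lineage, rep(c, length(z)))
      host_node <- c(host_node, z)
    }
  }
  data.frame(lineage = lineage, host_node = host_node,
             time = m$ordering$depth[host_node])
}

#' Audit a mapping for time consistency and structural feasibility
#'
#' Returns `TRUE` iff (a) every parasite child's event happens no earlier
#' than its parent's event, with each child's anchor inside the host subtree
#' its lineage starts from (and, for a codivergence, the two children on
#' distinct sides of the anchor node), and (b) every host switch's take-off
#' and landing edges are both alive at the switch's time index, i.e. the
#' edges share a time interval of the ordering.  A mapping that fails is
#' biologically infeasible.
#'
#' @param m a `cophy_mapping`.
#' @return logical scalar; on `FALSE` the attribute `"reason"` names the
#'   first violation.
#' @export
audit_time_consistency <- function(m) {
  idx <- mapping_index(m)
  H <- m$tanglegram$host
  P <- m$tanglegram$parasite
  d <- m$ordering$depth
  fail <- function(...) structure(FALSE, reason = paste0(...))
  for (i in seq_len(nrow(m$events))) {
    p <- m$events$node[i]
    kind <- idx$kind[p]
    tp <- idx$time[p]
    kids <- c(P$left[p], P$right[p])
    for (c in kids) {
      if (idx$time[c] < tp) {
        return(fail("parasite node ", c, " event (t=", idx$time[c],
                    ") precedes its parent ", p, " (t=", tp, ")"))
      }
      b <- lineage_start(m, idx, p, c)
      if (!is_ancestor(H, b, idx$host[c])) {
        return(fail("child ", c, " anchored at host ", idx$host[c],
                    " outside its lineage start ", b))
      }
    }
    if (kind == "codivergence") {
      h <- idx$host[p]
      if (H$is_leaf[h]) return(fail("codivergence anchored at a host leaf"))
      if (tp != d[h]) return(fail("codivergence at host ", h,
                                  " must use time ", d[h]))
      b1 <- lineage_start(m, idx, p, kids[1L])
      b2 <- lineage_start(m, idx, p, kids[2L])
      if (b1 == b2) {
        return(fail("codivergence children both descend host side ", b1))
      }
    } else if (kind == "duplication") {
      w <- idx$host[p]
      if (idx$pre_root[p]) {
        if (w != H$root) return(fail("pre-root duplication not on root edge"))
      } else {
        lo <- if (is.na(H$parent[w])) -1L else d[H$parent[w]]
        if (tp < lo || tp >= d[w]) {
          return(fail("duplication time ", tp, " outside edge interval [",
                      lo, ",", d[w], ")"))
        }
      }
    } else if (kind == "host_switch") {
      w <- idx$host[p]; y <- idx$landing[p]
      if (is.na(y)) return(fail("host switch without landing edge"))
      if (w == y) return(fail("host switch take-off and landing coincide"))
      for (e in c(w, y)) {
        lo <- if (is.na(H$parent[e])) -1L else d[H$parent[e]]
        if (tp < lo || tp >= d[e]) {
          return(fail("switch time ", tp, " outside span [", lo, ",", d[e],
                      ") of edge below host ", if (e == w) "take-off" else "landing"))
        }
      }
      if (!setequal(c(idx$tko[p], idx$lnd[p]), kids)) {
        return(fail("switch children labels do not match parasite topology"))
      }
    } else {
      return(fail("unknown event kind ", kind))
    }
  }
  TRUE
}

#' Ordered event history of a mapping
#'
#' All events (including materialised losses) sorted by time index, parents
#' before descendants at equal times.
#'
#' @param m a `cophy_mapping`.
#' @return data.frame with columns `kind`, `node` (parasite node or lineage),
#'   `host`, `time`, `landing`.
#' @export
event_history <- function(m) {
  P <- m$tanglegram$parasite
  ev <- m$events
  base <- data.frame(kind = ev$kind, node = ev$node, host = ev$host,
                     time = ev$time, landing = ev$landing)
  ls <- mapping_losses(m)
  if (nrow(ls)) {
    base <- rbind(base, data.frame(kind = "loss", node = ls$lineage,
                                   host = ls$host_node, time = ls$time,
                                   landing = NA_integer_))
  }
  base[order(base$time, P$enter[base$node]), , drop = FALSE]
}
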