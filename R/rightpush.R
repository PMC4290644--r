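#' Level-ancestor index over the host tree
#'
#' Jump-pointer (binary lifting) structure keyed by the ordering depths:
#' after linear-ish preprocessing, `la_query()` returns the unique ancestor
#' `a` of a node with `d(a) <= q < d(child-on-path)`.  The collapse
#' ordering makes depths strictly increasing along every root path, so the
#' query is a monotone search over jump pointers.
#'
#' @param host a [cophy_tree()].
#' @param ordering a valid `cophy_ordering`.
#' @return an object of class `cophy_la_index`.
#' @export
build_la_index <- function(host, ordering) {
  if (!validate_ordering(host, ordering)) stop("invalid ordering")
  n <- host$n_nodes
  K <- max(1L, ceiling(log2(n)))
  up <- matrix(NA_integer_, nrow = K, ncol = n)
  up[1L, ] <- host$parent
  if (K > 1L) {
    for (j in 2:K) {
      prev <- up[j - 1L, ]
      up[j, ] <- ifelse(is.na(prev), NA_integer_, prev[prev])
      # note: prev[prev] with NA indices yields NA, which is what we want
    }
  }
  structure(list(up = up, depth = ordering$depth, K = K, host = host),
            class = "cophy_la_index")
}

#' Level-ancestor query
#'
#' @param la a [build_la_index()].
#' @param node a host node id.
#' @param q a depth (time) value.
#' @return the deepest ancestor-or-self `a` of `node` with `d(a) <= q`.
#'   `la_edge()` additionally returns the edge containing interval `q` on
#'   the root path of `node` as its lower endpoint (requires
#'   `q < d(node)`).
#' @export
la_query <- function(la, node, q) {
  d <- la$depth
  if (d[node] <= q) return(node)
  la$host$parent[la_edge(la, node, q)]
}

#' @rdname la_query
#' @export
la_edge <- function(la, node, q) {
  d <- la$depth
  if (d[node] <= q) stop("no edge below depth ", q, " on the path to node ", node)
  a <- node
  for (j in la$K:1) {
    b <- la$up[j, a]
    if (!is.na(b) && d[b] > q) a <- b
  }
  a  # lower endpoint: d(parent(a)) <= q < d(a)
}

#' Optimal take-off/landing edges for one host switch
#'
#' For a switch event of parasite node `p` with children anchored at host
#' positions `s` (take-off side) and `t` (landing side), finds the deepest
#' shared time interval compatible with the children's own event times and
#' returns the pair of edges alive in that interval on the two root paths,
#' together with the number of loss events remaining between the relocated
#' edges and the children.  Pushing an edge never moves it above its
#' current position.
#'
#' @param m a `cophy_mapping`.
#' @param p a parasite internal node whose event is a host switch.
#' @param la a [build_la_index()] for the mapping's host and ordering.
#' @return list with `takeoff` (lower end of e_i), `landing` (lower end of
#'   e_j), `time` (relocated time index) and `loss_count`.
#' @export
optimal_switch_edges <- function(m, p, la) {
  idx <- mapping_index(m)
  if (is.na(idx$kind[p]) || idx$kind[p] != "host_switch") {
    stop("parasite node ", p, " does not carry a host switch event")
  }
  H <- m$tanglegram$host
  d <- m$ordering$depth
  ct <- idx$tko[p]; cl <- idx$lnd[p]
  s <- idx$host[ct]; t <- idx$host[cl]
  cap <- min(idx$time[ct], idx$time[cl], d[s] - 1L, d[t] - 1L)
  if (cap < idx$time[p]) {
    stop("internal: relocation bound below current switch time")
  }
  z_i <- la_edge(la, s, cap)
  z_j <- la_edge(la, t, cap)
  if (z_i == z_j) stop("internal: take-off and landing collapse to one edge")
  list(takeoff = z_i, landing = z_j, time = cap,
       loss_count = path_crossings(H, z_i, s) + path_crossings(H, z_j, t))
}

#' Right Push: relocate host switches towards the leaves
#'
#' Linear post-processing pass that walks the parasite tree bottom-up
#' (children before parents, so descendants are settled first) and moves
#' every host switch's take-off and landing edges to the deepest time
#' interval compatible with the children's events.  Only loss events can
#' change, and only downwards: relocating the landing edge removes the
#' crossings between the old and new landing points, while relocating the
#' take-off edge is cost-neutral (the crossings move between the parent
#' lineage and the take-off lineage, a telescoping sum).  The event order
#' and all codivergence/duplication/switch counts are preserved, so the
#' output remains time-consistent.  Idempotent.
#'
#' @param m a `cophy_mapping`.
#' @return a `cophy_mapping` with `mapping_cost(out) <= mapping_cost(m)`.
#' @export
right_push <- function(m) {
  ev <- m$events
  if (!any(ev$kind == "host_switch")) return(m)
  la <- build_la_index(m$tanglegram$host, m$ordering)
  P <- m$tanglegram$parasite
  work <- m
  row_of <- match(seq_len(P$n_nodes), work$events$node)
  for (p in tree_postorder(P)) {
    row <- row_of[p]
    if (is.na(row) || work$events$kind[row] != "host_switch") next
    opt <- optimal_switch_edges(work, p, la)
    work$events$host[row] <- opt$takeoff
    work$events$landing[row] <- opt$landing
    work$events$time[row] <- opt$time
  }
  work$op_count <- m$op_count + 4 * sum(ev$kind == "host_switch") +
    m$tanglegram$host$n_nodes
  work
}
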