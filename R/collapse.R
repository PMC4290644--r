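#' Collapse engine configuration
#'
#' @param hybrids enable the four two-event hybrid patterns.
#' @param dup_switch keep the duplication-switch hybrid enabled (it is a
#'   default pattern; set `FALSE` to drop it while keeping the other three).
#' @param disabled character vector of pattern kinds to disable individually
#'   (`"CODIV_SWITCH"`, `"DUP_SWITCH"`, `"LOSS_SWITCH"`, `"DOUBLE_SWITCH"`).
#' @param dfs_levels bound on the number of parasite levels the pattern
#'   detection may walk through (base patterns need 2, hybrids 4); kept as a
#'   visible constant — detection never looks past
#'   leaf/sibling/parent/parent's-other-child.
#' @return a `cophy_collapse_config` list.
#' @export
collapse_config <- function(hybrids = TRUE, dup_switch = TRUE,
                            disabled = character(), dfs_levels = 4L) {
  if (!dup_switch) disabled <- union(disabled, "DUP_SWITCH")
  if (!hybrids) {
    disabled <- union(disabled, c("CODIV_SWITCH", "DUP_SWITCH",
                                  "LOSS_SWITCH", "DOUBLE_SWITCH"))
  }
  structure(list(hybrids = hybrids, disabled = disabled,
                 dfs_levels = as.integer(dfs_levels)),
            class = "cophy_collapse_config")
}

# selection priority on cost ties: hybrids outrank the base pattern they
# extend so a tied hybrid wins and commits both events at the deep position
.pattern_priority <- c(CODIVERGENCE = 1, CODIV_SWITCH = 2, DOUBLE_SWITCH = 3,
                       LOSS_SWITCH = 4, DUP_SWITCH = 5, DUPLICATION = 6,
                       HOST_SWITCH = 7, DEFER_CODIV = 8)

#' @keywords internal
pattern_cost <- function(kind, scheme) {
  switch(kind,
    CODIVERGENCE = scheme$w_codivergence,
    DUPLICATION = scheme$w_duplication,
    HOST_SWITCH = scheme$w_host_switch,
    CODIV_SWITCH = scheme$w_codivergence + scheme$w_host_switch,
    DUP_SWITCH = scheme$w_duplication + scheme$w_host_switch,
    LOSS_SWITCH = scheme$w_loss + scheme$w_host_switch,
    DOUBLE_SWITCH = 2 * scheme$w_host_switch,
    # one-level lookahead: lose the cherry now, codiverge (for certain) at
    # its parent -- available when the switch partner sits exactly on the
    # host cherry's live sibling
    DEFER_CODIV = scheme$w_loss + scheme$w_codivergence,
    stop("unknown pattern kind ", kind))
}

#' Create a collapse state
#'
#' Working state of the collapse loop.  The host needs only a merge map
#' (cherries collapse bottom-up into their parent, tracked union-find
#' style), the live association is `pos` composed with that merge map, and
#' candidate parasite cherries are held in per-host-node pending lists that
#' are spliced into the parent when a cherry collapses, so every pending
#' pattern is allocated upward in O(1) and examined only when its host
#' position is processed.
#'
#' @param tg a [tanglegram()].
#' @param ordering a valid `cophy_ordering`.
#' @param scheme a [cost_scheme()].
#' @param config a [collapse_config()].
#' @return an environment of class `cophy_collapse_state`.
#' @export
collapse_state <- function(tg, ordering = NULL, scheme = jungle_scheme(),
                           config = collapse_config()) {
  H <- tg$host; P <- tg$parasite
  check_host(H)
  if (is.null(ordering)) ordering <- default_ordering(H)
  if (!validate_ordering(H, ordering)) stop("invalid ordering")
  st <- new.env(parent = emptyenv())
  st$tg <- tg; st$H <- H; st$P <- P
  st$d <- ordering$depth; st$ordering <- ordering
  st$scheme <- scheme; st$config <- config
  st$pos <- tg$phi                     # anchor position at liveness time
  st$uf <- seq_len(H$n_nodes)          # host merge map (collapsed -> parent)
  st$p_live <- P$is_leaf               # parasite live-leaf flags
  st$pend <- vector("list", H$n_nodes) # pending parasite cherries (parent id)
  for (q in which(!P$is_leaf)) {
    if (P$is_leaf[P$left[q]] && P$is_leaf[P$right[q]]) {
      for (h in unique(tg$phi[c(P$left[q], P$right[q])])) {
        st$pend[[h]] <- c(st$pend[[h]], q)
      }
    }
  }
  st$ev_node <- integer(0); st$ev_kind <- character(0)
  st$ev_host <- integer(0); st$ev_time <- integer(0)
  st$ev_landing <- integer(0); st$ev_tko <- integer(0)
  st$ev_lnd <- integer(0); st$ev_preroot <- logical(0)
  st$ops <- 0
  st$last_live <- NA_integer_
  st$last_pair <- NA_integer_
  st$match_idx <- 0L
  class(st) <- "cophy_collapse_state"
  st
}

# live host position of a collapsed-away node (path-halving find)
#' @keywords internal
uf_find <- function(st, h) {
  while (st$uf[h] != h) {
    st$uf[h] <- st$uf[st$uf[h]]
    h <- st$uf[h]
    st$ops <- st$ops + 1
  }
  h
}

#' @keywords internal
live_pos <- function(st, x) uf_find(st, st$pos[x])

#' @keywords internal
record_event <- function(st, node, kind, host, time, landing = NA_integer_,
                         tko = NA_integer_, lnd = NA_integer_,
                         preroot = FALSE) {
  st$ev_node <- c(st$ev_node, node); st$ev_kind <- c(st$ev_kind, kind)
  st$ev_host <- c(st$ev_host, host); st$ev_time <- c(st$ev_time, time)
  st$ev_landing <- c(st$ev_landing, landing)
  st$ev_tko <- c(st$ev_tko, tko); st$ev_lnd <- c(st$ev_lnd, lnd)
  st$ev_preroot <- c(st$ev_preroot, preroot)
  st$ops <- st$ops + 1
}

#' Detect local patterns at a host cherry
#'
#' Classifies every pending parasite cherry whose live position touches the
#' host cherry against the pattern table.  Per candidate the walk is a
#' bounded depth-first search through the parasite tree: the two cherry
#' leaves, their parent and the parent's other child — at most 4 parasite
#' levels, a constant.  Hybrid variants are emitted alongside their base
#' pattern when the extension applies and is enabled.  Pending cherries that
#' do not (yet) touch the host cherry are retained for the parent.
#'
#' @param st a [collapse_state()].
#' @param cherry list with `i_left`, `i_right`, `i_parent` (host node ids).
#' @return list of pattern matches (possibly empty).
#' @export
detect_patterns <- function(st, cherry) {
  A <- cherry$i_left; B <- cherry$i_right
  qs <- unique(as.integer(c(st$pend[[A]], st$pend[[B]], st$pend[[cherry$i_parent]])))
  st$pend[[A]] <- integer(0)
  st$pend[[B]] <- integer(0)
  st$pend[[cherry$i_parent]] <- integer(0)
  st$ops <- st$ops + length(qs) + 1
  res <- classify_pairs(st, cherry, qs)
  # unmatched-but-live cherries wait at the merged node for the parent
  st$pend[[cherry$i_parent]] <- res$leftover
  res$matches
}

# classify pending parasite cherries (given by their parent node ids)
#' @keywords internal
classify_pairs <- function(st, cherry, qs) {
  A <- cherry$i_left; B <- cherry$i_right; v <- cherry$i_parent
  P <- st$P; H <- st$H
  inside <- c(A, B)
  matches <- list()
  leftover <- integer(0)
  disabled <- st$config$disabled
  idx <- st$match_idx
  for (q in qs) {
    x <- P$left[q]; s <- P$right[q]
    st$ops <- st$ops + 1
    if (!st$p_live[x] || !st$p_live[s]) next       # consumed: drop the entry
    px <- live_pos(st, x); ps <- live_pos(st, s)
    if (!(px %in% inside)) {                        # orient x inside
      tmp <- x; x <- s; s <- tmp
      tmp <- px; px <- ps; ps <- tmp
    }
    if (!(px %in% inside)) { leftover <- c(leftover, q); next }
    in_s <- ps %in% inside
    # hybrid context: the cherry parent's other child, one level further up
    gp <- P$parent[q]
    r <- if (!is.na(gp)) {
      rr <- if (P$left[gp] == q) P$right[gp] else P$left[gp]
      if (st$p_live[rr]) rr else NA_integer_
    } else NA_integer_
    pr <- if (is.na(r)) NA_integer_ else live_pos(st, r)
    st$ops <- st$ops + 2
    add <- function(kind, ...) {
      idx <<- idx + 1L
      matches[[length(matches) + 1L]] <<- c(
        list(kind = kind, i_left = A, i_right = B, i_parent = v,
             p_left = x, p_right = s, p_parent = q, idx = idx), list(...))
    }
    outside_ok <- function(pp) !(pp %in% c(A, B, v))
    if (in_s && px != ps) {                        # spans both cherry leaves
      add("CODIVERGENCE")
      if (!is.na(r) && outside_ok(pr) && !is.na(H$parent[v]) &&
          !("CODIV_SWITCH" %in% disabled)) {
        add("CODIV_SWITCH", orient = "a", p_grand = gp, p_r = r,
            upper_target = pr)
      }
    } else if (in_s) {                             # both on one cherry leaf
      add("DUPLICATION", takeoff_side = px)
      if (!is.na(r) && pr != px && pr != v && !("DUP_SWITCH" %in% disabled)) {
        add("DUP_SWITCH", takeoff_side = px, p_grand = gp, p_r = r,
            upper_target = pr)
      }
    } else if (ps != v) {                          # one inside, one outside
      X <- px; C <- ps
      add("HOST_SWITCH", takeoff_side = X, switch_target = C,
          p_inside = x, p_outside = s)
      hp <- H$parent[v]
      if (!is.na(hp)) {
        hs <- if (H$left[hp] == v) H$right[hp] else H$left[hp]
        if (C == hs) add("DEFER_CODIV")
      }
      if (!("LOSS_SWITCH" %in% disabled)) {
        add("LOSS_SWITCH", takeoff_side = X, switch_target = C,
            p_inside = x, p_outside = s)
      }
      if (!is.na(r)) {
        Y <- if (X == A) B else A
        if (pr == Y && !("CODIV_SWITCH" %in% disabled)) {
          add("CODIV_SWITCH", orient = "b", takeoff_side = X,
              switch_target = C, p_inside = x, p_outside = s,
              p_grand = gp, p_r = r)
        } else if (outside_ok(pr) && pr != C &&
                   !("DOUBLE_SWITCH" %in% disabled)) {
          add("DOUBLE_SWITCH", takeoff_side = X, switch_target = C,
              p_inside = x, p_outside = s, p_grand = gp, p_r = r,
              upper_target = pr)
        }
      }
    } else {                                       # partner already above v
      leftover <- c(leftover, q)
    }
  }
  st$match_idx <- idx
  list(matches = matches, leftover = leftover)
}

# is a previously detected match still applicable?
#' @keywords internal
match_valid <- function(mm, st) {
  ok <- st$p_live[mm$p_left] && st$p_live[mm$p_right]
  if (ok && !is.null(mm$p_r) && !is.na(mm$p_r)) ok <- st$p_live[mm$p_r]
  ok
}

#' Choose among detected patterns
#'
#' Picks the match with minimum local cost under the active cost scheme;
#' ties are broken by a fixed kind priority (CODIVERGENCE, CODIV_SWITCH,
#' DOUBLE_SWITCH, LOSS_SWITCH, DUP_SWITCH, DUPLICATION, HOST_SWITCH, then
#' the deferral lookahead) and then by smallest traversal index.  An empty
#' match list yields the LOSS decision (collapse the host cherry).
#'
#' @param matches list of matches from [detect_patterns()].
#' @param scheme a [cost_scheme()].
#' @return the selected match (with `local_cost` filled in) or a
#'   `list(kind = "LOSS")` decision.
#' @export
choose_pattern <- function(matches, scheme = jungle_scheme()) {
  if (!length(matches)) return(list(kind = "LOSS"))
  cost <- vapply(matches, function(mm) pattern_cost(mm$kind, scheme), 0)
  prio <- vapply(matches, function(mm) .pattern_priority[[mm$kind]], 0)
  ord <- order(cost, prio, vapply(matches, `[[`, 0L, "idx"))
  best <- matches[[ord[1L]]]
  best$local_cost <- cost[ord[1L]]
  best
}

#' @keywords internal
consume <- function(st, nodes) {
  st$p_live[nodes] <- FALSE
}

#' @keywords internal
make_live <- function(st, node, at) {
  st$p_live[node] <- TRUE
  st$pos[node] <- at
  st$last_live <- node
  st$last_pair <- NA_integer_
  par <- st$P$parent[node]
  st$ops <- st$ops + 1
  if (!is.na(par)) {
    sib <- if (st$P$left[par] == node) st$P$right[par] else st$P$left[par]
    if (st$p_live[sib]) {  # a new parasite cherry forms: register it
      for (h in unique(c(at, live_pos(st, sib)))) {
        st$pend[[h]] <- c(st$pend[[h]], par)
      }
      st$last_pair <- par
    }
  }
}

#' @keywords internal
host_collapse <- function(st, v, A, B) {
  st$uf[A] <- v; st$uf[B] <- v
  # Lemma-2 style: unprocessed pending patterns transfer to the parent
  st$pend[[v]] <- as.integer(c(st$pend[[v]], st$pend[[A]], st$pend[[B]]))
  st$pend[[A]] <- integer(0)
  st$pend[[B]] <- integer(0)
  st$ops <- st$ops + 1
  invisible(st)
}

#' Apply a chosen pattern (or the LOSS decision)
#'
#' Mutates the collapse state: records the pattern's event(s), collapses the
#' matched parasite cherry/cherries and/or the host cherry, and updates the
#' live association.  Codivergence-bearing patterns do not collapse the host
#' cherry immediately — several parasite lineages may codiverge at the same
#' host node — the cherry collapses when no pattern is left.  Host-switch
#' take-off edges are anchored at the processed cherry (the deepest
#' admissible position at this step); precise relocation is [right_push()]'s
#' job, so the engine may over-count losses.
#'
#' @param st a [collapse_state()].
#' @param match a match from [choose_pattern()] (or `list(kind="LOSS")`
#'   with `i_left`, `i_right`, `i_parent` set).
#' @return `TRUE` if the host cherry was collapsed (processing of this
#'   cherry ends), else `FALSE`.
#' @export
apply_pattern <- function(st, match) {
  v <- match$i_parent; A <- match$i_left; B <- match$i_right
  d <- st$d
  st$ops <- st$ops + 1
  if (match$kind %in% c("LOSS", "DEFER_CODIV")) {
    host_collapse(st, v, A, B)
    return(TRUE)
  }
  x <- match$p_left; s <- match$p_right; q <- match$p_parent
  if (!st$p_live[x] || !st$p_live[s] ||
      (!is.null(match$p_r) && !is.na(match$p_r) && !st$p_live[match$p_r])) {
    stop("internal: stale pattern match applied")
  }
  switch(match$kind,
    CODIVERGENCE = {
      record_event(st, q, "codivergence", v, d[v])
      consume(st, c(x, s))
      make_live(st, q, v)
      FALSE
    },
    DUPLICATION = {
      X <- match$takeoff_side
      record_event(st, q, "duplication", X, d[v])
      consume(st, c(x, s))
      make_live(st, q, X)
      FALSE
    },
    HOST_SWITCH = {
      X <- match$takeoff_side; C <- match$switch_target
      record_event(st, q, "host_switch", X, d[v], landing = C,
                   tko = match$p_inside, lnd = match$p_outside)
      consume(st, c(x, s))
      make_live(st, q, X)
      FALSE
    },
    LOSS_SWITCH = {
      # switch at the cherry plus the committed failure-to-diverge: the
      # merged node is lifted straight above the cherry parent
      X <- match$takeoff_side; C <- match$switch_target
      record_event(st, q, "host_switch", X, d[v], landing = C,
                   tko = match$p_inside, lnd = match$p_outside)
      consume(st, c(x, s))
      make_live(st, q, v)
      FALSE
    },
    CODIV_SWITCH = {
      gm <- match$p_grand; r <- match$p_r
      if (identical(match$orient, "a")) {
        # codivergence at the cherry, switch one parasite level above it
        record_event(st, q, "codivergence", v, d[v])
        record_event(st, gm, "host_switch", v, d[v] - 1L,
                     landing = match$upper_target, tko = q, lnd = r)
      } else {
        # switch at the cherry, codivergence at the level above
        X <- match$takeoff_side; C <- match$switch_target
        record_event(st, q, "host_switch", X, d[v], landing = C,
                     tko = match$p_inside, lnd = match$p_outside)
        record_event(st, gm, "codivergence", v, d[v])
      }
      consume(st, c(x, s, q, r))
      make_live(st, gm, v)
      FALSE
    },
    DUP_SWITCH = {
      X <- match$takeoff_side
      gm <- match$p_grand; r <- match$p_r
      record_event(st, gm, "host_switch", X, d[v],
                   landing = match$upper_target, tko = q, lnd = r)
      record_event(st, q, "duplication", X, d[v])
      consume(st, c(x, s, q, r))
      make_live(st, gm, X)
      FALSE
    },
    DOUBLE_SWITCH = {
      X <- match$takeoff_side; C <- match$switch_target
      gm <- match$p_grand; r <- match$p_r
      record_event(st, gm, "host_switch", X, d[v],
                   landing = match$upper_target, tko = q, lnd = r)
      record_event(st, q, "host_switch", X, d[v], landing = C,
                   tko = match$p_inside, lnd = match$p_outside)
      consume(st, c(x, s, q, r))
      make_live(st, gm, X)
      FALSE
    },
    stop("unknown pattern kind ", match$kind))
}

#' Greedy cherry-collapse reconstruction
#'
#' The main loop: host cherries are processed in decreasing depth order;
#' for each cherry, pending patterns are classified once, the cheapest is
#' applied, and only the pattern each application can newly create is
#' (re)classified, so detection work is amortised over the patterns
#' produced.  Terminal states: a codivergence at the root arises from the
#' ordinary root-cherry round; leftover host structure is ignored; leftover
#' parasite nodes are appended above the host root as pre-root duplication
#' events.  The output is always time-consistent: every committed host
#' switch jumps between edges that are provably contemporaneous under the
#' ordering.
#'
#' @param tg a [tanglegram()].
#' @param ordering a `cophy_ordering` (default: [default_ordering()]).
#' @param scheme a [cost_scheme()].
#' @param config a [collapse_config()].
#' @return a [new_cophy_mapping()] with `op_count` filled in.
#' @examples
#' tg <- read_tanglegram("((A,B),C);", "((a,b),c);", "a\tA\nb\tB\nc\tC")
#' m <- tree_collapse(tg)
#' mapping_cost(m)  # 0: perfectly congruent
#' @export
tree_collapse <- function(tg, ordering = NULL, scheme = jungle_scheme(),
                          config = collapse_config()) {
  if (is.null(ordering)) ordering <- default_ordering(tg$host)
  st <- collapse_state(tg, ordering, scheme, config)
  H <- st$H; P <- st$P
  sched <- schedule_cherries(H, ordering)
  # pattern kinds bucketed by (local cost, tie priority): selection policy
  # identical to choose_pattern(), but pops are amortised O(1) because an
  # invalidated match is discarded at most once
  kinds <- names(.pattern_priority)
  kcost <- vapply(kinds, pattern_cost, 0, scheme = scheme)
  kind_order <- kinds[order(kcost, .pattern_priority[kinds])]
  for (v in sched) {
    cherry <- list(i_left = H$left[v], i_right = H$right[v], i_parent = v)
    st$ops <- st$ops + 1
    bq <- lapply(kinds, function(k) list())
    names(bq) <- kinds
    bhead <- stats::setNames(rep(1L, length(kinds)), kinds)
    push <- function(ms) {
      for (mm in ms) bq[[mm$kind]][[length(bq[[mm$kind]]) + 1L]] <<- mm
      st$ops <- st$ops + length(ms)
    }
    pop <- function() {
      for (k in kind_order) {
        while (bhead[[k]] <= length(bq[[k]])) {
          mm <- bq[[k]][[bhead[[k]]]]
          bhead[[k]] <<- bhead[[k]] + 1L
          st$ops <- st$ops + 1
          if (match_valid(mm, st)) return(mm)
        }
      }
      NULL
    }
    push(detect_patterns(st, cherry))
    repeat {
      ch <- pop()
      if (is.null(ch)) {
        loss <- list(kind = "LOSS", i_left = cherry$i_left,
                     i_right = cherry$i_right, i_parent = v)
        apply_pattern(st, loss)
        break
      }
      if (apply_pattern(st, ch)) break
      if (!is.na(st$last_pair)) {
        res <- classify_pairs(st, cherry, st$last_pair)
        push(res$matches)
      }
    }
  }
  # terminal state: leftover parasite nodes become pre-root duplications
  has_event <- logical(P$n_nodes)
  has_event[st$ev_node] <- TRUE
  for (q in tree_postorder(P)) {
    if (!P$is_leaf[q] && !has_event[q]) {
      record_event(st, q, "duplication", H$root, 0L, preroot = TRUE)
      has_event[q] <- TRUE
    }
  }
  events <- data.frame(node = st$ev_node, kind = st$ev_kind,
                       host = st$ev_host, time = st$ev_time,
                       landing = st$ev_landing, takeoff_child = st$ev_tko,
                       landing_child = st$ev_lnd, pre_root = st$ev_preroot,
                       stringsAsFactors = FALSE)
  new_cophy_mapping(tg, ordering, events, op_count = st$ops)
}
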