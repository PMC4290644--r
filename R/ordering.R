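#' Node orderings: unique integer depths for host internal nodes
#'
#' A node ordering assigns every internal node of the host a unique integer
#' depth, with the root at 0 and depths strictly increasing from parent to
#' child; all leaves share the common depth `n_internal`.  The ordering
#' totally orders host divergence times and is what makes host-switch
#' time-consistency checkable with integer comparisons: the edge from `u` to
#' `v` is alive during the half-open interval `[d(u), d(v))`.
#'
#' @param host a [cophy_tree()].
#' @return an object of class `cophy_ordering`: list with `depth` (integer
#'   vector over all node ids) and `n_internal`.
#' @seealso [validate_ordering()], [schedule_cherries()]
#' @export
default_ordering <- function(host) {
  check_host(host)
  depth <- integer(host$n_nodes)
  ints <- which(!host$is_leaf)
  # preorder rank guarantees parent depth < child depth
  depth[ints[order(host$enter[ints])]] <- seq_along(ints) - 1L
  depth[host$is_leaf] <- host$n_internal
  new_ordering(depth, host$n_internal)
}

#' @keywords internal
new_ordering <- function(depth, n_internal) {
  structure(list(depth = as.integer(depth), n_internal = as.integer(n_internal)),
            class = "cophy_ordering")
}

#' @keywords internal
check_host <- function(host) {
  if (!inherits(host, "cophy_tree")) stop("host is not a cophy_tree")
  if (host$n_leaves < 2L) {
    stop("host tree must have at least 2 leaves (single-node trees are rejected)")
  }
  invisible(host)
}

#' Validate a node ordering against its host tree
#'
#' Returns `TRUE` iff the ordering satisfies every invariant: the root at
#' depth 0, internal depths a permutation of `0..n_internal-1`, every leaf at
#' `n_internal`, and each child strictly deeper than its parent.  A
#' structurally unusable ordering (wrong length, missing values) is an input
#' error, distinct from returning `FALSE`.
#'
#' @param host a [cophy_tree()].
#' @param ordering a `cophy_ordering`.
#' @return logical scalar.
#' @export
validate_ordering <- function(host, ordering) {
  check_host(host)
  if (!inherits(ordering, "cophy_ordering")) stop("not a cophy_ordering")
  d <- ordering$depth
  if (length(d) != host$n_nodes || anyNA(d)) {
    stop("ordering must assign a depth to every host node")
  }
  n_int <- host$n_internal
  if (ordering$n_internal != n_int) return(FALSE)
  ints <- which(!host$is_leaf)
  if (d[host$root] != 0L) return(FALSE)
  if (!identical(sort(d[ints]), seq_len(n_int) - 1L)) return(FALSE)
  if (any(d[host$is_leaf] != n_int)) return(FALSE)
  kids <- which(!is.na(host$parent))
  all(d[kids] > d[host$parent[kids]])
}

#' Cherry processing schedule
#'
#' Returns the host internal nodes in the order their cherries are (or
#' become) processable: strictly decreasing depth, deepest first.  Uses a
#' bucket keyed by depth (depths are a permutation of `0..n_internal-1`), so
#' the operation count is linear in the host size, never `O(m log m)`.
#'
#' @param host a [cophy_tree()].
#' @param ordering a valid `cophy_ordering`.
#' @return integer vector of internal node ids, deepest first.
#' @export
schedule_cherries <- function(host, ordering) {
  if (!validate_ordering(host, ordering)) stop("invalid ordering")
  bucket <- integer(host$n_internal)
  for (v in which(!host$is_leaf)) {
    bucket[ordering$depth[v] + 1L] <- v
  }
  rev(bucket)
}
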