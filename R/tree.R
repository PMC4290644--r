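#' Rooted bifurcating phylogeny container
#'
#' `cophy_tree` objects hold a rooted, strictly bifurcating tree with uniquely
#' labelled leaves.  Nodes are integer ids `1..n_nodes`; internal structure is
#' stored as flat parent/left/right vectors so that the collapse engine can
#' address nodes in O(1).  With `L` leaves a valid tree has exactly `L - 1`
#' internal nodes.  Single-node trees (one leaf, no internal node) can be
#' produced by the simulator but are rejected as hosts by all reconstruction
#' entry points.
#'
#' @param parent integer vector, `NA` at the root.
#' @param left,right integer vectors of child ids, `NA` at leaves.
#' @param label character vector of leaf labels (`NA` for internal nodes).
#' @return an object of class `cophy_tree` with fields `parent`, `left`,
#'   `right`, `label`, `root`, `is_leaf`, `n_nodes`, `n_leaves`, `n_internal`,
#'   plus precomputed traversal indices `enter`/`exit` (subtree tests) and
#'   `n_int_path` (number of internal nodes on the root path, inclusive).
#' @export
cophy_tree <- function(parent, left, right, label) {
  n <- length(parent)
  stopifnot(length(left) == n, length(right) == n, length(label) == n)
  is_leaf <- is.na(left) & is.na(right)
  root <- which(is.na(parent))
  if (length(root) != 1L) {
    stop("tree must have exactly one root (found ", length(root), ")")
  }
  if (any(xor(is.na(left), is.na(right)))) {
    stop("internal nodes must have exactly 2 children (bifurcating tree)")
  }
  lab <- label[is_leaf]
  if (any(is.na(lab)) || any(!nzchar(lab))) {
    stop("every leaf needs a non-empty label")
  }
  if (anyDuplicated(lab)) {
    stop("duplicate leaf label: ", lab[duplicated(lab)][1L])
  }
  n_leaves <- sum(is_leaf)
  n_internal <- n - n_leaves
  if (n_leaves >= 2L && n_internal != n_leaves - 1L) {
    stop("a bifurcating tree with ", n_leaves, " leaves must have ",
         n_leaves - 1L, " internal nodes")
  }
  tr <- structure(
    list(parent = as.integer(parent), left = as.integer(left),
         right = as.integer(right), label = as.character(label),
         root = as.integer(root), is_leaf = is_leaf,
         n_nodes = n, n_leaves = n_leaves, n_internal = n_internal),
    class = "cophy_tree")
  # preorder enter/exit numbering + internal-node count along root paths;
  # these back the O(1) subtree membership and loss-count primitives
  enter <- integer(n); exit <- integer(n); nip <- integer(n)
  clock <- 0L
  stack <- root
  # iterative DFS (host trees can be deep; avoid R recursion limits)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v < 0L) {  # sentinel: close node -v
      clock <- clock + 1L
      exit[-v] <- clock
      next
    }
    clock <- clock + 1L
    enter[v] <- clock
    p <- tr$parent[v]
    nip[v] <- (if (is.na(p)) 0L else nip[p]) + (if (is_leaf[v]) 0L else 1L)
    stack <- c(stack, -v)
    if (!is_leaf[v]) stack <- c(stack, tr$right[v], tr$left[v])
  }
  tr$enter <- enter
  tr$exit <- exit
  tr$n_int_path <- nip
  tr
}

#' @export
print.cophy_tree <- function(x, ...) {
  cat("<cophy_tree> ", x$n_leaves, " leaves, ", x$n_internal,
      " internal nodes\n", sep = "")
  invisible(x)
}

#' Is `anc` an ancestor of (or equal to) `node`?
#' @param tree a `cophy_tree`.
#' @param anc,node node ids.
#' @return logical.
#' @keywords internal
is_ancestor <- function(tree, anc, node) {
  tree$enter[anc] <= tree$enter[node] & tree$exit[node] <= tree$exit[anc]
}

#' Number of host divergences a lineage crosses travelling from node `b`
#' down to node `target` (both on one root-to-leaf path), excluding the
#' divergence at `target` itself but including the one at `b`.  This is the
#' loss count contributed by a parasite lineage that starts on the edge above
#' `b` and whose own event is anchored at `target`.
#' @keywords internal
path_crossings <- function(tree, b, target) {
  if (!is_ancestor(tree, b, target)) {
    stop("internal: target ", target, " is not below ", b)
  }
  pb <- tree$parent[b]
  base <- if (is.na(pb)) 0L else tree$n_int_path[pb]
  tree$n_int_path[target] - base - (if (tree$is_leaf[target]) 0L else 1L)
}

#' Nodes crossed between `b` and `target` (for loss event materialisation).
#' Returns the internal node ids on the path from `b` to `target`, excluding
#' `target`, root-most first.
#' @keywords internal
path_crossed_nodes <- function(tree, b, target) {
  out <- integer(0)
  z <- target
  while (z != b) {
    z <- tree$parent[z]
    if (!tree$is_leaf[z]) out <- c(z, out)
  }
  out
}

#' Leaf id lookup by label
#' @keywords internal
leaf_ids <- function(tree) {
  ids <- which(tree$is_leaf)
  stats::setNames(ids, tree$label[ids])
}

#' Postorder node ids (children before parents)
#' @keywords internal
tree_postorder <- function(tree) {
  order(tree$exit)
}

#' Preorder node ids (parents before children)
#' @keywords internal
tree_preorder <- function(tree) {
  order(tree$enter)
}

#' Convert an ape "phylo" object to a cophy_tree
#' @keywords internal
from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nn)
  left <- rep(NA_integer_, nn)
  right <- rep(NA_integer_, nn)
  label <- rep(NA_character_, nn)
  label[seq_len(ntip)] <- phy$tip.label
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    parent[b] <- a
    if (is.na(left[a])) left[a] <- b
    else if (is.na(right[a])) right[a] <- b
    else {
      kids <- c(left[a], right[a], phy$edge[phy$edge[, 1L] == a, 2L])
      bad <- unique(kids)
      tips <- unlist(lapply(bad, function(k) descendant_tips_phylo(phy, k, ntip)))
      stop("polytomy at clade {", paste(utils::head(sort(unique(tips)), 6L),
           collapse = ","), if (length(unique(tips)) > 6L) ",..." else "",
           "}: trees must be strictly bifurcating")
    }
  }
  cophy_tree(parent, left, right, label)
}

#' @keywords internal
descendant_tips_phylo <- function(phy, node, ntip) {
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, descendant_tips_phylo, phy = phy, ntip = ntip))
}

#' Read a rooted bifurcating tree from Newick text
#'
#' Wraps [ape::read.tree()] and validates the result: exactly one rooted
#' statement, strictly bifurcating, unique non-empty leaf labels.  Branch
#' lengths, if present, are parsed and discarded (timing comes from the node
#' ordering, never from branch lengths).  Internal node labels are preserved
#' but never used for identity.
#'
#' @param text a single Newick statement (string).
#' @return a [cophy_tree()].
#' @examples
#' tr <- read_newick("((A,B),C);")
#' tr$n_leaves
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("failed to parse Newick text (unbalanced parentheses?)")
  if (inherits(phy, "multiPhylo")) stop("expected a single Newick statement")
  if (length(phy$tip.label) < 2L) {
    stop("tree must have at least 2 leaves (single-node trees are rejected)")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1L])
  }
  tr <- from_phylo(phy)
  if (!is.null(phy$node.label)) {
    ids <- which(!tr$is_leaf)
    # ape stores node labels in internal-node numbering order
    nl <- phy$node.label
    if (length(nl) == length(ids)) {
      attr(tr, "node_label") <- stats::setNames(nl, ids[order(ids)])
    }
  }
  tr
}

#' Write a tree as Newick text
#'
#' Inverse of [read_newick()] up to isomorphism: the returned text re-reads to
#' a tree with identical topology and leaf labels.
#'
#' @param tree a [cophy_tree()].
#' @return a Newick string (with trailing semicolon).
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "cophy_tree")) stop("not a cophy_tree")
  if (tree$n_leaves < 2L) stop("cannot serialise a tree with fewer than 2 leaves")
  ape::write.tree(to_phylo(tree))
}

#' @keywords internal
to_phylo <- function(tree) {
  tips <- which(tree$is_leaf)
  ints <- which(!tree$is_leaf)
  # ape numbering: tips 1..L in their order, then internals with root first
  tip_no <- stats::setNames(seq_along(tips), tips)
  int_sorted <- ints[order(tree$enter[ints])]  # root gets L+1
  int_no <- stats::setNames(tree$n_leaves + seq_along(int_sorted), int_sorted)
  num <- integer(tree$n_nodes)
  num[tips] <- tip_no
  num[int_sorted] <- int_no
  edge <- matrix(0L, nrow = tree$n_nodes - 1L, ncol = 2L)
  j <- 0L
  for (v in int_sorted) {
    for (ch in c(tree$left[v], tree$right[v])) {
      j <- j + 1L
      edge[j, ] <- c(num[v], num[ch])
    }
  }
  phy <- list(edge = edge, tip.label = tree$label[tips],
              Nnode = tree$n_internal)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Descendant leaf labels of a node, sorted (stable clade descriptor)
#' @keywords internal
clade_labels <- function(tree, node) {
  sel <- tree$enter >= tree$enter[node] & tree$exit <= tree$exit[node] &
    tree$is_leaf
  sort(tree$label[sel])
}

#' @keywords internal
clade_key <- function(tree, node) paste(clade_labels(tree, node), collapse = "+")
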