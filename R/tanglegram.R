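#' Tanglegrams: (H, P, phi)
#'
#' A tanglegram couples a host tree `H`, a parasite tree `P` and a leaf
#' association map `phi` sending each parasite leaf to exactly one host leaf
#' (several parasites may share a host; a parasite never inhabits more than
#' one host).
#'
#' @param host,parasite [cophy_tree()] objects.
#' @param phi integer vector indexed by parasite leaf id, holding host leaf
#'   ids, or a named character vector `parasite_label -> host_label`.
#' @return an object of class `cophy_tanglegram` with fields `host`,
#'   `parasite` and `phi` (integer map over parasite node ids; `NA` for
#'   parasite internal nodes).
#' @export
tanglegram <- function(host, parasite, phi) {
  if (!inherits(host, "cophy_tree") || !inherits(parasite, "cophy_tree")) {
    stop("host and parasite must be cophy_tree objects")
  }
  p_leaves <- which(parasite$is_leaf)
  map <- rep(NA_integer_, parasite$n_nodes)
  if (is.character(phi)) {
    hl <- leaf_ids(host)
    pl <- leaf_ids(parasite)
    if (!all(names(phi) %in% names(pl))) {
      bad <- setdiff(names(phi), names(pl))
      stop("association names unknown parasite leaf: ", paste(bad, collapse = ", "))
    }
    if (!all(phi %in% names(hl))) {
      bad <- setdiff(phi, names(hl))
      stop("association names unknown host leaf: ", paste(bad, collapse = ", "))
    }
    if (anyDuplicated(names(phi))) {
      stop("parasite leaf associated more than once: ",
           names(phi)[duplicated(names(phi))][1L],
           " (each parasite may only inhabit a single host)")
    }
    map[pl[names(phi)]] <- hl[phi]
  } else {
    phi <- as.integer(phi)
    if (length(phi) == parasite$n_nodes) map <- phi
    else if (length(phi) == length(p_leaves)) map[p_leaves] <- phi
    else stop("phi has the wrong length")
  }
  if (anyNA(map[p_leaves])) {
    miss <- parasite$label[p_leaves[is.na(map[p_leaves])]]
    stop("no host association for parasite leaf: ", paste(miss, collapse = ", "))
  }
  if (any(!host$is_leaf[map[p_leaves]])) stop("phi must target host leaves")
  structure(list(host = host, parasite = parasite, phi = map),
            class = "cophy_tanglegram")
}

#' @export
print.cophy_tanglegram <- function(x, ...) {
  cat("<cophy_tanglegram> host ", x$host$n_leaves, " leaves, parasite ",
      x$parasite$n_leaves, " leaves\n", sep = "")
  invisible(x)
}

#' Read a tanglegram from Newick texts plus a TSV association table
#'
#' The association table has one row per parasite leaf,
#' `parasite_leaf<TAB>host_leaf`; lines starting with `#` are comments.
#' Every parasite leaf must appear exactly once and every named label must
#' exist in the corresponding tree.
#'
#' @param host_text,parasite_text single Newick statements.
#' @param assoc_text the TSV table as a string (or vector of lines).
#' @return a [tanglegram()].
#' @examples
#' tg <- read_tanglegram("((A,B),C);", "((a,b),c);",
#'                       "a\tA\nb\tB\nc\tC")
#' @export
read_tanglegram <- function(host_text, parasite_text, assoc_text) {
  host <- read_newick(host_text)
  parasite <- read_newick(parasite_text)
  if (length(assoc_text) > 1L) assoc_text <- paste(assoc_text, collapse = "\n")
  tab <- utils::read.table(text = assoc_text, sep = "\t", comment.char = "#",
                           header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(tab) != 2L) stop("association table must have exactly 2 tab-separated columns")
  phi <- stats::setNames(tab[[2L]], tab[[1L]])
  tg <- tanglegram(host, parasite, phi)
  # totality: every parasite leaf must have a row
  pl <- leaf_ids(parasite)
  miss <- setdiff(names(pl), tab[[1L]])
  if (length(miss)) {
    stop("no host association for parasite leaf: ", paste(miss, collapse = ", "))
  }
  tg
}

#' Serialise the parts of a tanglegram
#'
#' Returns the host/parasite Newick strings and the TSV association text;
#' `read_tanglegram()` applied to the result reproduces the tanglegram.
#'
#' @param tg a [tanglegram()].
#' @return named list `host`, `parasite`, `assoc`.
#' @export
write_tanglegram <- function(tg) {
  pl <- which(tg$parasite$is_leaf)
  rows <- paste(tg$parasite$label[pl], tg$host$label[tg$phi[pl]], sep = "\t")
  list(host = write_newick(tg$host), parasite = write_newick(tg$parasite),
       assoc = paste(rows, collapse = "\n"))
}
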