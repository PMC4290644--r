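#' Simulation parameters for synthetic cophylogenies
#'
#' The generator grows a pure-birth (Yule) host tree and co-simulates a
#' parasite down it.  At every host divergence faced by a parasite lineage
#' one of four outcomes is drawn: codivergence (track both host children),
#' loss (track one child; the parasite is absent on the other), duplication
#' (two parasite lineages, both still facing the divergence) or host switch
#' (one lineage stays, the other jumps to a uniformly chosen contemporaneous
#' host edge).  The default probabilities (0.5, 0.2, 0.15, 0.15) are this
#' package's declared stand-in for the reference generator, whose exact
#' parameterisation is not published; see the methods vignette.
#'
#' @param n_host_leaves number of host leaves (>= 2).
#' @param p_codiv,p_dup,p_switch,p_loss event probabilities, summing to 1.
#' @param rng_seed optional integer seed used by [generate_instance()].
#' @return a `cophy_sim_params` list.
#' @export
sim_params <- function(n_host_leaves, p_codiv = 0.5, p_dup = 0.2,
                       p_switch = 0.15, p_loss = 0.15, rng_seed = NULL) {
  p <- c(p_codiv, p_dup, p_switch, p_loss)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("event probabilities must be non-negative and sum to 1")
  }
  if (n_host_leaves < 2L) stop("n_host_leaves must be >= 2")
  structure(list(n_host_leaves = as.integer(n_host_leaves),
                 p_codiv = p_codiv, p_dup = p_dup, p_switch = p_switch,
                 p_loss = p_loss, rng_seed = rng_seed),
            class = "cophy_sim_params")
}

#' Yule (pure birth) tree
#'
#' Repeatedly picks a uniformly random extant lineage and splits it until
#' `n_leaves` tips exist.  Leaves are labelled `H1..Hn` in node-id order.
#' Deterministic under `set.seed()`.
#'
#' @param n_leaves number of tips (>= 2).
#' @param prefix leaf label prefix.
#' @return a [cophy_tree()].
#' @export
yule_tree <- function(n_leaves, prefix = "H") {
  if (n_leaves < 2L) stop("n_leaves must be >= 2")
  n_nodes <- 2L * n_leaves - 1L
  parent <- rep(NA_integer_, n_nodes)
  left <- rep(NA_integer_, n_nodes)
  right <- rep(NA_integer_, n_nodes)
  nxt <- 1L
  new_node <- function(par) {
    id <- nxt; nxt <<- nxt + 1L
    parent[id] <<- par
    id
  }
  root <- new_node(NA_integer_)
  extant <- c(new_node(root), new_node(root))
  left[root] <- extant[1L]; right[root] <- extant[2L]
  while (length(extant) < n_leaves) {
    i <- if (length(extant) == 1L) 1L else sample.int(length(extant), 1L)
    v <- extant[i]
    a <- new_node(v); b <- new_node(v)
    left[v] <- a; right[v] <- b
    extant <- c(extant[-i], a, b)
  }
  label <- rep(NA_character_, n_nodes)
  leaves <- which(is.na(left[seq_len(nxt - 1L)]))
  label[leaves] <- paste0(prefix, seq_along(leaves))
  cophy_tree(parent, left, right, label)
}

#' Co-simulate a parasite down a host tree
#'
#' See [sim_params()] for the model.  The generated history is
#' time-consistent by construction: a switching lineage can only land on a
#' host edge alive in the interval just before the divergence it is facing
#' (at the host root no contemporaneous edge exists, so the draw is
#' renormalised over the other events there).  Loss tracks one child, so
#' the parasite never goes extinct; a parasite with a single leaf is
#' possible (and is filtered by [generate_instance()]).
#'
#' @param host a [cophy_tree()].
#' @param params a [sim_params()].
#' @return list with `parasite` (a [cophy_tree()]), `phi` (named character,
#'   parasite label -> host label) and `log` (data.frame of simulated
#'   events: kind, host node, time).
#' @export
evolve_parasite <- function(host, params) {
  ord <- default_ordering(host)
  d <- ord$depth
  span_lo <- ifelse(is.na(host$parent), -1L, d[host$parent])
  span_hi <- ifelse(host$is_leaf, ord$n_internal, d)
  pparent <- integer(0); pleft <- integer(0); pright <- integer(0)
  leaf_host <- integer(0)
  log_kind <- character(0); log_host <- integer(0); log_time <- integer(0)
  new_p <- function() {
    pparent <<- c(pparent, NA_integer_)
    pleft <<- c(pleft, NA_integer_); pright <<- c(pright, NA_integer_)
    leaf_host <<- c(leaf_host, NA_integer_)
    length(pparent)
  }
  probs <- c(params$p_codiv, params$p_dup, params$p_switch, params$p_loss)
  # One draw per host divergence per lineage.  A daughter created by a
  # duplication or switch resolves the divergence it is facing with the
  # renormalised codivergence/loss draw (allow_extra = FALSE), so each
  # lineage triggers at most one independent event per host node and
  # parasite size stays commensurate with host size.
  sim_at <- function(h, allow_extra = TRUE) {
    if (host$is_leaf[h]) {
      id <- new_p()
      leaf_host[id] <<- h
      return(id)
    }
    pr <- probs
    if (!allow_extra) pr[2:3] <- 0
    if (is.na(host$parent[h])) pr[3L] <- 0  # no landing edge before the root
    pr <- pr / sum(pr)
    ev <- sample.int(4L, 1L, prob = pr)
    if (ev == 4L) {               # loss: follow one child only
      child <- if (stats::runif(1) < 0.5) host$left[h] else host$right[h]
      log_kind <<- c(log_kind, "loss"); log_host <<- c(log_host, h)
      log_time <<- c(log_time, d[h])
      return(sim_at(child))
    }
    id <- new_p()
    if (ev == 1L) {               # codivergence
      a <- sim_at(host$left[h]); b <- sim_at(host$right[h])
      log_kind <<- c(log_kind, "codivergence")
    } else if (ev == 2L) {        # duplication just before the divergence
      a <- sim_at(h, FALSE); b <- sim_at(h, FALSE)
      log_kind <<- c(log_kind, "duplication")
    } else {                      # host switch at the interval before d(h)
      tau <- d[h] - 1L
      cand <- which(span_lo <= tau & tau < span_hi)
      cand <- cand[cand != h]
      w <- if (length(cand) == 1L) cand else sample(cand, 1L)
      a <- sim_at(h, FALSE); b <- sim_at(w)
      log_kind <<- c(log_kind, "host_switch")
    }
    pleft[id] <<- a; pright[id] <<- b
    pparent[a] <<- id; pparent[b] <<- id
    log_host <<- c(log_host, h); log_time <<- c(log_time, d[h])
    id
  }
  sim_at(host$root)
  n <- length(pparent)
  label <- rep(NA_character_, n)
  leaves <- which(!is.na(leaf_host))
  label[leaves] <- paste0("p", seq_along(leaves))
  parasite <- cophy_tree(pparent, pleft, pright, label)
  phi <- stats::setNames(host$label[leaf_host[leaves]], label[leaves])
  list(parasite = parasite, phi = phi,
       log = data.frame(kind = log_kind, host = log_host, time = log_time))
}

#' Generate a synthetic tanglegram instance
#'
#' Composes [yule_tree()] and [evolve_parasite()]; instances whose parasite
#' degenerates to a single leaf are redrawn (single-node trees are excluded
#' from all analyses).  With `rng_seed` set the instance is fully
#' reproducible.
#'
#' @param params a [sim_params()].
#' @return a [tanglegram()]; the simulated truth log is attached as
#'   attribute `"truth_log"`.
#' @export
generate_instance <- function(params) {
  if (!inherits(params, "cophy_sim_params")) stop("params must come from sim_params()")
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  for (try in seq_len(100L)) {
    host <- yule_tree(params$n_host_leaves)
    sim <- evolve_parasite(host, params)
    if (sim$parasite$n_leaves >= 2L) {
      tg <- tanglegram(host, sim$parasite, sim$phi)
      attr(tg, "truth_log") <- sim$log
      return(tg)
    }
  }
  stop("parasite degenerated to a single leaf in 100 consecutive draws; ",
       "increase p_codiv/p_dup/p_switch")
}
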