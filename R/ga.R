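#' Admissible depth range of an internal host node
#'
#' Chromosome genes are depths of the non-root internal nodes.  A node's
#' gene is bounded below by the number of ancestor nodes between it and the
#' root (inclusive of the root) and above by the number of internal nodes
#' minus the number of internal descendants minus one, so `i <= gene <= j`
#' for every valid ordering.
#'
#' @param host a [cophy_tree()].
#' @param node an internal, non-root host node id.
#' @return integer vector `c(i, j)`.
#' @export
gene_range <- function(host, node) {
  check_host(host)
  if (host$is_leaf[node]) stop("gene_range: node ", node, " is a leaf")
  if (node == host$root) stop("gene_range: the root has fixed depth 0")
  i <- host$n_int_path[host$parent[node]]  # internal ancestors incl. root
  ndesc <- sum(!host$is_leaf & host$enter > host$enter[node] &
                 host$exit < host$exit[node])
  j <- host$n_internal - ndesc - 1L
  if (i > j) stop("internal: empty gene range")
  c(i, j)
}

#' @keywords internal
ga_nodes <- function(host) {
  ints <- which(!host$is_leaf)
  ints <- ints[order(host$enter[ints])]
  ints[ints != host$root]
}

#' @keywords internal
decode_chromosome <- function(host, genes) {
  nodes <- ga_nodes(host)
  stopifnot(length(genes) == length(nodes))
  depth <- integer(host$n_nodes)
  depth[host$root] <- 0L
  depth[nodes] <- as.integer(genes)
  depth[host$is_leaf] <- host$n_internal
  new_ordering(depth, host$n_internal)
}

#' @keywords internal
repair_chromosome <- function(host, genes, ranges, max_tries = 20L) {
  nodes <- ga_nodes(host)
  for (try in seq_len(max_tries)) {
    ord <- decode_chromosome(host, genes)
    if (validate_ordering(host, ord)) return(genes)
    d <- ord$depth
    bad <- vapply(seq_along(nodes), function(ix) {
      v <- nodes[ix]
      dup <- sum(d[c(host$root, nodes)] == d[v]) > 1L
      par_ok <- d[v] > d[host$parent[v]]
      kid <- c(host$left[v], host$right[v])
      kid <- kid[!host$is_leaf[kid]]
      kid_ok <- all(d[kid] > d[v])
      dup || !par_ok || !kid_ok
    }, TRUE)
    if (!any(bad)) bad[] <- TRUE  # defensive: resample everything
    genes[bad] <- vapply(which(bad), function(ix) {
      r <- ranges[[ix]]
      if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
    }, 0L)
  }
  ord <- default_ordering(host)
  ord$depth[nodes]
}

#' Draw a random valid chromosome
#'
#' Genes are drawn uniformly within their admissible ranges, then repaired
#' (only conflicting genes are resampled, up to a bounded number of
#' rounds) until the decoded ordering validates; as a deterministic
#' fallback the [default_ordering()] ranks are used.  Uses R's RNG, so
#' results are reproducible under `set.seed()`.
#'
#' @param host a [cophy_tree()].
#' @return integer gene vector (possibly length 0 for a 2-leaf host).
#' @export
random_chromosome <- function(host) {
  nodes <- ga_nodes(host)
  ranges <- lapply(nodes, function(v) gene_range(host, v))
  genes <- vapply(ranges, function(r) {
    if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
  }, 0L)
  repair_chromosome(host, genes, ranges)
}

#' GA fitness of a chromosome
#'
#' The Jungle (or supplied) cost of the collapsed-and-pushed mapping under
#' the decoded ordering; lower is fitter.
#'
#' @param tg a [tanglegram()].
#' @param genes an integer gene vector decoding to a valid ordering.
#' @param scheme a [cost_scheme()].
#' @param config a [collapse_config()].
#' @param use_right_push apply [right_push()] before scoring.
#' @return numeric cost.
#' @export
ga_fitness <- function(tg, genes, scheme = jungle_scheme(),
                       config = collapse_config(), use_right_push = TRUE) {
  ord <- decode_chromosome(tg$host, genes)
  if (!validate_ordering(tg$host, ord)) stop("chromosome decodes to an invalid ordering")
  m <- tree_collapse(tg, ord, scheme, config)
  if (use_right_push) m <- right_push(m)
  mapping_cost(m, scheme)
}

#' Genetic algorithm configuration
#'
#' Defaults mirror the reference configuration: 100 iterations with a
#' population of 100.  Selection/crossover/mutation operators are standard
#' choices (tournament of 2, uniform crossover, per-gene mutation rate
#' 1/#genes, elitism 1) and are all configurable.
#'
#' @param population_size,generations GA size (population must be >= 2).
#' @param mutation_rate per-gene resample probability (`NULL`: 1/#genes).
#' @param tournament_size,elitism_count selection/elitism parameters.
#' @param rng_seed optional integer seed applied at the start of the run.
#' @return a `cophy_ga_config` list.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      mutation_rate = NULL, tournament_size = 2L,
                      elitism_count = 1L, rng_seed = NULL) {
  if (population_size < 2L) stop("population_size must be >= 2")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism_count = as.integer(elitism_count),
                 rng_seed = rng_seed),
            class = "cophy_ga_config")
}

#' Search node orderings with a genetic algorithm
#'
#' Iterates over the exponential space of valid internal node orderings,
#' scoring each chromosome with the greedy collapse plus Right Push.
#' Tournament selection, uniform crossover, per-gene mutation with repair,
#' and elitism guarantee the best-so-far cost is monotone non-increasing.
#' Fully reproducible from `config$rng_seed`.
#'
#' @param tg a [tanglegram()].
#' @param config a [ga_config()].
#' @param scheme a [cost_scheme()].
#' @param collapse_cfg a [collapse_config()].
#' @param use_right_push apply [right_push()] inside the fitness.
#' @return list with `best_mapping`, `best_cost`, `best_ordering`,
#'   `history` (best-so-far cost after each generation, starting with the
#'   initial population).
#' @export
run_ga <- function(tg, config = ga_config(), scheme = jungle_scheme(),
                   collapse_cfg = collapse_config(), use_right_push = TRUE) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  host <- tg$host
  nodes <- ga_nodes(host)
  ranges <- lapply(nodes, function(v) gene_range(host, v))
  ng <- length(nodes)
  mrate <- if (is.null(config$mutation_rate)) {
    if (ng > 0L) 1 / ng else 0
  } else config$mutation_rate
  pop <- replicate(config$population_size, random_chromosome(host),
                   simplify = FALSE)
  score <- function(genes) ga_fitness(tg, genes, scheme, collapse_cfg,
                                      use_right_push)
  fit <- vapply(pop, score, 0)
  best_i <- which.min(fit)
  best_genes <- pop[[best_i]]; best_cost <- fit[best_i]
  history <- best_cost
  pick <- function() {
    ix <- sample.int(length(pop), config$tournament_size, replace = TRUE)
    ix[which.min(fit[ix])]
  }
  for (g in seq_len(config$generations)) {
    elite_ix <- order(fit)[seq_len(min(config$elitism_count, length(pop)))]
    newpop <- pop[elite_ix]
    while (length(newpop) < config$population_size) {
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      child <- p1
      if (ng > 0L) {
        take2 <- stats::runif(ng) < 0.5
        child[take2] <- p2[take2]
        mut <- stats::runif(ng) < mrate
        if (any(mut)) {
          child[mut] <- vapply(which(mut), function(ix) {
            r <- ranges[[ix]]
            if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
          }, 0L)
        }
        child <- repair_chromosome(host, child, ranges)
      }
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, score, 0)
    gen_best <- which.min(fit)
    if (fit[gen_best] < best_cost) {
      best_cost <- fit[gen_best]
      best_genes <- pop[[gen_best]]
    }
    history <- c(history, best_cost)
  }
  ord <- decode_chromosome(host, best_genes)
  m <- tree_collapse(tg, ord, scheme, collapse_cfg)
  if (use_right_push) m <- right_push(m)
  list(best_mapping = m, best_cost = best_cost, best_ordering = ord,
       history = history)
}
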