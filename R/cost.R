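#' Event cost schemes
#'
#' Per-event weights used to score a cophylogeny mapping.  The default is the
#' Jungle scheme: codivergence 0, duplication 1, host switch 2 (a duplication
#' followed by a switch), loss 1.  Any non-negative weights are accepted.
#'
#' @param codivergence,duplication,host_switch,loss non-negative weights.
#' @return an object of class `cophy_costs`.
#' @export
cost_scheme <- function(codivergence = 0, duplication = 1,
                        host_switch = 2, loss = 1) {
  w <- c(codivergence = codivergence, duplication = duplication,
         host_switch = host_switch, loss = loss)
  if (any(!is.finite(w)) || any(w < 0)) stop("event weights must be finite and non-negative")
  structure(list(w_codivergence = codivergence, w_duplication = duplication,
                 w_host_switch = host_switch, w_loss = loss),
            class = "cophy_costs")
}

#' @rdname cost_scheme
#' @export
jungle_scheme <- function() cost_scheme(0, 1, 2, 1)

#' Total cost of an event tally
#'
#' @param counts named list or vector with `n_codivergence`, `n_duplication`,
#'   `n_host_switch`, `n_loss`.
#' @param scheme a [cost_scheme()].
#' @return numeric scalar
#'   `w_c * n_c + w_d * n_d + w_s * n_s + w_l * n_l`.
#' @export
total_cost <- function(counts, scheme = jungle_scheme()) {
  counts <- as.list(counts)
  need <- c("n_codivergence", "n_duplication", "n_host_switch", "n_loss")
  if (!all(need %in% names(counts))) stop("counts must carry ", paste(need, collapse = ", "))
  v <- vapply(counts[need], function(x) as.numeric(x)[1L], 0)
  if (any(v < 0)) stop("event counts must be non-negative")
  sum(v * c(scheme$w_codivergence, scheme$w_duplication,
            scheme$w_host_switch, scheme$w_loss))
}
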