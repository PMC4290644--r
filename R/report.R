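#' Serialise a mapping as a JSON report
#'
#' The report is self-contained: it embeds the input Newick/association
#' texts, the node ordering, the full ordered event history (with
#' materialised losses and human-readable clade descriptors), the re-tallied
#' event counts, the total cost under the supplied scheme, and an echo of
#' the configuration and seed.  `read_report()` rebuilds the mapping from a
#' report, so reports can be re-audited.
#'
#' @param m a `cophy_mapping`.
#' @param scheme a [cost_scheme()].
#' @param file optional path to write to.
#' @param config,seed optional run configuration echo.
#' @param deterministic suppress the timestamp field for byte-stable output.
#' @return (invisibly) the JSON string.
#' @export
write_report <- function(m, scheme = jungle_scheme(), file = NULL,
                         config = NULL, seed = NULL, deterministic = FALSE) {
  tg <- m$tanglegram
  H <- tg$host
  counts <- count_events(m)
  hist <- event_history(m)
  key <- function(nodes) vapply(nodes, function(v) clade_key(H, v), "")
  pkey <- function(nodes) {
    vapply(nodes, function(v) {
      paste(clade_labels(tg$parasite, v), collapse = "+")
    }, "")
  }
  edge_desc <- function(lower) {
    vapply(lower, function(v) {
      if (is.na(v)) return(NA_character_)
      up <- H$parent[v]
      paste0(if (is.na(up)) "(root)" else clade_key(H, up),
             "->", clade_key(H, v))
    }, "")
  }
  events_out <- data.frame(
    kind = hist$kind,
    parasite = pkey(hist$node),
    host = key(hist$host),
    time_index = hist$time,
    takeoff_edge = ifelse(hist$kind == "host_switch",
                          edge_desc(hist$host), NA_character_),
    landing_edge = ifelse(hist$kind == "host_switch",
                          edge_desc(hist$landing), NA_character_),
    stringsAsFactors = FALSE)
  parts <- write_tanglegram(tg)
  obj <- list(
    tool = "cophycollapse",
    version = as.character(utils::packageVersion("cophycollapse")),
    seed = seed,
    config = config,
    input = list(host = parts$host, parasite = parts$parasite,
                 associations = parts$assoc),
    scheme = list(codivergence = scheme$w_codivergence,
                  duplication = scheme$w_duplication,
                  host_switch = scheme$w_host_switch,
                  loss = scheme$w_loss),
    ordering = list(n_internal = m$ordering$n_internal,
                    depth = m$ordering$depth),
    counts = counts,
    total_cost = total_cost(counts, scheme),
    events = events_out,
    raw_events = m$events)
  if (!deterministic) obj$timestamp <- format(Sys.time(), tz = "UTC")
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null")
  if (!is.null(file)) writeLines(json, file)
  invisible(as.character(json))
}

#' Rebuild a mapping from a JSON report
#'
#' @param text_or_file JSON text or a file path.
#' @return list with `mapping` (a `cophy_mapping`), `scheme` and the parsed
#'   report.
#' @export
read_report <- function(text_or_file) {
  rpt <- jsonlite::fromJSON(text_or_file)
  need <- c("input", "ordering", "raw_events", "scheme")
  if (!all(need %in% names(rpt))) {
    stop("report schema mismatch: missing ",
         paste(setdiff(need, names(rpt)), collapse = ", "))
  }
  tg <- read_tanglegram(rpt$input$host, rpt$input$parasite,
                        rpt$input$associations)
  ord <- new_ordering(rpt$ordering$depth, rpt$ordering$n_internal)
  if (!validate_ordering(tg$host, ord)) stop("report carries an invalid ordering")
  ev <- as.data.frame(rpt$raw_events)
  for (col in c("node", "host", "time", "landing", "takeoff_child",
                "landing_child")) {
    ev[[col]] <- as.integer(ev[[col]])
  }
  ev$pre_root <- as.logical(ev$pre_root)
  m <- new_cophy_mapping(tg, ord, ev)
  sc <- cost_scheme(rpt$scheme$codivergence, rpt$scheme$duplication,
                    rpt$scheme$host_switch, rpt$scheme$loss)
  list(mapping = m, scheme = sc, report = rpt)
}
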