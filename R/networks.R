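#' Annual dyadic grooming rates
#'
#' Converts an observation table to dyadic rates for one year: minutes of
#' grooming given standardized by minutes of shared party membership.
#' Ordered dyads whose exposure falls below `min_exposure` (including
#' zero-exposure dyads, whose rate is undefined) are omitted.
#'
#' @param obs observation table (`year`, `actor_id`, `receiver_id`,
#'   `groom_min`, `co_party_min`).
#' @param year the annual window to extract.
#' @param min_exposure minimum dyadic co-party minutes for a rate to be
#'   considered observed. Default 0: any positive co-membership qualifies.
#' @return data.frame of class `dyad_rates`: `year`, `actor`, `receiver`,
#'   `groom_min`, `co_party_min`, `rate`. Empty (with a warning) if the
#'   year is absent.
#' @examples
#' obs <- data.frame(year = 1, actor_id = "a", receiver_id = "b",
#'                   groom_min = 30, co_party_min = 600)
#' compute_dyadic_rates(obs, 1)$rate  # 0.05
#' @export
compute_dyadic_rates <- function(obs, year, min_exposure = 0) {
  stopifnot(is.data.frame(obs), min_exposure >= 0)
  o <- obs[obs$year == year, , drop = FALSE]
  if (nrow(o) == 0)
    warning(sprintf("no observations for year %s; returning empty rate table", year))
  keep <- o$co_party_min > 0 & o$co_party_min >= min_exposure
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("year %s: omitting %d dyad(s) below exposure threshold %g",
                    year, n_drop, min_exposure))
  o <- o[keep, , drop = FALSE]
  res <- data.frame(
    year = o$year,
    actor = o$actor_id,
    receiver = o$receiver_id,
    groom_min = o$groom_min,
    co_party_min = o$co_party_min,
    rate = if (nrow(o)) o$groom_min / o$co_party_min else numeric(0),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("dyad_rates", "data.frame")
  res
}

composition_sexes <- function(composition) {
  switch(composition,
         mixed = c("F", "M"),
         male_only = "M",
         female_only = "F",
         stop(sprintf("unknown composition '%s'", composition), call. = FALSE))
}

#' Build one annual grooming network
#'
#' Assembles an igraph network for one year and one sex composition. Nodes
#' are all roster members of that composition alive that year -- membership,
#' not interaction, defines presence, so individuals with no grooming are
#' retained as isolates. Directed edges carry the dyadic rate; undirected
#' edges carry the sum of the two directed rates of the dyad. Zero-rate
#' dyads carry no edge.
#'
#' @param rates a `dyad_rates` table (see [compute_dyadic_rates()]).
#' @param roster individual-year attribute table (`id`, `year`, `sex`,
#'   `age`, `rank`, `time_swollen`).
#' @param year annual window.
#' @param composition one of `"mixed"`, `"male_only"`, `"female_only"`.
#' @param directed logical.
#' @return an igraph graph with vertex attributes `sex`, `age`, `rank`,
#'   `time_swollen` and graph attributes `year`, `composition`.
#' @export
build_network <- function(rates, roster, year,
                          composition = c("mixed", "male_only", "female_only"),
                          directed = TRUE) {
  composition <- match.arg(composition)
  ry <- roster[roster$year == year, , drop = FALSE]
  r <- rates[rates$year == year, , drop = FALSE]
  missing_ids <- setdiff(unique(c(r$actor, r$receiver)), ry$id)
  if (length(missing_ids) > 0)
    stop(sprintf("rate table references id(s) missing from roster year %s: %s",
                 year, paste(missing_ids, collapse = ", ")), call. = FALSE)
  nodes <- ry[ry$sex %in% composition_sexes(composition),
              c("id", "sex", "age", "rank", "time_swollen"), drop = FALSE]
  e <- r[r$actor %in% nodes$id & r$receiver %in% nodes$id & r$rate > 0,
         c("actor", "receiver", "rate"), drop = FALSE]
  if (!directed && nrow(e) > 0) {
    lo <- pmin(e$actor, e$receiver)
    hi <- pmax(e$actor, e$receiver)
    w <- tapply(e$rate, paste(lo, hi, sep = "\r"), sum)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    e <- data.frame(actor = vapply(parts, `[`, "", 1),
                    receiver = vapply(parts, `[`, "", 2),
                    rate = as.numeric(w), stringsAsFactors = FALSE)
  }
  names(e) <- c("from", "to", "weight")
  g <- igraph::graph_from_data_frame(e, directed = directed, vertices = nodes)
  g <- igraph::set_graph_attr(g, "year", year)
  igraph::set_graph_attr(g, "composition", composition)
}

#' Build the full annual network sequence
#'
#' One directed/undirected network pair per (year x composition), ordered by
#' year then composition. Degree and strength downstream use the directed
#' member; betweenness, transitivity and eigenvector centrality the
#' undirected member.
#'
#' @param obs observation table.
#' @param roster attribute table.
#' @param compositions character vector of compositions to build.
#' @param min_exposure passed to [compute_dyadic_rates()].
#' @return list of entries `list(year, composition, directed, undirected)`.
#' @export
network_sequence <- function(obs, roster,
                             compositions = c("mixed", "male_only", "female_only"),
                             min_exposure = 0) {
  years <- sort(unique(obs$year))
  if (length(years) == 0) {
    warning("empty observation table; no networks built")
    return(list())
  }
  out <- list()
  for (y in years) {
    rates <- compute_dyadic_rates(obs, y, min_exposure)
    for (comp in compositions) {
      out[[length(out) + 1]] <- list(
        year = y, composition = comp,
        directed = build_network(rates, roster, y, comp, directed = TRUE),
        undirected = build_network(rates, roster, y, comp, directed = FALSE))
    }
  }
  out
}

#' Write networks as edge lists and GraphML
#'
#' @param nets result of [network_sequence()].
#' @param dir output directory.
#' @return invisibly, the edge-list CSV path.
#' @export
write_networks <- function(nets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(nets, function(entry) {
    g <- entry$undirected
    e <- igraph::as_data_frame(g, what = "edges")
    if (nrow(e) == 0) return(NULL)
    data.frame(year = entry$year, composition = entry$composition,
               u = e$from, v = e$to, weight = e$weight,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  csv <- file.path(dir, "edges_undirected.csv")
  utils::write.csv(edges, csv, row.names = FALSE)
  for (entry in nets) {
    igraph::write_graph(
      entry$undirected,
      file.path(dir, sprintf("net_%s_%s.graphml", entry$year, entry$composition)),
      format = "graphml")
  }
  invisible(csv)
}
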