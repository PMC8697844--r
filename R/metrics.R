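#' Directed degree and strength
#'
#' In-degree and out-degree count grooming partners (any positive-rate
#' edge); in-strength and out-strength sum the dyadic rates of grooming
#' received and given. Isolates score zero on all four.
#'
#' @param net a directed annual grooming network.
#' @return data.frame: `id`, `in_degree`, `out_degree`, `in_strength`,
#'   `out_strength`, in vertex order.
#' @export
degree_strength <- function(net) {
  if (!igraph::is_directed(net))
    stop("degree_strength requires a directed network", call. = FALSE)
  w <- igraph::E(net)$weight
  data.frame(
    id = igraph::V(net)$name,
    in_degree = as.integer(igraph::degree(net, mode = "in")),
    out_degree = as.integer(igraph::degree(net, mode = "out")),
    in_strength = as.numeric(igraph::strength(net, mode = "in", weights = w)),
    out_strength = as.numeric(igraph::strength(net, mode = "out", weights = w)),
    stringsAsFactors = FALSE
  )
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness on the undirected weighted network, counting for
#' each ego the shortest paths between other member pairs that pass through
#' it (ties contribute fractionally; endpoints excluded; unnormalized).
#' Grooming rates are affinities, so they are converted to path costs
#' before shortest paths are computed: by default the cost of an edge is
#' the reciprocal of its weight, so stronger ties make shorter paths. The
#' alternative `"linear"` transform uses `max(w) - w + min(w)`.
#'
#' @param net an undirected annual grooming network with positive weights.
#' @param transform affinity-to-distance transform.
#' @return named numeric vector of betweenness scores, in vertex order.
#' @export
weighted_betweenness <- function(net, transform = c("reciprocal", "linear")) {
  transform <- match.arg(transform)
  if (igraph::is_directed(net))
    stop("weighted_betweenness requires an undirected network", call. = FALSE)
  w <- igraph::E(net)$weight
  if (length(w) == 0)
    return(stats::setNames(rep(0, igraph::vcount(net)), igraph::V(net)$name))
  if (any(w <= 0))
    stop("weighted_betweenness: all edge weights must be positive", call. = FALSE)
  dist <- switch(transform,
                 reciprocal = 1 / w,
                 linear = max(w) - w + min(w))
  b <- igraph::betweenness(net, weights = dist, directed = FALSE,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Weighted local transitivity (Barrat clustering coefficient)
#'
#' Proportion of ego's partners that are also partners with each other,
#' weighted by ego's tie strengths (Barrat et al. coefficient):
#' `c_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh`.
#' Egos with fewer than two partners have no defined value and return `NA`.
#'
#' @param net an undirected annual grooming network.
#' @return named numeric vector in \[0, 1\] (or `NA`), in vertex order.
#' @export
weighted_local_transitivity <- function(net) {
  if (igraph::is_directed(net))
    stop("weighted_local_transitivity requires an undirected network", call. = FALSE)
  if (igraph::ecount(net) == 0)
    return(stats::setNames(rep(NA_real_, igraph::vcount(net)), igraph::V(net)$name))
  ct <- igraph::transitivity(net, type = "barrat",
                             weights = igraph::E(net)$weight, isolates = "NaN")
  ct[is.nan(ct)] <- NA_real_
  stats::setNames(as.numeric(ct), igraph::V(net)$name)
}

#' Weighted eigenvector centrality
#'
#' Principal eigenvector of the weighted adjacency matrix, nonnegative and
#' rescaled so the maximum over nodes is 1. Computed on the full graph:
#' nodes in minor disconnected components score (numerically) zero. A
#' network with no edges, or all-zero weights, yields all zeros with a
#' warning.
#'
#' @param net an undirected annual grooming network.
#' @return named numeric vector in \[0, 1\], in vertex order.
#' @export
eigenvector_centrality <- function(net) {
  if (igraph::is_directed(net))
    stop("eigenvector_centrality requires an undirected network", call. = FALSE)
  nm <- igraph::V(net)$name
  w <- igraph::E(net)$weight
  if (length(w) == 0 || all(w == 0)) {
    warning("network has no positive-weight edges; eigenvector centrality set to 0")
    return(stats::setNames(rep(0, igraph::vcount(net)), nm))
  }
  # ARPACK draws a random starting vector; pin (and afterwards restore) the
  # RNG stream so repeated calls are bit-identical and callers' seeds are
  # untouched
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(20211201L)
  ev <- igraph::eigen_centrality(net, weights = w, scale = TRUE)$vector
  stats::setNames(as.numeric(ev), nm)
}

METRIC_NAMES <- c("in_degree", "out_degree", "in_strength", "out_strength",
                  "betweenness", "local_transitivity", "eigenvector_centrality")

#' Node-level integration metrics for an annual network sequence
#'
#' Computes the seven integration measures for every node of every
#' (year x composition) network pair and joins the individual-year
#' attributes. Degree and strength come from the directed member of each
#' pair; betweenness, local transitivity and eigenvector centrality from
#' the undirected member.
#'
#' @param nets list of network pairs from [network_sequence()].
#' @param betweenness_transform passed to [weighted_betweenness()].
#' @return data.frame with one row per node-year-composition: `id`, `year`,
#'   `composition`, the seven metrics, `sex`, `age`, `rank`, `time_swollen`.
#'   Local transitivity is `NA` where ego has fewer than two partners.
#' @export
metrics_table <- function(nets, betweenness_transform = "reciprocal") {
  rows <- lapply(nets, function(entry) {
    gd <- entry$directed
    gu <- entry$undirected
    ids_d <- igraph::V(gd)$name
    ids_u <- igraph::V(gu)$name
    if (!identical(sort(ids_d), sort(ids_u)))
      stop(sprintf("node-set mismatch between directed and undirected networks (year %s, %s)",
                   entry$year, entry$composition), call. = FALSE)
    ds <- degree_strength(gd)
    und <- data.frame(
      id = ids_u,
      betweenness = as.numeric(weighted_betweenness(gu, betweenness_transform)),
      local_transitivity = as.numeric(weighted_local_transitivity(gu)),
      eigenvector_centrality = as.numeric(suppressWarnings(eigenvector_centrality(gu))),
      stringsAsFactors = FALSE)
    attrs <- data.frame(
      id = ids_u,
      sex = igraph::V(gu)$sex,
      age = igraph::V(gu)$age,
      rank = igraph::V(gu)$rank,
      time_swollen = igraph::V(gu)$time_swollen,
      stringsAsFactors = FALSE)
    m <- merge(merge(ds, und, by = "id"), attrs, by = "id")
    m$year <- entry$year
    m$composition <- entry$composition
    m
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res <- res[, c("id", "year", "composition", METRIC_NAMES,
                 "sex", "age", "rank", "time_swollen")]
  res <- res[order(res$year, res$composition, res$id), , drop = FALSE]
  rownames(res) <- NULL
  n_undef <- sum(is.na(res$local_transitivity))
  if (n_undef > 0)
    message(sprintf("local transitivity undefined (degree < 2) for %d node-year rows",
                    n_undef))
  res
}

#' Observations to metrics in one call
#'
#' Runs [network_sequence()] then [metrics_table()].
#'
#' @param obs observation table.
#' @param roster attribute table.
#' @param compositions compositions to build.
#' @param min_exposure dyadic exposure threshold.
#' @param betweenness_transform passed through.
#' @return see [metrics_table()].
#' @export
compute_metrics <- function(obs, roster,
                            compositions = c("mixed", "male_only", "female_only"),
                            min_exposure = 0,
                            betweenness_transform = "reciprocal") {
  nets <- network_sequence(obs, roster, compositions, min_exposure)
  metrics_table(nets, betweenness_transform)
}
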