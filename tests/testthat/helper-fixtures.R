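# Shared fixtures: all built in code at test time.

# A small, fast scenario for unit tests (the full default scenario is used
# only where a test's property needs it).
tiny_scenario <- function(seed = 1, ...) {
  slum_scenario(seed = seed, n_nodes = 60L, n_dwellings = 30L,
                n_facilities_by_class = c("private clinic" = 3L,
                                          "public clinic" = 3L,
                                          "private hospital" = 2L,
                                          "public hospital" = 2L), ...)
}

# Hand-built network: vertices with coordinates, edges with explicit lengths.
toy_network <- function(ids, x, y, edges, lengths) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$x <- x
  igraph::V(g)$y <- y
  if (length(lengths) > 0)
    g <- igraph::add_edges(g, as.vector(t(matrix(match(edges, ids),
                                                 ncol = 2))),
                           attr = list(length_m = lengths))
  g
}

# Random connected small graph with metric coordinates (for oracle tests).
random_connected_graph <- function(n) {
  x <- stats::runif(n, 0, 100); y <- stats::runif(n, 0, 100)
  ids <- sprintf("n%d", seq_len(n))
  D <- as.matrix(stats::dist(cbind(x, y)))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < 0.5
  full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
  mst_el <- igraph::as_edgelist(igraph::mst(full), names = FALSE)
  el <- unique(rbind(pairs[keep, , drop = FALSE],
                     cbind(pmin(mst_el[, 1], mst_el[, 2]),
                           pmax(mst_el[, 1], mst_el[, 2]))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- ids
  igraph::V(g)$x <- x
  igraph::V(g)$y <- y
  igraph::E(g)$length_m <- D[el]
  g
}

# Independent shortest-path oracle: exhaustive enumeration of simple paths.
brute_shortest_m <- function(network, a, b) {
  ids <- igraph::V(network)$name
  el <- igraph::as_edgelist(network)
  len <- igraph::E(network)$length_m
  adj <- lapply(ids, function(v) {
    i <- which(el[, 1] == v | el[, 2] == v)
    list(nb = ifelse(el[i, 1] == v, el[i, 2], el[i, 1]), w = len[i])
  })
  names(adj) <- ids
  best <- Inf
  walk <- function(v, seen, acc) {
    if (acc >= best) return(invisible())
    if (v == b) { best <<- acc; return(invisible()) }
    nb <- adj[[v]]
    for (k in seq_along(nb$nb)) {
      u <- nb$nb[k]
      if (!(u %in% seen)) walk(u, c(seen, u), acc + nb$w[k])
    }
  }
  walk(a, a, 0)
  best
}

# Independent bypass oracle: explicit pairwise comparison.
brute_bypasses <- function(totals, ids, visited_id) {
  vtot <- totals[ids == visited_id]
  hit <- which(totals < vtot & ids != visited_id)
  data.frame(bypassed = ids[hit], weight = vtot - totals[hit],
             stringsAsFactors = FALSE)
}

# A minimal raw visit tibble.
make_visits <- function(...) {
  rows <- list(...)
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
    data.frame(visit_id = r$visit_id, dwelling_id = r$dwelling_id,
               facility_id = r$facility_id,
               reported_travel_min = r$reported_travel_min %||% 10,
               transport_cost = r$transport_cost %||% 0,
               consultation_cost = r$consultation_cost %||% 50,
               wait_min = r$wait_min %||% 20,
               mode = r$mode %||% "foot",
               stringsAsFactors = FALSE))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
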