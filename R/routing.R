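#' Pedestrian routing over a road-and-footpath network
#'
#' The road-and-footpath network is an undirected igraph whose vertices carry
#' metric coordinates (`x`, `y`, metres) and whose edges carry a strictly
#' positive `length_m`. Dwellings and facilities are snapped to their nearest
#' network node and travel times are shortest-path distances divided by a
#' constant walking speed: the study design assumes all trips are made on
#' foot from home.
#'
#' @name routing
NULL

check_network <- function(network) {
  if (!igraph::is_igraph(network) || igraph::vcount(network) == 0)
    abort_routing("network is empty or not an igraph object")
  if (igraph::ecount(network) > 0) {
    len <- igraph::E(network)$length_m
    if (is.null(len) || any(!is.finite(len)) || any(len <= 0))
      abort_routing("every network edge must carry a finite positive length_m")
  }
  invisible(network)
}

#' Snap a point to its nearest network node
#'
#' Uses straight-line (Euclidean) distance to node coordinates; ties are
#' broken by the lexicographically lowest node id. Snapping to nodes rather
#' than edge interiors is a documented approximation that is negligible on
#' dense footpath networks.
#'
#' @param x,y Point coordinates in the network's metric system.
#' @param network Road network (igraph with vertex attributes `x`, `y`).
#' @return The node id (vertex name) of the nearest node.
#' @export
snap_to_node <- function(x, y, network) {
  check_network(network)
  nx <- igraph::V(network)$x
  ny <- igraph::V(network)$y
  ids <- igraph::V(network)$name
  d2 <- (nx - x)^2 + (ny - y)^2
  hit <- which(d2 == min(d2))
  if (length(hit) > 1) hit <- hit[order(ids[hit])][1]
  ids[hit]
}

#' Shortest-path network distance between two nodes
#'
#' @param network Road network.
#' @param a,b Node ids (vertex names).
#' @return Minimum total edge length in metres over all paths from `a` to `b`.
#' @export
shortest_path_m <- function(network, a, b) {
  check_network(network)
  ids <- igraph::V(network)$name
  if (!(a %in% ids) || !(b %in% ids))
    abort_routing(sprintf("unknown node id: %s",
                          paste(setdiff(c(a, b), ids), collapse = ", ")))
  d <- igraph::distances(network, v = a, to = b, weights = igraph::E(network)$length_m)[1, 1]
  if (!is.finite(d))
    abort_routing(sprintf("nodes %s and %s are in different components", a, b))
  d
}

#' Convert a network distance to walking time
#'
#' @param distance_m Distance in metres.
#' @param walking_speed_m_per_min Walking speed in metres per minute (> 0).
#' @return Travel time in minutes.
#' @export
travel_time_min <- function(distance_m, walking_speed_m_per_min) {
  if (!is.numeric(walking_speed_m_per_min) || walking_speed_m_per_min <= 0)
    abort_config("walking speed must be positive")
  distance_m / walking_speed_m_per_min
}

#' Bridge stray components onto the main network
#'
#' OSM extracts commonly contain small disconnected fragments. Each smaller
#' component is joined to the largest component by a straight-line edge
#' between its closest pair of nodes, at a configurable length penalty that
#' stands in for informal off-network walking.
#'
#' @param network Road network.
#' @param penalty Multiplier applied to the Euclidean length of each added
#'   bridge edge (default 1.5).
#' @return A connected network.
#' @export
connect_components <- function(network, penalty = 1.5) {
  check_network(network)
  comp <- igraph::components(network)
  while (comp$no > 1) {
    main <- which.max(comp$csize)
    other <- which(comp$membership != main)
    inmain <- which(comp$membership == main)
    ox <- igraph::V(network)$x[other]; oy <- igraph::V(network)$y[other]
    mx <- igraph::V(network)$x[inmain]; my <- igraph::V(network)$y[inmain]
    dd <- outer(ox, mx, "-")^2 + outer(oy, my, "-")^2
    hit <- arrayInd(which.min(dd), dim(dd))
    from <- igraph::V(network)$name[other[hit[1]]]
    to <- igraph::V(network)$name[inmain[hit[2]]]
    len <- penalty * sqrt(dd[hit[1], hit[2]])
    network <- igraph::add_edges(network,
                                 c(igraph::V(network)[from], igraph::V(network)[to]),
                                 attr = list(length_m = len))
    comp <- igraph::components(network)
  }
  network
}

#' Travel-time matrix between dwellings and substitutable facilities
#'
#' Computes, for every (dwelling, facility) pair with the facility flagged
#' substitutable, the walking time along the shortest network path between
#' their snapped nodes. Implemented as single-source shortest-path trees
#' rooted at each facility node, which is numerically identical to pairwise
#' queries.
#'
#' @param dwellings Tibble with columns `id`, `snapped_node`.
#' @param facilities Tibble with columns `id`, `snapped_node`, `substitutable`.
#' @param network Road network.
#' @param walking_speed_m_per_min Walking speed (m/min).
#' @return A numeric matrix, rows = dwelling ids, columns = substitutable
#'   facility ids, entries in minutes.
#' @export
travel_time_matrix <- function(dwellings, facilities, network,
                               walking_speed_m_per_min = 80) {
  check_network(network)
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  if (nrow(fac) == 0) abort_input("no substitutable facilities to route to")
  if (is.null(dwellings$snapped_node) || anyNA(dwellings$snapped_node) ||
      is.null(fac$snapped_node) || anyNA(fac$snapped_node))
    abort_routing("all sites must be snapped to network nodes first")
  src <- unique(fac$snapped_node)
  dst <- unique(dwellings$snapped_node)
  dm <- igraph::distances(network, v = src, to = dst,
                          weights = igraph::E(network)$length_m)
  dm <- dm[match(fac$snapped_node, src), match(dwellings$snapped_node, dst),
           drop = FALSE]
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
    abort_routing(sprintf(
      "no path between facility %s and dwelling %s (disconnected network; see connect_components())",
      fac$id[bad[1]], dwellings$id[bad[2]]))
  }
  tt <- t(dm) / walking_speed_m_per_min
  dimnames(tt) <- list(dwellings$id, fac$id)
  tt
}

#' Snap dwellings and facilities to the network
#'
#' Fills/overwrites the `snapped_node` column of both site tables.
#'
#' @param dwellings,facilities Site tibbles with `x`, `y` columns.
#' @param network Road network.
#' @return A list with elements `dwellings` and `facilities`.
#' @export
snap_sites <- function(dwellings, facilities, network) {
  snap1 <- function(df) {
    df$snapped_node <- vapply(seq_len(nrow(df)), function(i)
      snap_to_node(df$x[i], df$y[i], network), character(1))
    df
  }
  list(dwellings = snap1(dwellings), facilities = snap1(facilities))
}
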