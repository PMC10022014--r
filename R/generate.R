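#' Generate a synthetic road-and-footpath network
#'
#' Draws `n_nodes` uniform points in the square study area, connects pairs
#' closer than the random-geometric-graph connectivity radius, then adds the
#' Euclidean minimum-spanning-tree edges so the network is always connected.
#' Every edge carries its Euclidean length in metres. The result is a simple,
#' reproducible stand-in for an OSM footpath extract.
#'
#' @param scenario A [slum_scenario()].
#' @return An undirected igraph with vertex attributes `name`, `x`, `y` and
#'   edge attribute `length_m`.
#' @export
generate_network <- function(scenario) {
  validate_scenario(scenario)
  n <- scenario$n_nodes
  side <- scenario$area_side_m
  set.seed(scenario$seed)
  x <- stats::runif(n, 0, side)
  y <- stats::runif(n, 0, side)
  ids <- sprintf("n%05d", seq_len(n))

  D <- as.matrix(stats::dist(cbind(x, y)))
  # RGG connectivity radius ~ sqrt(log n / (pi n)) on the unit square
  r <- 1.1 * side * sqrt(log(max(n, 3)) / (pi * n))
  adj <- D <= r
  adj[!lower.tri(adj)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)

  full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
  mst <- igraph::mst(full, weights = igraph::E(full)$weight)
  mst_el <- igraph::as_edgelist(mst, names = FALSE)
  el <- unique(rbind(
    cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])),
    cbind(pmin(mst_el[, 1], mst_el[, 2]), pmax(mst_el[, 1], mst_el[, 2]))
  ))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- ids
  igraph::V(g)$x <- x
  igraph::V(g)$y <- y
  igraph::E(g)$length_m <- D[el]
  check_network(g)
  g
}

#' Place dwellings and facilities and plant latent quality
#'
#' Dwellings and clinics are placed uniformly over the area; hospital
#' locations are sampled with probability proportional to their distance from
#' the area centroid, which makes hospitals peripheral and reproduces the
#' observed geometry in which hospitals draw patients from further away.
#' Each facility receives a latent quality `q ~ Normal(class mean, quality_sd)`
#' (the planted "perceived quality", in currency units), a mean consultation
#' price (hospitals dearer than clinics on average) and a mean waiting time.
#' All sites are snapped to the network.
#'
#' @param scenario A [slum_scenario()].
#' @param network Network from [generate_network()].
#' @return A list with `dwellings` (tibble: id, x, y, snapped_node),
#'   `facilities` (tibble: id, x, y, size_class, funding, class,
#'   substitutable, mean_price, mean_wait_min, snapped_node) and `truth`
#'   (tibble: facility_id, q).
#' @export
place_sites <- function(scenario, network) {
  validate_scenario(scenario)
  check_network(network)
  if (igraph::components(network)$no != 1)
    abort_config("place_sites requires a connected network")
  nf <- scenario$n_facilities_by_class
  if (sum(nf) > igraph::vcount(network))
    abort_config("more facilities requested than network nodes available for placement")
  side <- scenario$area_side_m
  set.seed(scenario$seed + 1L)

  dwellings <- tibble::tibble(
    id = sprintf("d%05d", seq_len(scenario$n_dwellings)),
    x = stats::runif(scenario$n_dwellings, 0, side),
    y = stats::runif(scenario$n_dwellings, 0, side)
  )

  classes <- rep(HCP_CLASSES, times = nf[HCP_CLASSES])
  n_fac <- length(classes)
  fx <- numeric(n_fac); fy <- numeric(n_fac)
  hosp <- grepl("hospital", classes)
  n_cl <- sum(!hosp)
  fx[!hosp] <- stats::runif(n_cl, 0, side)
  fy[!hosp] <- stats::runif(n_cl, 0, side)
  if (any(hosp)) {
    # weighted sample of candidate points, weight = distance from centroid
    cand_x <- stats::runif(200 * sum(hosp), 0, side)
    cand_y <- stats::runif(200 * sum(hosp), 0, side)
    w <- euclid(cand_x, cand_y, side / 2, side / 2)
    pick <- sample.int(length(cand_x), sum(hosp), prob = w)
    fx[hosp] <- cand_x[pick]
    fy[hosp] <- cand_y[pick]
  }

  q <- stats::rnorm(n_fac, scenario$quality_by_class_mean[classes],
                    scenario$quality_sd)
  mean_price <- scenario$price_by_class_mean[classes] *
    stats::rlnorm(n_fac, 0, 0.25)
  mean_wait <- scenario$wait_by_class_mean[classes] *
    stats::rlnorm(n_fac, 0, 0.25)

  facilities <- tibble::tibble(
    id = sprintf("f%03d", seq_len(n_fac)),
    x = fx, y = fy,
    size_class = ifelse(hosp, "hospital", "clinic"),
    funding = ifelse(grepl("private", classes), "private", "public"),
    class = classes,
    substitutable = TRUE,
    mean_price = as.numeric(mean_price),
    mean_wait_min = as.numeric(mean_wait)
  )

  snapped <- snap_sites(dwellings, facilities, network)
  truth <- tibble::tibble(facility_id = facilities$id, q = q)
  list(dwellings = snapped$dwellings, facilities = snapped$facilities,
       truth = truth)
}

#' True generalized access costs of the synthetic population
#'
#' The generator's own access-cost matrix: for dwelling d and facility f,
#' `AC(d, f) = mean_price_f + value_of_time * (travel_min(d, f) + mean_wait_f)`
#' with zero transport cost under the on-foot assumption. This is the cost
#' that drives the simulated choice rule, and the reference against which
#' the analysis pipeline is validated.
#'
#' @param scenario A [slum_scenario()].
#' @param dwellings,facilities Site tables from [place_sites()].
#' @param network The road network.
#' @return List with `ac` (dwellings x facilities access-cost matrix) and
#'   `tt` (the underlying travel-time matrix, minutes).
#' @export
true_access_cost_matrix <- function(scenario, dwellings, facilities, network) {
  tt <- travel_time_matrix(dwellings, facilities, network,
                           scenario$walking_speed_m_per_min)
  fac <- facilities[match(colnames(tt), facilities$id), ]
  ac <- sweep(scenario$value_of_time_per_min * tt, 2,
              fac$mean_price + scenario$value_of_time_per_min * fac$mean_wait_min,
              "+")
  list(ac = ac, tt = tt)
}

#' Simulate individual visit records
#'
#' Each visit originates at a uniformly drawn dwelling; the visited facility
#' is drawn from a multinomial-logit rule with
#' `P(f) proportional to exp(beta_cost * (q_f - AC(d, f)))`, so patients trade
#' off access cost against planted latent quality. Reported travel time is
#' the true network walking time under multiplicative lognormal noise;
#' consultation cost and waiting time are drawn around the facility means.
#' A fraction `missing_rate` of cost/waiting fields is blanked and a fraction
#' `placeholder_rate` of reported travel times is replaced by the 999-minute
#' placeholder, emulating the survey artefacts the cleaning module removes.
#'
#' @param scenario A [slum_scenario()].
#' @param network Road network.
#' @param dwellings,facilities,truth Output of [place_sites()].
#' @param n_visits Number of visit records to simulate (>= 1).
#' @return Tibble with columns visit_id, dwelling_id, facility_id,
#'   reported_travel_min, transport_cost, consultation_cost, wait_min, mode.
#' @export
simulate_visits <- function(scenario, network, dwellings, facilities, truth,
                            n_visits = 2000L) {
  validate_scenario(scenario)
  if (!is_count(n_visits)) abort_config("n_visits must be a positive integer")
  mats <- true_access_cost_matrix(scenario, dwellings, facilities, network)
  ac <- mats$ac; tt <- mats$tt
  q <- truth$q[match(colnames(ac), truth$facility_id)]
  set.seed(scenario$seed + 2L)

  dw_idx <- sample.int(nrow(dwellings), n_visits, replace = TRUE)
  util <- sweep(-scenario$beta_cost * ac, 2, scenario$beta_cost * q, "+")
  # row-stable softmax choice per visit
  fac_idx <- vapply(dw_idx, function(i) {
    u <- util[i, ]
    p <- exp(u - max(u))
    sample.int(length(p), 1L, prob = p)
  }, integer(1))

  fid <- colnames(ac)[fac_idx]
  fac <- facilities[match(fid, facilities$id), ]
  tt_true <- tt[cbind(dw_idx, fac_idx)]

  reported <- tt_true * stats::rlnorm(n_visits, 0, scenario$travel_noise_sdlog)
  consult <- fac$mean_price * stats::rlnorm(n_visits, 0, scenario$cost_noise_sdlog)
  wait <- fac$mean_wait_min * stats::rlnorm(n_visits, 0, scenario$cost_noise_sdlog)
  mode <- sample(names(scenario$mode_shares), n_visits, replace = TRUE,
                 prob = scenario$mode_shares)
  transport <- ifelse(mode == "foot", 0,
                      stats::rlnorm(n_visits, log(20), 0.4))

  if (scenario$missing_rate > 0) {
    consult[stats::runif(n_visits) < scenario$missing_rate] <- NA_real_
    wait[stats::runif(n_visits) < scenario$missing_rate] <- NA_real_
  }
  if (scenario$placeholder_rate > 0)
    reported[stats::runif(n_visits) < scenario$placeholder_rate] <- 999

  tibble::tibble(
    visit_id = sprintf("v%06d", seq_len(n_visits)),
    dwelling_id = dwellings$id[dw_idx],
    facility_id = fid,
    reported_travel_min = reported,
    transport_cost = transport,
    consultation_cost = consult,
    wait_min = wait,
    mode = mode
  )
}

#' Run the whole generator
#'
#' Convenience wrapper: network, sites, planted truth and visit records in
#' one call.
#'
#' @param scenario A [slum_scenario()].
#' @param n_visits Number of visit records.
#' @return List with `scenario`, `network`, `dwellings`, `facilities`,
#'   `truth`, `visits`.
#' @export
simulate_scenario <- function(scenario, n_visits = 2000L) {
  network <- generate_network(scenario)
  sites <- place_sites(scenario, network)
  visits <- simulate_visits(scenario, network, sites$dwellings,
                            sites$facilities, sites$truth, n_visits)
  list(scenario = scenario, network = network, dwellings = sites$dwellings,
       facilities = sites$facilities, truth = sites$truth, visits = visits)
}
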