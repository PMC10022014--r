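#' Read and write the pipeline's file formats
#'
#' The pipeline exchanges three layers: the road network as GraphML (vertex
#' attributes `x`, `y` in metres; edge attribute `length_m`), sites as a
#' GeoJSON FeatureCollection of point features (dwellings and facilities in
#' one file, distinguished by a `kind` property), and visit records as a
#' comma-separated table with a header row. Coordinates are assumed to be in
#' a projected metric system; geographic lon/lat inputs must be reprojected
#' before use, as all internal distances are metres.
#'
#' @name data_io
NULL

#' @rdname data_io
#' @param network Road network (igraph).
#' @param path File path.
#' @export
write_network <- function(network, path) {
  check_network(network)
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname data_io
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort_input(paste("network file not found:", path))
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse",
                             edge.attr.comb = list(length_m = "min", "ignore"))
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id))
    igraph::V(g)$name <- igraph::V(g)$id
  check_network(g)
  g
}

#' @rdname data_io
#' @param dwellings,facilities Site tibbles.
#' @export
write_sites <- function(dwellings, facilities, path) {
  feat <- function(x, y, props) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = props)
  }
  fd <- lapply(seq_len(nrow(dwellings)), function(i)
    feat(dwellings$x[i], dwellings$y[i],
         list(kind = "dwelling", id = dwellings$id[i])))
  ff <- lapply(seq_len(nrow(facilities)), function(i)
    feat(facilities$x[i], facilities$y[i],
         list(kind = "facility", id = facilities$id[i],
              size = facilities$size_class[i],
              funding = facilities$funding[i],
              substitutable = facilities$substitutable[i],
              mean_price = facilities$mean_price[i],
              mean_wait_min = facilities$mean_wait_min[i])))
  fc <- list(type = "FeatureCollection", features = c(fd, ff))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname data_io
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) abort_input(paste("sites file not found:", path))
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    abort_input("sites file is not a GeoJSON FeatureCollection")
  rows_d <- list(); rows_f <- list()
  for (i in seq_along(fc$features)) {
    ft <- fc$features[[i]]
    g <- ft$geometry; p <- ft$properties
    if (is.null(g) || is.null(g$type) || g$type != "Point" ||
        length(g$coordinates) != 2)
      abort_input(sprintf("sites feature %d: malformed point geometry", i))
    x <- as.numeric(g$coordinates[[1]]); y <- as.numeric(g$coordinates[[2]])
    if (!is.finite(x) || !is.finite(y))
      abort_input(sprintf("sites feature %d: non-finite coordinates", i))
    if (identical(p$kind, "dwelling")) {
      rows_d[[length(rows_d) + 1]] <- tibble::tibble(id = p$id, x = x, y = y)
    } else if (identical(p$kind, "facility")) {
      rows_f[[length(rows_f) + 1]] <- tibble::tibble(
        id = p$id, x = x, y = y,
        size_class = p$size, funding = p$funding,
        substitutable = isTRUE(p$substitutable),
        mean_price = if (is.null(p$mean_price)) NA_real_ else as.numeric(p$mean_price),
        mean_wait_min = if (is.null(p$mean_wait_min)) NA_real_ else as.numeric(p$mean_wait_min))
    } else {
      abort_input(sprintf("sites feature %d: unknown kind '%s'", i,
                          as.character(p$kind)))
    }
  }
  dwellings <- dplyr::bind_rows(rows_d)
  facilities <- dplyr::bind_rows(rows_f)
  for (tb in list(dwellings, facilities)) {
    if (nrow(tb) > 0 && anyDuplicated(tb$id))
      abort_input(paste("duplicate site ids:",
                        paste(unique(tb$id[duplicated(tb$id)]), collapse = ", ")))
  }
  if (nrow(facilities) > 0)
    facilities$class <- facility_class_vec(facilities$size_class,
                                           facilities$funding)
  list(dwellings = dwellings, facilities = facilities)
}

VISIT_COLS <- c("visit_id", "dwelling_id", "facility_id",
                "reported_travel_min", "transport_cost",
                "consultation_cost", "wait_min", "mode")

#' @rdname data_io
#' @param visits Visit-record tibble.
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits[, VISIT_COLS], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname data_io
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) abort_input(paste("visits file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(visit_id = "character",
                                       dwelling_id = "character",
                                       facility_id = "character"),
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(VISIT_COLS, names(df))
  if (length(missing_cols) > 0)
    abort_input(paste("visits file lacks columns:",
                      paste(missing_cols, collapse = ", ")))
  tibble::as_tibble(df[, VISIT_COLS])
}

#' Load and cross-validate the three input layers
#'
#' Reads the network, site and visit files and checks referential
#' integrity: every visit must reference a known dwelling and facility.
#' Unresolved ids are reported with their row numbers.
#'
#' @param network_path GraphML network file.
#' @param sites_path GeoJSON sites file (dwellings + facilities).
#' @param visits_path CSV visit-record file.
#' @return List with `network`, `dwellings`, `facilities`, `visits`.
#' @export
load_inputs <- function(network_path, sites_path, visits_path) {
  network <- read_network(network_path)
  sites <- read_sites(sites_path)
  visits <- read_visits(visits_path)
  if (nrow(visits) > 0) {
    bad_f <- !(visits$facility_id %in% sites$facilities$id)
    bad_d <- !(visits$dwelling_id %in% sites$dwellings$id)
    if (any(bad_f))
      abort_input(sprintf(
        "visits reference unknown facilities: %s (rows %s)",
        paste(unique(visits$facility_id[bad_f]), collapse = ", "),
        paste(utils::head(which(bad_f), 10), collapse = ", ")))
    if (any(bad_d))
      abort_input(sprintf(
        "visits reference unknown dwellings: %s (rows %s)",
        paste(unique(visits$dwelling_id[bad_d]), collapse = ", "),
        paste(utils::head(which(bad_d), 10), collapse = ", ")))
    if (anyDuplicated(visits$visit_id))
      abort_input("duplicate visit_id values in visits file")
  }
  list(network = network, dwellings = sites$dwellings,
       facilities = sites$facilities, visits = visits)
}

#' Write every layer of a simulated scenario to a directory
#'
#' Emits `network.graphml`, `sites.geojson`, `visits.csv`,
#' `ground_truth.csv` and `scenario.cfg` (a flat key=value record of the
#' generator parameters).
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_scenario_files <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("network.graphml", "sites.geojson", "visits.csv",
                            "ground_truth.csv", "scenario.cfg"))
  write_network(sim$network, paths[1])
  write_sites(sim$dwellings, sim$facilities, paths[2])
  write_visits(sim$visits, paths[3])
  utils::write.csv(sim$truth, paths[4], row.names = FALSE)
  sc <- sim$scenario
  keyvals <- c(
    sprintf("seed=%d", sc$seed),
    sprintf("area_side_m=%.10g", sc$area_side_m),
    sprintf("n_nodes=%d", sc$n_nodes),
    sprintf("n_dwellings=%d", sc$n_dwellings),
    sprintf("walking_speed_m_per_min=%.10g", sc$walking_speed_m_per_min),
    sprintf("value_of_time_per_min=%.10g", sc$value_of_time_per_min),
    sprintf("beta_cost=%.10g", sc$beta_cost),
    sprintf("quality_sd=%.10g", sc$quality_sd),
    sprintf("missing_rate=%.10g", sc$missing_rate),
    sprintf("placeholder_rate=%.10g", sc$placeholder_rate)
  )
  writeLines(keyvals, paths[5])
  invisible(paths)
}
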