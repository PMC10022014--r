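#' Run the full perceived-quality analysis on in-memory inputs
#'
#' Orchestrates the pipeline: clean the visit records, refresh facility
#' means and impute missing fields, snap sites and compute the travel-time
#' matrix, build per-visit access-cost profiles, detect bypass events,
#' aggregate the Perceived Quality Index, and assemble the descriptive
#' summaries.
#'
#' @param network Road network (igraph).
#' @param dwellings,facilities Site tables.
#' @param visits Raw visit table.
#' @param params A [cost_params()] object.
#' @param rules A [cleaning_rules()] object.
#' @param means_everywhere Cost the visited facility from facility means
#'   (sensitivity mode).
#' @param normalise_per_visit Per-visit weight normalisation for the PQI
#'   (sensitivity mode).
#' @return A `pqi_analysis` list: cleaned visits, cleaning/imputation
#'   reports, travel-time matrix, profiles, events, pqi table, class
#'   summary, correlations, mode shares.
#' @export
analyze_visits <- function(network, dwellings, facilities, visits,
                           params = cost_params(),
                           rules = cleaning_rules(),
                           means_everywhere = FALSE,
                           normalise_per_visit = FALSE) {
  check_network(network)
  network <- connect_components(network)
  if (is.null(facilities$class))
    facilities$class <- facility_class(facilities$size_class,
                                       facilities$funding)

  cleaned <- clean_visits(visits, rules)
  fac <- facilities
  if (nrow(cleaned$visits) > 0)
    fac <- facility_means(fac, cleaned$visits)
  imputed <- if (nrow(cleaned$visits) > 0)
    impute_missing(cleaned$visits, fac)
  else list(visits = cleaned$visits,
            log = tibble::tibble(visit_id = character(), field = character(),
                                 level = character(), value = numeric()))

  snapped <- snap_sites(dwellings, fac, network)
  tt <- travel_time_matrix(snapped$dwellings, snapped$facilities, network,
                           params$walking_speed)
  prof <- access_cost_profiles(imputed$visits, snapped$facilities, tt,
                               params, means_everywhere)
  vis_used <- imputed$visits[imputed$visits$facility_id %in% colnames(tt), ,
                             drop = FALSE]
  events <- find_all_bypasses(prof$profiles)
  pqi <- compute_pqi(events, snapped$facilities, vis_used,
                     normalise_per_visit)
  summary_tbl <- class_summary(pqi, prof$profiles, vis_used,
                               snapped$facilities, events)
  vac <- visits_vs_access_cost(prof$profiles, vis_used, snapped$facilities)
  pac <- pqi_vs_access_cost(pqi, prof$profiles, vis_used, snapped$facilities)
  home <- validate_home_origin(vis_used, tt)

  structure(list(
    visits_clean = vis_used,
    cleaning_report = cleaned$report,
    imputation_log = imputed$log,
    excluded_visits = prof$excluded,
    facilities = snapped$facilities,
    dwellings = snapped$dwellings,
    tt_matrix = tt,
    profiles = prof$profiles,
    events = events,
    pqi = pqi,
    class_summary = summary_tbl,
    visits_vs_cost = vac,
    pqi_vs_cost = pac,
    home_origin = home,
    mode_share = mode_share(vis_used),
    params = params
  ), class = "pqi_analysis")
}

#' @export
print.pqi_analysis <- function(x, ...) {
  cat("Perceived-quality analysis\n")
  cat(sprintf("  visits analysed: %d (%d bypass events)\n",
              nrow(x$visits_clean), nrow(x$events)))
  cat("  class summary:\n")
  print(as.data.frame(x$class_summary), digits = 4)
  cat(sprintf("  visits ~ access cost: r = %s\n", format(x$visits_vs_cost$r)))
  cat(sprintf("  PQI ~ access cost:    r = %s\n", format(x$pqi_vs_cost$r)))
  cat(sprintf("  home-origin check:    r = %s (n = %d)\n",
              format(x$home_origin$r), x$home_origin$n))
  invisible(x)
}

#' Write all analysis outputs to a directory
#'
#' Emits tidy delimited tables: cleaning report, imputation log, cost
#' profiles, bypass events, PQI table, class summary, per-facility scatter
#' tables and mode shares.
#'
#' @param analysis A `pqi_analysis` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    p
  }
  files <- c(
    wr(analysis$cleaning_report, "cleaning_report.csv"),
    wr(analysis$imputation_log, "imputation_log.csv"),
    wr(analysis$profiles, "cost_profiles.csv"),
    wr(analysis$events, "bypass_events.csv"),
    wr(analysis$pqi, "pqi.csv"),
    wr(analysis$class_summary, "class_summary.csv"),
    wr(analysis$visits_vs_cost$table, "visits_vs_access_cost.csv"),
    wr(analysis$pqi_vs_cost$table, "pqi_vs_access_cost.csv"),
    wr(analysis$mode_share, "mode_share.csv"),
    wr(analysis$home_origin$table, "home_origin_check.csv"))
  invisible(files)
}
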