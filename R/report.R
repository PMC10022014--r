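#' Pearson correlation with explicit preconditions
#'
#' Thin wrapper over the product-moment correlation that enforces the
#' reporting convention: at least 3 complete pairs and non-zero variance in
#' both series, otherwise a classed error.
#'
#' @param x,y Paired numeric vectors.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop_pqi("pqi_correlation_error", "need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_pqi("pqi_correlation_error",
             "correlation undefined: a series has zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Mean visits per facility by class
#'
#' For each of the four provider classes, the mean number of recorded
#' visits per facility, plus each class's share of all visits and the
#' public/private funding shares.
#'
#' @param visits Cleaned visit table.
#' @param facilities Facility table.
#' @return List with `by_class` (tibble: class, n_facilities, total_visits,
#'   mean_visits) and `funding_share` (named numeric).
#' @export
popularity_by_class <- function(visits, facilities) {
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  vc <- table(factor(visits$facility_id, levels = fac$id))
  per_fac <- tibble::tibble(facility_id = fac$id, class = fac$class,
                            funding = fac$funding,
                            visits = as.numeric(vc))
  by_class <- dplyr::summarise(
    dplyr::group_by(per_fac, .data$class),
    n_facilities = dplyr::n(),
    total_visits = sum(.data$visits),
    mean_visits = mean(.data$visits), .groups = "drop")
  total <- sum(per_fac$visits)
  funding_share <- if (total > 0)
    tapply(per_fac$visits, per_fac$funding, sum) / total
  else c(private = 0, public = 0)
  list(by_class = by_class,
       funding_share = as.numeric(funding_share) |>
         stats::setNames(names(funding_share)))
}

per_facility_cost_table <- function(profiles, visits, facilities) {
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  # mean access cost over all individuals' profiles, per facility
  mac <- tapply(profiles$total, profiles$facility_id, mean)
  vc <- table(factor(visits$facility_id, levels = fac$id))
  tibble::tibble(facility_id = fac$id, class = fac$class,
                 visit_count = as.numeric(vc),
                 mean_access_cost = as.numeric(mac[fac$id]),
                 mean_travel_min = as.numeric(
                   tapply(profiles$travel_min, profiles$facility_id,
                          mean)[fac$id]))
}

#' Facility popularity against access cost
#'
#' Builds the per-facility (visit count, mean access cost) table and its
#' Pearson correlation. A strongly negative correlation would mean access
#' cost alone drives choice; a weak one leaves room for perceived quality.
#'
#' @param profiles Long access-cost profile table.
#' @param visits Cleaned visit table.
#' @param facilities Facility table.
#' @return List with `table` and `r` (NA with a warning when fewer than 3
#'   facilities received visits).
#' @export
visits_vs_access_cost <- function(profiles, visits, facilities) {
  tab <- per_facility_cost_table(profiles, visits, facilities)
  r <- tryCatch(pearson_r(tab$visit_count, tab$mean_access_cost),
                pqi_correlation_error = function(e) {
                  warning(conditionMessage(e)); NA_real_
                })
  list(table = tab, r = r)
}

#' PQI against access cost
#'
#' @param pqi_table Output of [compute_pqi()].
#' @param profiles Long access-cost profile table.
#' @param visits Cleaned visit table.
#' @param facilities Facility table.
#' @return List with `table` (facility_id, class, pqi, mean_access_cost)
#'   and `r`.
#' @export
pqi_vs_access_cost <- function(pqi_table, profiles, visits, facilities) {
  tab <- per_facility_cost_table(profiles, visits, facilities)
  tab <- dplyr::left_join(pqi_table[, c("facility_id", "pqi")], tab,
                          by = "facility_id")
  r <- tryCatch(pearson_r(tab$pqi, tab$mean_access_cost),
                pqi_correlation_error = function(e) {
                  warning(conditionMessage(e)); NA_real_
                })
  list(table = tab, r = r)
}

#' Validate the trips-start-at-home assumption
#'
#' Correlates the reported travel time of each visit with the travel time
#' computed from the individual's home over the network. A strong positive
#' correlation supports costing trips from home.
#'
#' @param visits Cleaned visit table (reported_travel_min used where
#'   non-missing).
#' @param tt_matrix Travel-time matrix.
#' @return List with `r`, `n` (visits used) and the paired table.
#' @export
validate_home_origin <- function(visits, tt_matrix) {
  ok <- !is.na(visits$reported_travel_min) &
    visits$dwelling_id %in% rownames(tt_matrix) &
    visits$facility_id %in% colnames(tt_matrix)
  v <- visits[ok, , drop = FALSE]
  computed <- tt_matrix[cbind(v$dwelling_id, v$facility_id)]
  tab <- tibble::tibble(visit_id = v$visit_id,
                        reported_min = v$reported_travel_min,
                        computed_min = as.numeric(computed))
  if (nrow(tab) < 3) {
    warning("fewer than 3 usable visits; home-origin validation skipped")
    return(list(r = NA_real_, n = nrow(tab), table = tab))
  }
  r <- tryCatch(pearson_r(tab$reported_min, tab$computed_min),
                pqi_correlation_error = function(e) {
                  warning(conditionMessage(e)); NA_real_
                })
  list(r = r, n = nrow(tab), table = tab)
}

#' Transport-mode shares
#'
#' Shares over the non-missing reported modes; audits the on-foot
#' assumption on any dataset.
#'
#' @param visits Visit table.
#' @return Tibble: mode, n, share.
#' @export
mode_share <- function(visits) {
  m <- visits$mode[!is.na(visits$mode)]
  if (length(m) == 0)
    return(tibble::tibble(mode = character(), n = integer(), share = numeric()))
  tab <- sort(table(m), decreasing = TRUE)
  tibble::tibble(mode = names(tab), n = as.integer(tab),
                 share = as.numeric(tab) / length(m))
}

#' Class-level summary of the whole analysis
#'
#' One row per provider class: mean visits per facility, mean travel time
#' and access cost (over all individual profiles), mean and standard
#' deviation of the PQI, and the bypass-behaviour means.
#'
#' @param pqi_table Output of [compute_pqi()].
#' @param profiles Long access-cost profile table.
#' @param visits Cleaned visit table.
#' @param facilities Facility table.
#' @param events Bypass-event table.
#' @return Tibble with one row per class.
#' @export
class_summary <- function(pqi_table, profiles, visits, facilities, events) {
  pop <- popularity_by_class(visits, facilities)$by_class
  cost <- per_facility_cost_table(profiles, visits, facilities)
  bs <- bypass_statistics(events, visits, facilities)
  pq <- dplyr::summarise(dplyr::group_by(pqi_table, .data$class),
                         mean_pqi = mean(.data$pqi),
                         sd_pqi = stats::sd(.data$pqi), .groups = "drop")
  co <- dplyr::summarise(dplyr::group_by(cost, .data$class),
                         mean_travel_min = mean(.data$mean_travel_min),
                         mean_access_cost = mean(.data$mean_access_cost),
                         .groups = "drop")
  out <- dplyr::left_join(pop, co, by = "class")
  out <- dplyr::left_join(out, pq, by = "class")
  out <- dplyr::left_join(out, bs, by = "class")
  out[match(HCP_CLASSES, out$class), , drop = FALSE]
}
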