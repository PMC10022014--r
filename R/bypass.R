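#' Detect the facilities bypassed by one visit
#'
#' A bypass occurs when a patient visits a provider although an alternative
#' provider with a *strictly* lower generalized access cost was available to
#' them; equal-cost alternatives are not bypasses. Each bypass event is
#' weighted by the access-cost difference (visited minus bypassed, always
#' positive): cheap nearby alternatives that were passed over weigh more
#' than alternatives almost as expensive as the visited provider.
#'
#' @param profile Access-cost profile of one visit (tibble with columns
#'   `facility_id`, `total`, and optionally `visit_id`).
#' @param visited_id Id of the facility actually visited.
#' @return Tibble of bypass events: visit_id, visited_facility_id,
#'   bypassed_facility_id, weight.
#' @export
find_bypasses <- function(profile, visited_id) {
  if (!(visited_id %in% profile$facility_id))
    abort_contract(sprintf("visited facility %s absent from profile", visited_id))
  vtot <- profile$total[profile$facility_id == visited_id][1]
  below <- profile$total < vtot & profile$facility_id != visited_id
  tibble::tibble(
    visit_id = if (!is.null(profile$visit_id)) profile$visit_id[below]
               else rep(NA_character_, sum(below)),
    visited_facility_id = rep(visited_id, sum(below)),
    bypassed_facility_id = profile$facility_id[below],
    weight = vtot - profile$total[below])
}

#' Detect bypass events for every visit in a profile table
#'
#' @param profiles Long profile table from [access_cost_profiles()] (must
#'   contain the `visited` flag).
#' @return Tibble of bypass events over all visits.
#' @export
find_all_bypasses <- function(profiles) {
  if (nrow(profiles) == 0)
    return(tibble::tibble(visit_id = character(),
                          visited_facility_id = character(),
                          bypassed_facility_id = character(),
                          weight = numeric()))
  vrow <- profiles[profiles$visited, c("visit_id", "facility_id", "total")]
  names(vrow) <- c("visit_id", "visited_facility_id", "visited_total")
  ev <- dplyr::inner_join(profiles[!profiles$visited,
                                   c("visit_id", "facility_id", "total")],
                          vrow, by = "visit_id")
  ev <- ev[ev$total < ev$visited_total, , drop = FALSE]
  tibble::tibble(visit_id = ev$visit_id,
                 visited_facility_id = ev$visited_facility_id,
                 bypassed_facility_id = ev$facility_id,
                 weight = ev$visited_total - ev$total)
}

#' Aggregate bypass events into the Perceived Quality Index
#'
#' Every facility starts at a PQI of 0. Each bypass event adds its weight to
#' the visited facility's PQI and subtracts it from the bypassed facility's
#' PQI, so the index is exactly zero-sum over facilities. A high PQI marks a
#' provider that patients repeatedly chose despite cheaper alternatives; a
#' low (negative) PQI marks a provider frequently passed over.
#'
#' @param events Bypass-event table from [find_all_bypasses()].
#' @param facilities Facility table (substitutable facilities define the
#'   index's support).
#' @param visits Optional cleaned visit table, used to count visits
#'   received per facility.
#' @param normalise_per_visit If TRUE, each event's weight is divided by the
#'   number of events of its visit (sensitivity-analysis variant; default
#'   FALSE, the raw access-cost difference).
#' @return Tibble: facility_id, class, pqi, visits_received, times_bypassed,
#'   times_visited_in_events.
#' @export
compute_pqi <- function(events, facilities, visits = NULL,
                        normalise_per_visit = FALSE) {
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  known <- unique(c(events$visited_facility_id, events$bypassed_facility_id))
  if (length(setdiff(known, fac$id)) > 0)
    abort_contract(paste("events reference unknown facilities:",
                         paste(setdiff(known, fac$id), collapse = ", ")))
  w <- events$weight
  if (nrow(events) > 0 && any(w <= 0))
    abort_contract("bypass event weights must be strictly positive")
  if (normalise_per_visit && nrow(events) > 0) {
    per_visit <- table(events$visit_id)
    w <- w / as.numeric(per_visit[events$visit_id])
  }
  plus <- tapply(w, events$visited_facility_id, sum)
  minus <- tapply(w, events$bypassed_facility_id, sum)
  pqi <- numeric(nrow(fac)); names(pqi) <- fac$id
  pqi[names(plus)] <- pqi[names(plus)] + as.numeric(plus)
  pqi[names(minus)] <- pqi[names(minus)] - as.numeric(minus)

  times_bypassed <- integer(nrow(fac)); names(times_bypassed) <- fac$id
  tb <- table(events$bypassed_facility_id)
  times_bypassed[names(tb)] <- as.integer(tb)
  tv <- table(events$visited_facility_id)
  times_visited <- integer(nrow(fac)); names(times_visited) <- fac$id
  times_visited[names(tv)] <- as.integer(tv)

  visits_received <- integer(nrow(fac)); names(visits_received) <- fac$id
  if (!is.null(visits) && nrow(visits) > 0) {
    vc <- table(visits$facility_id)
    hit <- intersect(names(vc), fac$id)
    visits_received[hit] <- as.integer(vc[hit])
  }
  tibble::tibble(facility_id = fac$id, class = fac$class,
                 pqi = as.numeric(pqi),
                 visits_received = as.integer(visits_received),
                 times_bypassed = as.integer(times_bypassed),
                 times_visited_in_events = as.integer(times_visited))
}

#' Class-level bypass behaviour summaries
#'
#' Reports, per facility class, the mean number of times a facility of that
#' class is bypassed, and the mean number of other facilities bypassed per
#' visit to that class.
#'
#' @param events Bypass-event table.
#' @param visits Cleaned visit table (defines visits per class).
#' @param facilities Facility table.
#' @return Tibble: class, mean_times_bypassed, mean_bypasses_per_visit.
#' @export
bypass_statistics <- function(events, visits, facilities) {
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  cls_of <- function(ids) fac$class[match(ids, fac$id)]
  out <- tibble::tibble(class = HCP_CLASSES,
                        mean_times_bypassed = 0,
                        mean_bypasses_per_visit = 0)
  if (nrow(events) > 0) {
    tb <- table(events$bypassed_facility_id)
    per_fac <- numeric(nrow(fac)); names(per_fac) <- fac$id
    per_fac[names(tb)] <- as.numeric(tb)
    mtb <- tapply(per_fac, fac$class, mean)
    out$mean_times_bypassed <- ifelse(out$class %in% names(mtb),
                                      as.numeric(mtb[out$class]), 0)
  }
  vis_sub <- visits[visits$facility_id %in% fac$id, , drop = FALSE]
  if (nrow(vis_sub) > 0) {
    ev_per_visit <- table(events$visit_id)
    n_ev <- as.numeric(ev_per_visit[vis_sub$visit_id])
    n_ev[is.na(n_ev)] <- 0
    mbp <- tapply(n_ev, cls_of(vis_sub$facility_id), mean)
    out$mean_bypasses_per_visit <- ifelse(out$class %in% names(mbp),
                                          as.numeric(mbp[out$class]), 0)
  }
  out
}
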