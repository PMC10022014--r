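#' Cleaning rules for visit records
#'
#' Survey tables typically contain enumerator placeholder values (for
#' example a travel time of 999 minutes) and the occasional nonsensical
#' entry. Cleaning drops such records; it never drops records for being
#' merely missing (missingness is handled by [impute_missing()]), and a
#' recorded zero is a valid observation, never treated as missing.
#'
#' @param placeholder_values Values in time fields that mark a placeholder
#'   (default 999).
#' @param max_travel_min Upper plausibility bound on reported travel time,
#'   minutes (default 720, i.e. 12 h on foot).
#' @param max_wait_min Upper plausibility bound on waiting time, minutes.
#' @return A `pqi_cleaning_rules` list.
#' @export
cleaning_rules <- function(placeholder_values = c(999),
                           max_travel_min = 720,
                           max_wait_min = 720) {
  structure(list(placeholder_values = placeholder_values,
                 max_travel_min = max_travel_min,
                 max_wait_min = max_wait_min),
            class = "pqi_cleaning_rules")
}

#' Drop placeholder and implausible visit records
#'
#' Each dropped record is attributed to exactly one rule, checked in order:
#' placeholder time value, negative value in any numeric field, travel time
#' above the plausibility cap, waiting time above the cap. Cleaning is total
#' (never errors) and idempotent.
#'
#' @param visits Visit-record tibble.
#' @param rules A [cleaning_rules()] object.
#' @return List with `visits` (the retained records) and `report`, a tibble
#'   of per-rule drop counts plus the retained count.
#' @export
clean_visits <- function(visits, rules = cleaning_rules()) {
  n <- nrow(visits)
  time_cols <- c("reported_travel_min", "wait_min")
  num_cols <- c("reported_travel_min", "transport_cost",
                "consultation_cost", "wait_min")

  is_placeholder <- rep(FALSE, n)
  for (cc in time_cols) {
    v <- visits[[cc]]
    is_placeholder <- is_placeholder | (!is.na(v) & v %in% rules$placeholder_values)
  }
  is_negative <- rep(FALSE, n)
  for (cc in num_cols) {
    v <- visits[[cc]]
    is_negative <- is_negative | (!is.na(v) & v < 0)
  }
  over_travel <- !is.na(visits$reported_travel_min) &
    visits$reported_travel_min > rules$max_travel_min
  over_wait <- !is.na(visits$wait_min) & visits$wait_min > rules$max_wait_min

  drop_rule <- rep(NA_character_, n)
  drop_rule[over_wait] <- "wait_above_cap"
  drop_rule[over_travel] <- "travel_above_cap"
  drop_rule[is_negative] <- "negative_value"
  drop_rule[is_placeholder] <- "placeholder_value"  # highest precedence

  keep <- is.na(drop_rule)
  labels <- c("placeholder_value", "negative_value", "travel_above_cap",
              "wait_above_cap")
  report <- tibble::tibble(
    rule = c(labels, "retained"),
    count = unname(c(vapply(labels, function(l)
      sum(drop_rule == l, na.rm = TRUE), integer(1)), sum(keep)))
  )
  list(visits = visits[keep, , drop = FALSE], report = report)
}

#' Fill missing consultation costs and waiting times with facility means
#'
#' Missing `consultation_cost` and `wait_min` are replaced by the mean of
#' the non-missing observed values for the same facility; a facility with no
#' observations of a field falls back to the mean over its four-way class,
#' and an empty class to the global mean. Non-missing values are never
#' touched. Every imputation is logged.
#'
#' @param visits Cleaned visit-record tibble.
#' @param facilities Facility table (for the class fallback).
#' @return List with `visits` (imputed) and `log`, a tibble
#'   (visit_id, field, level, value) with one row per imputed field.
#' @export
impute_missing <- function(visits, facilities) {
  out <- visits
  logs <- list()
  cls <- facilities$class[match(visits$facility_id, facilities$id)]
  for (field in c("consultation_cost", "wait_min")) {
    v <- out[[field]]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss))
      stop_pqi("pqi_imputation_error",
               sprintf("field %s is missing for every record: nothing to average",
                       field))
    fac_mean <- tapply(v[!miss], visits$facility_id[!miss], mean)
    cls_mean <- tapply(v[!miss], cls[!miss], mean)
    glob_mean <- mean(v[!miss])
    fill <- fac_mean[visits$facility_id]
    level <- rep("facility", nrow(visits))
    no_fac <- is.na(fill)
    fill[no_fac] <- cls_mean[cls[no_fac]]
    level[no_fac] <- "class"
    no_cls <- is.na(fill)
    fill[no_cls] <- glob_mean
    level[no_cls] <- "global"
    out[[field]][miss] <- as.numeric(fill[miss])
    logs[[field]] <- tibble::tibble(
      visit_id = visits$visit_id[miss], field = field,
      level = level[miss], value = as.numeric(fill[miss]))
  }
  list(visits = out,
       log = if (length(logs)) dplyr::bind_rows(logs)
             else tibble::tibble(visit_id = character(), field = character(),
                                 level = character(), value = numeric()))
}

facility_class_vec <- function(size_class, funding) {
  ok_size <- size_class %in% c("clinic", "hospital")
  ok_fund <- funding %in% c("public", "private")
  if (any(!ok_size))
    stop_pqi("pqi_class_error",
             paste("unknown facility size:",
                   paste(unique(size_class[!ok_size]), collapse = ", ")))
  if (any(!ok_fund))
    stop_pqi("pqi_class_error",
             paste("unknown funding source:",
                   paste(unique(funding[!ok_fund]), collapse = ", ")))
  paste(funding, size_class)
}

#' Four-way facility classification
#'
#' Maps facility size (clinic/hospital) and funding (public/private) to one
#' of the four analysis classes: "private clinic", "public clinic",
#' "private hospital", "public hospital". Facilities that are not reasonable
#' substitutes for general outpatient care (dentists, pharmacies, maternity
#' clinics, ...) are excluded upstream via their `substitutable` flag and
#' are never classified.
#'
#' @param size_class "clinic" or "hospital" (vectorised).
#' @param funding "public" or "private".
#' @return Character vector of class labels.
#' @export
facility_class <- function(size_class, funding) {
  facility_class_vec(size_class, funding)
}
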