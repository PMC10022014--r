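#' Economic parameters of the generalized access cost
#'
#' The generalized access cost collapses everything a patient gives up to
#' use a provider into one currency figure: out-of-pocket transport cost,
#' the consultation (treatment) cost, and the opportunity cost of time spent
#' travelling and waiting, valued at a constant per-minute rate. The form is
#' the standard additive linear generalized cost of the accessibility
#' literature.
#'
#' @param value_of_time Currency per minute of travel or waiting (> 0 unless
#'   you deliberately want a money-only cost). Default 1; for real data this
#'   should be set to a local wage proxy.
#' @param walking_speed Walking speed in metres per minute (> 0).
#' @param wait_multiplier Relative per-minute weight of waiting time versus
#'   travel time (default 1: one common rate).
#' @return A `pqi_cost_params` list.
#' @export
cost_params <- function(value_of_time = 1, walking_speed = 80,
                        wait_multiplier = 1) {
  if (!is_scalar_num(value_of_time) || value_of_time < 0)
    abort_config("value_of_time must be a finite number >= 0")
  if (!is_scalar_num(walking_speed) || walking_speed <= 0)
    abort_config("walking_speed must be positive")
  if (!is_scalar_num(wait_multiplier) || wait_multiplier < 0)
    abort_config("wait_multiplier must be >= 0")
  structure(list(value_of_time = value_of_time,
                 walking_speed = walking_speed,
                 wait_multiplier = wait_multiplier),
            class = "pqi_cost_params")
}

#' Assemble one generalized access cost
#'
#' `total = transport + treatment + value_of_time * (travel_min +
#' wait_multiplier * wait_min)`. All components must be non-negative.
#'
#' @param travel_min Travel time, minutes.
#' @param wait_min Waiting time, minutes.
#' @param treatment Consultation/treatment cost, currency.
#' @param transport Out-of-pocket transport cost, currency.
#' @param params A [cost_params()] object.
#' @return A one-row tibble: total, travel_money, treatment, time_value,
#'   travel_min, wait_min.
#' @export
access_cost <- function(travel_min, wait_min, treatment, transport = 0,
                        params = cost_params()) {
  comp <- c(travel_min = travel_min, wait_min = wait_min,
            treatment = treatment, transport = transport)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop_pqi("pqi_cost_error",
             paste("access cost components must be finite and >= 0; got",
                   paste(sprintf("%s=%s", names(comp), comp), collapse = ", ")))
  time_value <- params$value_of_time *
    (travel_min + params$wait_multiplier * wait_min)
  tibble::tibble(total = transport + treatment + time_value,
                 travel_money = transport, treatment = treatment,
                 time_value = time_value,
                 travel_min = travel_min, wait_min = wait_min)
}

#' Access-cost profile of one visit over all substitutable facilities
#'
#' For the facility the patient actually visited, the cost uses the
#' record's own (post-imputation) consultation cost, waiting time and
#' transport cost — the costs the patient really faced. For every
#' alternative facility it uses the facility's mean price and mean waiting
#' time with zero transport cost, under the on-foot assumption. Setting
#' `means_everywhere = TRUE` costs the visited facility from its means too,
#' for sensitivity analysis.
#'
#' @param visit One visit record (one-row tibble), already cleaned/imputed.
#' @param facilities Facility table with `mean_price`, `mean_wait_min`,
#'   `substitutable`.
#' @param tt_matrix Travel-time matrix from [travel_time_matrix()].
#' @param params A [cost_params()] object.
#' @param means_everywhere Cost the visited facility from facility means as
#'   well (default FALSE).
#' @return Tibble with one row per substitutable facility: visit_id,
#'   facility_id, visited, travel_min, wait_min, treatment, travel_money,
#'   time_value, total.
#' @export
access_cost_profile <- function(visit, facilities, tt_matrix,
                                params = cost_params(),
                                means_everywhere = FALSE) {
  fac <- facilities[facilities$substitutable, , drop = FALSE]
  if (!(visit$facility_id %in% fac$id))
    stop_pqi("pqi_excluded_visit",
             sprintf("visit %s: visited facility %s is not a substitutable provider",
                     visit$visit_id, visit$facility_id))
  fac <- fac[match(colnames(tt_matrix), fac$id), , drop = FALSE]
  tt <- tt_matrix[visit$dwelling_id, ]

  wait <- fac$mean_wait_min
  treat <- fac$mean_price
  transp <- rep(0, nrow(fac))
  if (anyNA(wait) || anyNA(treat)) {
    bad <- fac$id[is.na(wait) | is.na(treat)]
    stop_pqi("pqi_cost_error",
             paste("facility means unavailable (impute first) for:",
                   paste(bad, collapse = ", ")))
  }
  vis <- fac$id == visit$facility_id
  if (!means_everywhere) {
    if (is.na(visit$consultation_cost) || is.na(visit$wait_min))
      stop_pqi("pqi_cost_error",
               sprintf("visit %s: consultation_cost/wait_min missing after imputation",
                       visit$visit_id))
    wait[vis] <- visit$wait_min
    treat[vis] <- visit$consultation_cost
    transp[vis] <- if (is.na(visit$transport_cost)) 0 else visit$transport_cost
  }
  time_value <- params$value_of_time * (tt + params$wait_multiplier * wait)
  tibble::tibble(
    visit_id = visit$visit_id,
    facility_id = fac$id,
    visited = vis,
    travel_min = as.numeric(tt),
    wait_min = wait,
    treatment = treat,
    travel_money = transp,
    time_value = as.numeric(time_value),
    total = as.numeric(transp + treat + time_value)
  )
}

#' Access-cost profiles for a whole visit table
#'
#' Vectorised equivalent of calling [access_cost_profile()] per visit.
#' Visits to non-substitutable facilities are excluded with a logged reason.
#'
#' @param visits Cleaned, imputed visit table.
#' @param facilities Facility table.
#' @param tt_matrix Travel-time matrix.
#' @param params A [cost_params()] object.
#' @param means_everywhere See [access_cost_profile()].
#' @return List with `profiles` (long tibble over visit x facility) and
#'   `excluded` (tibble visit_id, reason).
#' @export
access_cost_profiles <- function(visits, facilities, tt_matrix,
                                 params = cost_params(),
                                 means_everywhere = FALSE) {
  fac_ids <- colnames(tt_matrix)
  fac <- facilities[match(fac_ids, facilities$id), , drop = FALSE]
  ok <- visits$facility_id %in% fac_ids
  excluded <- tibble::tibble(
    visit_id = visits$visit_id[!ok],
    reason = "visited facility not substitutable")
  v <- visits[ok, , drop = FALSE]
  n_v <- nrow(v); n_f <- length(fac_ids)
  if (n_v == 0) {
    return(list(profiles = tibble::tibble(
      visit_id = character(), facility_id = character(), visited = logical(),
      travel_min = numeric(), wait_min = numeric(), treatment = numeric(),
      travel_money = numeric(), time_value = numeric(), total = numeric()),
      excluded = excluded))
  }
  if (anyNA(fac$mean_price) || anyNA(fac$mean_wait_min))
    stop_pqi("pqi_cost_error", "facility means unavailable; run impute/facility_means first")
  if (!means_everywhere &&
      (anyNA(v$consultation_cost) || anyNA(v$wait_min)))
    stop_pqi("pqi_cost_error", "visits carry missing fields; impute first")

  tt <- tt_matrix[v$dwelling_id, , drop = FALSE]
  wait <- matrix(fac$mean_wait_min, n_v, n_f, byrow = TRUE)
  treat <- matrix(fac$mean_price, n_v, n_f, byrow = TRUE)
  transp <- matrix(0, n_v, n_f)
  vis_idx <- cbind(seq_len(n_v), match(v$facility_id, fac_ids))
  vis <- matrix(FALSE, n_v, n_f)
  vis[vis_idx] <- TRUE
  if (!means_everywhere) {
    wait[vis_idx] <- v$wait_min
    treat[vis_idx] <- v$consultation_cost
    transp[vis_idx] <- ifelse(is.na(v$transport_cost), 0, v$transport_cost)
  }
  time_value <- params$value_of_time * (tt + params$wait_multiplier * wait)
  total <- transp + treat + time_value
  profiles <- tibble::tibble(
    visit_id = rep(v$visit_id, times = n_f),
    facility_id = rep(fac_ids, each = n_v),
    visited = as.vector(vis),
    travel_min = as.vector(tt),
    wait_min = as.vector(wait),
    treatment = as.vector(treat),
    travel_money = as.vector(transp),
    time_value = as.vector(time_value),
    total = as.vector(total))
  list(profiles = profiles, excluded = excluded)
}

#' Refresh facility mean price and waiting time from observed visits
#'
#' Sets each facility's `mean_price` and `mean_wait_min` to the mean of the
#' non-missing observed values of visits to that facility, falling back to
#' any value already present in the facility table, then to the class mean,
#' then to the global mean. These statistics cost the *alternative*
#' facilities in a profile and fill missing record fields.
#'
#' @param facilities Facility table.
#' @param visits Cleaned visit table.
#' @return The facility table with updated means.
#' @export
facility_means <- function(facilities, visits) {
  upd <- function(provided, field) {
    v <- visits[[field]]
    obs <- tapply(v[!is.na(v)], visits$facility_id[!is.na(v)], mean)
    est <- as.numeric(obs[facilities$id])
    est[is.na(est)] <- provided[is.na(est)]
    cls_mean <- tapply(est, facilities$class, mean, na.rm = TRUE)
    miss <- is.na(est)
    est[miss] <- as.numeric(cls_mean[facilities$class[miss]])
    est[is.na(est)] <- mean(est, na.rm = TRUE)
    est
  }
  facilities$mean_price <- upd(facilities$mean_price, "consultation_cost")
  facilities$mean_wait_min <- upd(facilities$mean_wait_min, "wait_min")
  facilities
}
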