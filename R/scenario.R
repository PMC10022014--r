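#' Define a synthetic settlement scenario
#'
#' A scenario bundles every parameter of the synthetic-data generator: the
#' spatial extent and density of the road-and-footpath network, the number of
#' dwellings and of healthcare providers in each of the four classes
#' (clinic/hospital crossed with private/public funding), the pedestrian and
#' economic parameters used to turn distances into generalized access costs,
#' the latent ("perceived") quality planted per facility class, and the
#' messiness of the simulated survey (missing fields, placeholder travel
#' times).
#'
#' Defaults describe a compact informal settlement: a 2 km square with a
#' dense footpath network, clinics scattered among the dwellings and the
#' sparser hospitals pushed toward the periphery, so that mean travel time
#' to a hospital exceeds that to a clinic. Latent quality means mirror the
#' class ordering the index is known to surface: highest for public
#' hospitals, hospitals above clinics, and private clinics slightly above
#' public clinics.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param area_side_m Side of the square study area, metres.
#' @param n_nodes Number of road-network nodes (>= 2).
#' @param n_dwellings Number of dwellings placed uniformly over the area.
#' @param n_facilities_by_class Named integer vector with entries
#'   `private clinic`, `public clinic`, `private hospital`, `public hospital`.
#' @param walking_speed_m_per_min Pedestrian speed, metres per minute.
#' @param value_of_time_per_min Currency value of one minute of travel or
#'   waiting time (the opportunity-cost rate of the generalized access cost).
#' @param beta_cost Choice sensitivity (1/currency, >= 0) of the
#'   multinomial-logit visit rule; larger values make simulated patients more
#'   strictly cost-minimising.
#' @param quality_by_class_mean Named numeric vector of latent quality means
#'   per class, in the same currency unit as the access cost.
#' @param quality_sd Standard deviation of per-facility latent quality around
#'   its class mean.
#' @param price_by_class_mean,wait_by_class_mean Named numeric vectors of
#'   mean consultation price (currency) and mean waiting time (minutes) per
#'   class.
#' @param travel_noise_sdlog sdlog of the lognormal multiplicative noise
#'   applied to true travel times to produce *reported* travel times.
#' @param cost_noise_sdlog sdlog of the lognormal spread of reported
#'   consultation costs and waiting times around the facility means.
#' @param missing_rate Fraction of consultation-cost and waiting-time fields
#'   blanked in the simulated survey, in [0, 1).
#' @param placeholder_rate Fraction of reported travel times replaced by the
#'   999-minute placeholder a careless enumerator might enter, in [0, 1).
#' @param mode_shares Named probabilities for the reported transport mode.
#'
#' @return An object of class `pqi_scenario` (a validated list).
#' @export
#' @examples
#' sc <- slum_scenario(seed = 1, n_nodes = 50, n_dwellings = 20,
#'                     n_facilities_by_class = c("private clinic" = 2,
#'                                               "public clinic" = 2,
#'                                               "private hospital" = 1,
#'                                               "public hospital" = 1))
#' sc$n_dwellings
slum_scenario <- function(seed = 1L,
                          area_side_m = 2000,
                          n_nodes = 400L,
                          n_dwellings = 500L,
                          n_facilities_by_class = c(
                            "private clinic"   = 20L,
                            "public clinic"    = 16L,
                            "private hospital" = 8L,
                            "public hospital"  = 6L),
                          walking_speed_m_per_min = 80,
                          value_of_time_per_min = 1,
                          beta_cost = 0.01,
                          quality_by_class_mean = c(
                            "private clinic"   = 50,
                            "public clinic"    = 0,
                            "private hospital" = 250,
                            "public hospital"  = 400),
                          quality_sd = 50,
                          price_by_class_mean = c(
                            "private clinic"   = 80,
                            "public clinic"    = 30,
                            "private hospital" = 300,
                            "public hospital"  = 120),
                          wait_by_class_mean = c(
                            "private clinic"   = 15,
                            "public clinic"    = 40,
                            "private hospital" = 30,
                            "public hospital"  = 90),
                          travel_noise_sdlog = 0.2,
                          cost_noise_sdlog = 0.15,
                          missing_rate = 0.05,
                          placeholder_rate = 0.02,
                          mode_shares = c(foot = 0.772,
                                          "public transport" = 0.18,
                                          other = 0.048)) {
  sc <- list(
    seed = as.integer(seed),
    area_side_m = area_side_m,
    n_nodes = as.integer(n_nodes),
    n_dwellings = as.integer(n_dwellings),
    n_facilities_by_class = n_facilities_by_class,
    walking_speed_m_per_min = walking_speed_m_per_min,
    value_of_time_per_min = value_of_time_per_min,
    beta_cost = beta_cost,
    quality_by_class_mean = quality_by_class_mean,
    quality_sd = quality_sd,
    price_by_class_mean = price_by_class_mean,
    wait_by_class_mean = wait_by_class_mean,
    travel_noise_sdlog = travel_noise_sdlog,
    cost_noise_sdlog = cost_noise_sdlog,
    missing_rate = missing_rate,
    placeholder_rate = placeholder_rate,
    mode_shares = mode_shares
  )
  class(sc) <- "pqi_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (!is_count(sc$n_nodes) || sc$n_nodes < 2)
    abort_config("scenario: n_nodes must be an integer >= 2")
  if (!is_count(sc$n_dwellings))
    abort_config("scenario: n_dwellings must be a positive integer")
  nf <- sc$n_facilities_by_class
  if (!all(HCP_CLASSES %in% names(nf)))
    abort_config(paste0("scenario: n_facilities_by_class must name all of: ",
                        paste(HCP_CLASSES, collapse = ", ")))
  if (any(nf < 0) || any(nf != round(nf)))
    abort_config("scenario: facility counts must be non-negative integers")
  if (sum(nf) < 1)
    abort_config("scenario: at least one facility is required")
  for (p in c("quality_by_class_mean", "price_by_class_mean",
              "wait_by_class_mean")) {
    if (!all(HCP_CLASSES %in% names(sc[[p]])))
      abort_config(sprintf("scenario: %s must name all four classes", p))
  }
  if (!is_scalar_num(sc$beta_cost) || sc$beta_cost < 0)
    abort_config("scenario: beta_cost must be a finite number >= 0")
  if (sc$walking_speed_m_per_min <= 0)
    abort_config("scenario: walking speed must be positive")
  if (sc$value_of_time_per_min < 0)
    abort_config("scenario: value_of_time_per_min must be >= 0")
  if (sc$missing_rate < 0 || sc$missing_rate >= 1 ||
      sc$placeholder_rate < 0 || sc$placeholder_rate >= 1 ||
      sc$missing_rate + sc$placeholder_rate >= 1)
    abort_config("scenario: missing_rate and placeholder_rate must lie in [0,1) and sum below 1")
  if (sc$quality_sd < 0)
    abort_config("scenario: quality_sd must be >= 0")
  invisible(sc)
}

#' @export
print.pqi_scenario <- function(x, ...) {
  cat("Synthetic settlement scenario (seed ", x$seed, ")\n", sep = "")
  cat("  area: ", x$area_side_m, " m square, ", x$n_nodes, " network nodes\n",
      sep = "")
  cat("  sites: ", x$n_dwellings, " dwellings; facilities: ",
      paste(sprintf("%s=%d", names(x$n_facilities_by_class),
                    x$n_facilities_by_class), collapse = ", "), "\n", sep = "")
  cat("  choice: beta_cost = ", x$beta_cost, ", quality_sd = ", x$quality_sd,
      "\n", sep = "")
  invisible(x)
}
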