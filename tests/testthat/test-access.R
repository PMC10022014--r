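test_that("access cost assembles the stated linear form", {
  p <- cost_params(value_of_time = 2)
  ac <- access_cost(travel_min = 20, wait_min = 30, treatment = 100,
                    transport = 0, params = p)
  expect_equal(ac$total, 100 + 2 * (20 + 30))
  expect_equal(ac$total, ac$travel_money + ac$treatment + ac$time_value)
  # value_of_time -> 0 reduces to pure monetary cost
  ac0 <- access_cost(20, 30, 100, 7, cost_params(value_of_time = 0))
  expect_equal(ac0$total, 107)
  expect_error(access_cost(-1, 0, 0), class = "pqi_cost_error")
})

test_that("doubling value_of_time exactly doubles time_value and nothing else", {
  a1 <- access_cost(15, 25, 80, 5, cost_params(value_of_time = 1.5))
  a2 <- access_cost(15, 25, 80, 5, cost_params(value_of_time = 3))
  expect_equal(a2$time_value, 2 * a1$time_value)
  expect_equal(a2$treatment, a1$treatment)
  expect_equal(a2$travel_money, a1$travel_money)
  expect_equal(a2$total - a1$total, a1$time_value)
})

test_that("total is non-decreasing in each component", {
  base <- access_cost(10, 10, 10, 10)$total
  expect_gte(access_cost(11, 10, 10, 10)$total, base)
  expect_gte(access_cost(10, 12, 10, 10)$total, base)
  expect_gte(access_cost(10, 10, 15, 10)$total, base)
  expect_gte(access_cost(10, 10, 10, 20)$total, base)
})

# Hand-computed 5-facility fixture: 1 dwelling at a node, facilities at known
# network distances; spreadsheet-style arithmetic frozen below.
manual_fixture <- function() {
  g <- toy_network(
    c("h", "p1", "p2", "p3", "p4", "p5"),
    x = c(0, 100, 200, 300, 400, 500), y = rep(0, 6),
    edges = rbind(c("h", "p1"), c("p1", "p2"), c("p2", "p3"),
                  c("p3", "p4"), c("p4", "p5")),
    lengths = c(100, 100, 100, 100, 100))
  dwell <- tibble::tibble(id = "d1", x = 0, y = 0, snapped_node = "h")
  fac <- tibble::tibble(
    id = paste0("f", 1:5),
    x = c(100, 200, 300, 400, 500), y = 0,
    size_class = c("clinic", "clinic", "clinic", "hospital", "hospital"),
    funding = c("private", "public", "private", "public", "private"),
    substitutable = TRUE,
    mean_price = c(50, 20, 60, 100, 250),
    mean_wait_min = c(10, 40, 15, 60, 20),
    snapped_node = paste0("p", 1:5))
  fac$class <- facility_class(fac$size_class, fac$funding)
  list(network = g, dwellings = dwell, facilities = fac)
}

test_that("profile matches a manual spreadsheet computation", {
  fx <- manual_fixture()
  p <- cost_params(value_of_time = 2, walking_speed = 100)
  tt <- travel_time_matrix(fx$dwellings, fx$facilities, fx$network, 100)
  # distances 100..500 m at 100 m/min -> 1..5 min
  expect_equal(as.numeric(tt["d1", ]), 1:5)
  visit <- tibble::tibble(visit_id = "v1", dwelling_id = "d1",
                          facility_id = "f3", reported_travel_min = 3,
                          transport_cost = 12, consultation_cost = 55,
                          wait_min = 20, mode = "foot")
  prof <- access_cost_profile(visit, fx$facilities, tt, p)
  # visited f3: 12 transport + 55 treatment + 2*(3 travel + 20 wait) = 113
  expect_equal(prof$total[prof$facility_id == "f3"], 113)
  # alternatives from means, zero transport:
  # f1: 50 + 2*(1+10) = 72 ; f2: 20 + 2*(2+40) = 104
  # f4: 100 + 2*(4+60) = 228 ; f5: 250 + 2*(5+20) = 300
  expect_equal(prof$total[match(c("f1", "f2", "f4", "f5"), prof$facility_id)],
               c(72, 104, 228, 300))
  expect_equal(prof$total, prof$travel_money + prof$treatment + prof$time_value)
})

test_that("alternative costs are independent of the individual's reported values", {
  fx <- manual_fixture()
  p <- cost_params(value_of_time = 2, walking_speed = 100)
  tt <- travel_time_matrix(fx$dwellings, fx$facilities, fx$network, 100)
  v1 <- tibble::tibble(visit_id = "v1", dwelling_id = "d1", facility_id = "f3",
                       reported_travel_min = 3, transport_cost = 12,
                       consultation_cost = 55, wait_min = 20, mode = "foot")
  v2 <- v1; v2$consultation_cost <- 500; v2$wait_min <- 120; v2$transport_cost <- 90
  p1 <- access_cost_profile(v1, fx$facilities, tt, p)
  p2 <- access_cost_profile(v2, fx$facilities, tt, p)
  alt <- p1$facility_id != "f3"
  expect_equal(p1$total[alt], p2$total[alt])
  expect_false(p1$total[!alt] == p2$total[!alt])
})

test_that("two identical facilities at equal distance get equal alternative costs", {
  g <- toy_network(c("h", "l", "r"), x = c(0, -50, 50), y = c(0, 0, 0),
                   edges = rbind(c("h", "l"), c("h", "r")), lengths = c(50, 50))
  dwell <- tibble::tibble(id = "d1", x = 0, y = 0, snapped_node = "h")
  fac <- tibble::tibble(id = c("fL", "fR", "fV"), x = c(-50, 50, 0), y = 0,
                        size_class = "clinic", funding = "public",
                        substitutable = TRUE, mean_price = 30,
                        mean_wait_min = 10,
                        snapped_node = c("l", "r", "h"))
  fac$class <- facility_class(fac$size_class, fac$funding)
  tt <- travel_time_matrix(dwell, fac, g, 50)
  visit <- tibble::tibble(visit_id = "v1", dwelling_id = "d1",
                          facility_id = "fV", reported_travel_min = 0,
                          transport_cost = 0, consultation_cost = 30,
                          wait_min = 10, mode = "foot")
  prof <- access_cost_profile(visit, fac, tt)
  expect_equal(prof$total[prof$facility_id == "fL"],
               prof$total[prof$facility_id == "fR"])
})

test_that("vectorised profiles equal the per-visit computation", {
  sim <- simulate_scenario(tiny_scenario(seed = 23, missing_rate = 0,
                                         placeholder_rate = 0), 40)
  snapped <- snap_sites(sim$dwellings, sim$facilities, sim$network)
  tt <- travel_time_matrix(snapped$dwellings, snapped$facilities, sim$network, 80)
  p <- cost_params()
  all_prof <- access_cost_profiles(sim$visits, snapped$facilities, tt, p)$profiles
  for (i in c(1, 17, 40)) {
    one <- access_cost_profile(sim$visits[i, ], snapped$facilities, tt, p)
    got <- all_prof[all_prof$visit_id == sim$visits$visit_id[i], ]
    got <- got[match(one$facility_id, got$facility_id), ]
    expect_equal(got$total, one$total)
    expect_equal(got$visited, one$visited)
  }
})

test_that("visits to non-substitutable facilities are excluded with a reason", {
  fx <- manual_fixture()
  fac <- fx$facilities
  fac$substitutable[fac$id == "f3"] <- FALSE
  tt <- travel_time_matrix(fx$dwellings, fac, fx$network, 100)
  visit <- tibble::tibble(visit_id = "v1", dwelling_id = "d1", facility_id = "f3",
                          reported_travel_min = 3, transport_cost = 0,
                          consultation_cost = 55, wait_min = 20, mode = "foot")
  expect_error(access_cost_profile(visit, fac, tt),
               class = "pqi_excluded_visit")
  res <- access_cost_profiles(visit, fac, tt)
  expect_equal(nrow(res$profiles), 0)
  expect_equal(res$excluded$visit_id, "v1")
})
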