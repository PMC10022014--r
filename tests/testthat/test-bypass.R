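test_that("bypass detection uses the strict-inequality rule", {
  prof <- tibble::tibble(visit_id = "v1",
                         facility_id = c("fv", "fa", "fb", "fc"),
                         total = c(200, 150, 200, 250))
  ev <- find_bypasses(prof, "fv")
  expect_equal(nrow(ev), 1)                  # the equal-cost one is no bypass
  expect_equal(ev$bypassed_facility_id, "fa")
  expect_equal(ev$weight, 50)

  # visited is the unique cost-minimiser: no events
  prof2 <- tibble::tibble(visit_id = "v2",
                          facility_id = c("fv", "fa"), total = c(100, 120))
  expect_equal(nrow(find_bypasses(prof2, "fv")), 0)

  expect_error(find_bypasses(prof, "zz"), class = "pqi_contract_error")
})

test_that("bypass detection matches exhaustive enumeration on random profiles", {
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(2:10, 1)
    ids <- paste0("f", seq_len(k))
    totals <- round(stats::runif(k, 10, 500), sample(0:2, 1))
    visited <- sample(ids, 1)
    prof <- tibble::tibble(visit_id = "v", facility_id = ids, total = totals)
    got <- find_bypasses(prof, visited)
    want <- brute_bypasses(totals, ids, visited)
    expect_setequal(got$bypassed_facility_id, want$bypassed)
    got <- got[match(want$bypassed, got$bypassed_facility_id), ]
    expect_equal(got$weight, want$weight)
    expect_true(all(got$weight > 0))
  }
})

test_that("find_all_bypasses agrees with per-visit detection", {
  sim <- simulate_scenario(tiny_scenario(seed = 33, missing_rate = 0,
                                         placeholder_rate = 0), 60)
  snapped <- snap_sites(sim$dwellings, sim$facilities, sim$network)
  tt <- travel_time_matrix(snapped$dwellings, snapped$facilities, sim$network, 80)
  prof <- access_cost_profiles(sim$visits, snapped$facilities, tt)$profiles
  all_ev <- find_all_bypasses(prof)
  for (vid in sample(unique(prof$visit_id), 10)) {
    sub <- prof[prof$visit_id == vid, ]
    one <- find_bypasses(sub, sub$facility_id[sub$visited])
    mine <- all_ev[all_ev$visit_id == vid, ]
    expect_setequal(mine$bypassed_facility_id, one$bypassed_facility_id)
  }
})

test_that("PQI aggregation is zero-sum and matches an independent tally", {
  set.seed(37)
  fac <- tibble::tibble(id = paste0("f", 1:8),
                        class = rep(HCP <- c("private clinic", "public clinic",
                                             "private hospital", "public hospital"), 2),
                        substitutable = TRUE)
  events <- tibble::tibble(
    visit_id = paste0("v", sample(1:40, 100, replace = TRUE)),
    visited_facility_id = sample(fac$id, 100, replace = TRUE),
    bypassed_facility_id = sample(fac$id, 100, replace = TRUE),
    weight = stats::runif(100, 1, 50))
  events <- events[events$visited_facility_id != events$bypassed_facility_id, ]
  pqi <- compute_pqi(events, fac)
  # independent tally by explicit loop
  ref <- sapply(fac$id, function(f)
    sum(events$weight[events$visited_facility_id == f]) -
      sum(events$weight[events$bypassed_facility_id == f]))
  expect_equal(pqi$pqi, unname(ref))
  expect_lt(abs(sum(pqi$pqi)) / sum(abs(pqi$pqi)), 1e-9)
  tb <- sapply(fac$id, function(f) sum(events$bypassed_facility_id == f))
  expect_equal(pqi$times_bypassed, unname(as.integer(tb)))
})

test_that("no events means every facility keeps its initial PQI of zero", {
  fac <- tibble::tibble(id = c("f1", "f2"), class = c("public clinic", "public hospital"),
                        substitutable = TRUE)
  empty <- tibble::tibble(visit_id = character(), visited_facility_id = character(),
                          bypassed_facility_id = character(), weight = numeric())
  pqi <- compute_pqi(empty, fac)
  expect_identical(pqi$pqi, c(0, 0))
})

test_that("a single event conserves: visited +w, bypassed -w", {
  fac <- tibble::tibble(id = c("f1", "f2"), class = c("public clinic", "public hospital"),
                        substitutable = TRUE)
  ev <- tibble::tibble(visit_id = "v1", visited_facility_id = "f2",
                       bypassed_facility_id = "f1", weight = 50)
  pqi <- compute_pqi(ev, fac)
  expect_equal(pqi$pqi[pqi$facility_id == "f2"], 50)
  expect_equal(pqi$pqi[pqi$facility_id == "f1"], -50)
  expect_equal(sum(pqi$pqi), 0)
  expect_error(compute_pqi(tibble::tibble(visit_id = "v", visited_facility_id = "zz",
                                          bypassed_facility_id = "f1", weight = 1), fac),
               class = "pqi_contract_error")
})

test_that("cheaper bypassed alternatives are penalised more", {
  prof <- tibble::tibble(visit_id = "v1",
                         facility_id = c("fv", "cheap", "nearly"),
                         total = c(300, 50, 290))
  ev <- find_bypasses(prof, "fv")
  w <- stats::setNames(ev$weight, ev$bypassed_facility_id)
  expect_gt(w["cheap"], w["nearly"])
})

test_that("per-class bypass statistics match a hand count", {
  fac <- tibble::tibble(id = c("f1", "f2", "f3", "f4"),
                        class = c("private clinic", "private clinic",
                                  "public hospital", "public hospital"),
                        substitutable = TRUE)
  visits <- make_visits(
    list(visit_id = "v1", dwelling_id = "d1", facility_id = "f3"),
    list(visit_id = "v2", dwelling_id = "d1", facility_id = "f4"))
  events <- tibble::tibble(
    visit_id = c("v1", "v1", "v1"),
    visited_facility_id = "f3",
    bypassed_facility_id = c("f1", "f2", "f4"),
    weight = c(10, 20, 5))
  bs <- bypass_statistics(events, visits, fac)
  # private clinics bypassed once each -> mean 1; hospitals (f3=0, f4=1) -> 0.5
  expect_equal(bs$mean_times_bypassed[bs$class == "private clinic"], 1)
  expect_equal(bs$mean_times_bypassed[bs$class == "public hospital"], 0.5)
  # v1 (public hospital) made 3 bypasses, v2 made 0 -> class mean 1.5
  expect_equal(bs$mean_bypasses_per_visit[bs$class == "public hospital"], 1.5)
  # zero events give all-zero class means
  empty <- events[0, ]
  bs0 <- bypass_statistics(empty, visits[0, ], fac)
  expect_true(all(bs0$mean_times_bypassed == 0))
  expect_true(all(bs0$mean_bypasses_per_visit == 0))
})

test_that("per-visit normalisation splits each visit's weight across its events", {
  fac <- tibble::tibble(id = c("f1", "f2", "f3"),
                        class = c("private clinic", "public clinic", "public hospital"),
                        substitutable = TRUE)
  events <- tibble::tibble(
    visit_id = c("v1", "v1", "v2"),
    visited_facility_id = c("f3", "f3", "f3"),
    bypassed_facility_id = c("f1", "f2", "f1"),
    weight = c(10, 30, 8))
  pqi <- compute_pqi(events, fac, normalise_per_visit = TRUE)
  expect_equal(pqi$pqi[pqi$facility_id == "f3"], (10 + 30) / 2 + 8)
  expect_equal(sum(pqi$pqi), 0)
})
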