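# Event consensus across regions.

test_that("region event tables expose each region's common events", {
  inp <- fig1_instance()
  reg <- cost_regions(pareto_reconcile(inp), cost_box(0.1, 5, 0.1, 5))
  tab <- region_event_table(reg)
  expect_length(tab, 2)
  # the transfer-optimum region carries the transfer event and the root
  # speciation (its unique reconciliation's full event set)
  tkey <- grep("^<0,1,0>$", names(tab))
  expect_length(tkey, 1)
  ev <- tab[[tkey]]
  expect_true(any(startsWith(ev, "T:")))
  expect_true(any(startsWith(ev, "S:")))
  expect_length(ev, 2)
  # a fit without event tracking cannot be summarised
  fit0 <- pareto_reconcile(inp, events = FALSE)
  expect_error(region_event_table(cost_regions(fit0, cost_box())),
               "events = TRUE")
})

test_that("the k-region partition is a disjoint cover of all common events", {
  inp <- fig1_instance()
  reg <- cost_regions(pareto_reconcile(inp), cost_box(0.1, 5, 0.1, 5))
  part <- partition_by_region_count(reg)
  tab <- region_event_table(reg)
  all_ev <- sort(unique(unlist(tab)))
  expect_equal(sort(unname(unlist(part))), all_ev)
  expect_equal(sum(lengths(part)), length(all_ev))
  # here the two regions map the root speciation to different species
  # nodes, so no event is shared: everything sits in the k = 1 bucket
  expect_length(part[["1"]], length(all_ev))
  expect_length(part[["2"]], 0)

  # single-region analysis: everything in bucket 1
  cong <- congruent_instance(4, seed = 21)
  reg1 <- cost_regions(pareto_reconcile(cong), cost_box())
  p1 <- partition_by_region_count(reg1)
  expect_length(p1, 1)
  expect_gt(length(p1[["1"]]), 0)
})

test_that("common events are exactly the oracle intersection per region", {
  sims <- random_instances(6, seed = 55)
  box <- cost_box("1/10", 5, "1/10", 5)
  for (sim in sims) {
    fit <- pareto_reconcile(sim$input)
    orc <- oracle_summary(sim$input)
    reg <- cost_regions(fit, box)
    for (r in reg) {
      v <- r$vector
      hit <- which(orc$vectors[, 1] == v[1] & orc$vectors[, 2] == v[2] &
                   orc$vectors[, 3] == v[3])
      common <- Reduce(intersect, lapply(orc$scenarios[hit], `[[`, "events"))
      expect_true(setequal(r$events, common))
      # every common event occurs in every optimal scenario at an interior
      # point of the region
      if (r$dimension == 2L) {
        pt <- region_interior_point(r)
        costs <- event_costs(pt[1], pt[2])
        cs <- vapply(orc$scenarios, function(s)
          as.numeric(reconciliation_cost(s$vector, costs)), numeric(1))
        optimal <- orc$scenarios[abs(cs - min(cs)) < 1e-9]
        for (ev in r$events)
          for (s in optimal)
            expect_true(ev %in% s$events)
      }
    }
  }
})

test_that("consensus support fractions behave and are monotone", {
  inp <- fig1_instance()
  reg <- cost_regions(pareto_reconcile(inp), cost_box(0.1, 5, 0.1, 5))
  sup_r <- consensus_support(reg, "region_fraction")
  sup_a <- consensus_support(reg, "area_fraction")
  expect_true(all(sup_r$region_fraction >= 0 & sup_r$region_fraction <= 1))
  expect_true(all(sup_a$area_fraction >= 0 & sup_a$area_fraction <= 1))
  # no shared events here: every event in 1 of 2 regions
  expect_true(all(sup_r$n_regions == 1))
  expect_true(all(sup_r$region_fraction == 0.5))
  # area fractions: transfer-region events cover area(R(<0,1,0>))/24.01
  tr_ev <- sup_a[sup_a$type == "transfer", ]
  expect_equal(tr_ev$area_fraction, (13037 / 600) / 24.01, tolerance = 1e-12)

  # support >= s is non-increasing in s under both measures
  for (sup in list(sup_r, sup_a))
    for (m in c("region_fraction", "area_fraction")) {
      curve <- support_curve(sup, seq(0, 1, by = 0.01), m)
      expect_true(all(diff(curve$n_events) <= 0))
    }

  # single-region analysis: support is 0 or 1 under the region measure
  cong <- congruent_instance(4, seed = 31)
  sup1 <- consensus_support(cost_regions(pareto_reconcile(cong), cost_box()))
  expect_true(all(sup1$region_fraction %in% c(0, 1)))

  # an event common to all regions has support 1 under both measures
  expect_true(all(sup1$area_fraction == 1))
})
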