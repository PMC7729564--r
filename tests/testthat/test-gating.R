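test_that("otsu threshold splits a bimodal sample between the modes", {
  x <- c(rep(1, 50), rep(1.1, 50), rep(10, 40), rep(10.5, 40))
  o <- otsu_threshold(x)
  expect_gt(o$threshold, 1.1)
  expect_lt(o$threshold, 10)
  expect_gt(o$separation, 4)
  # unimodal data yield weak separation
  set.seed(1)
  u <- otsu_threshold(rnorm(5000))
  expect_lt(u$separation, 4)
})

test_that("doublet exclusion recovers planted doublet fractions", {
  # no doublets planted
  pops0 <- well_populations(planted_weights(20, c(0.7, 0.2, 0.1),
                                            doublet_rate = 0))
  ev0 <- simulate_well_events(pops0, 5000, seed = 11)
  sg0 <- gate_singlets(ev0)
  expect_lt(nrow(sg0$doublets) / nrow(ev0), 0.005)

  # 10% planted doublets, default geometry
  pops <- well_populations(planted_weights(20, c(0.7, 0.2, 0.1),
                                           doublet_rate = 0.1))
  ev <- simulate_well_events(pops, 20000, seed = 12)
  sg <- gate_singlets(ev)
  expect_lt(abs(100 * nrow(sg$doublets) / nrow(ev) - 10), 1.5)
  # partition is exhaustive and disjoint
  expect_equal(nrow(sg$singlets) + nrow(sg$doublets), nrow(ev))
})

test_that("identical events gate identically and zero FSC_A is an anomaly", {
  ev <- centroid_events(50, live_centroid)
  sg <- gate_singlets(ev)
  expect_true(nrow(sg$singlets) == 50 || nrow(sg$doublets) == 50)
  ev$FSC_A[3] <- 0
  sg2 <- gate_singlets(ev)
  expect_equal(sg2$n_anomalies, 1)
  expect_true(3 %in% sg2$doublets$event_id)
})

test_that("viability gating recovers planted mortality", {
  # 50% dead at the default 10x dye separation
  pops <- well_populations(planted_weights(50, c(0.7, 0.2, 0.1), 0))
  ev <- simulate_well_events(pops, 20000, seed = 13)
  sg <- gate_singlets(ev)
  vb <- gate_viability(sg$singlets)
  truth <- 100 * mean(sg$singlets$true_pop == "singlet_dead")
  expect_lt(abs(vb$mortality_pct - truth), 1)
  expect_lt(abs(vb$mortality_pct - 50), 1.5)

  # zero planted dead: auto threshold must not split the live mode
  pops0 <- well_populations(planted_weights(0, c(0.7, 0.2, 0.1), 0))
  ev0 <- simulate_well_events(pops0, 20000, seed = 14)
  vb0 <- gate_viability(gate_singlets(ev0)$singlets)
  expect_lte(vb0$mortality_pct, 0.5)
  expect_true(vb0$degenerate)

  # all events at dead-level intensity
  evd <- centroid_events(100, dead_centroid)
  vbd <- gate_viability(evd)
  expect_equal(vbd$mortality_pct, 100)
})

test_that("DNA-content quadrants recover planted phase fractions", {
  pops <- well_populations(planted_weights(0, c(0.7, 0.2, 0.1), 0))
  ev <- simulate_well_events(pops, 20000, seed = 15)
  dna <- gate_dna_content(gate_viability(gate_singlets(ev)$singlets)$live)
  expect_lt(abs(dna$g0_pct - 70), 2)
  expect_lt(abs(dna$g2_pct - 20), 2)
  expect_lt(abs(dna$g1m_pct - 10), 2)

  # vegetative day-0 profile with no G0 planted
  pops0 <- well_populations(planted_weights(0, c(0, 0.7, 0.3), 0))
  ev0 <- simulate_well_events(pops0, 20000, seed = 16)
  dna0 <- gate_dna_content(gate_viability(gate_singlets(ev0)$singlets)$live)
  expect_lte(dna0$g0_pct, 1)

  # every event at the G0 centroid
  evg <- centroid_events(200, live_centroid)
  dnag <- gate_dna_content(evg)
  expect_equal(dnag$g0_pct, 100)
})

test_that("well summaries apply the 1000-singlet QC cutoff exactly", {
  ws_fail <- summarize_well(centroid_events(999, live_centroid))
  expect_false(ws_fail$qc_pass)
  expect_equal(ws_fail$n_singlets, 999)
  ws_pass <- summarize_well(centroid_events(1000, live_centroid))
  expect_true(ws_pass$qc_pass)
  # fractions still reported on QC failure
  expect_true(is.finite(ws_fail$mortality_pct))
  expect_error(summarize_well(centroid_events(0, live_centroid)), "empty")
})

test_that("gating conserves events at every stage and ignores row order", {
  pops <- well_populations(planted_weights(30, c(0.6, 0.25, 0.15), 0.05))
  ev <- simulate_well_events(pops, 8000, seed = 17)
  ws <- summarize_well(ev)
  expect_equal(ws$n_live + ws$n_dead, ws$n_singlets)
  expect_lte(ws$n_singlets, ws$n_events)
  expect_lte(ws$g0_pct + ws$g2_pct + ws$g1m_pct, 100 + 1e-9)

  set.seed(1)
  shuf <- ev[sample(nrow(ev)), ]
  ws2 <- summarize_well(shuf)
  for (f in c("n_events", "n_singlets", "n_live", "n_dead", "mortality_pct",
              "g0_pct", "g2_pct", "g1m_pct", "qc_pass")) {
    expect_equal(ws2[[f]], ws[[f]])
  }
})

test_that("fixed thresholds override the automatic splits", {
  pops <- well_populations(planted_weights(50, c(0.7, 0.2, 0.1), 0))
  ev <- simulate_well_events(pops, 4000, seed = 18)
  p <- gate_params(viability_threshold = 3, dna_a_split = sqrt(2),
                   dna_w_split = sqrt(2))
  ws <- summarize_well(ev, p)
  expect_equal(ws$thresholds$viability, 3)
  expect_lt(abs(ws$mortality_pct - 50), 2)
})
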