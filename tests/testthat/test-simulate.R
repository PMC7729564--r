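test_that("noise-free trajectories equal the generating model exactly", {
  tr <- simulate_trajectory(list(model_id = "exp2p", params = c(5, 0),
                                 timepoints = c(0, 1, 7), noise_sd = 0))
  expect_equal(tr$mortality_pct, c(5, 5, 5))
  tr2 <- simulate_trajectory(list(model_id = "exp2p", params = c(12.5, log(2)),
                                  timepoints = c(0, 1, 2), noise_sd = 0))
  expect_equal(tr2$mortality_pct, c(12.5, 25, 50))
  tr3 <- simulate_trajectory(list(model_id = "logistic3p",
                                  params = c(100, 1, 10),
                                  timepoints = c(0, 10), noise_sd = 0))
  expect_equal(tr3$mortality_pct[2], 50)
  # planted (noise-free) mortality always carried alongside observations
  expect_equal(tr2$true_pct, tr2$mortality_pct, tolerance = 1e-12)
})

test_that("trajectory validation and clamping behave", {
  expect_error(
    simulate_trajectory(list(model_id = "exp2p", params = c(5, 0.1),
                             timepoints = c(0, 7, 7), noise_sd = 0)),
    "offending index 3")
  # heavy noise still stays on the percentage scale
  tr <- simulate_trajectory(list(model_id = "exp2p", params = c(50, 0),
                                 timepoints = c(0, 1, 7, 14), noise_sd = 200),
                            seed = 3)
  expect_true(all(tr$mortality_pct >= 0 & tr$mortality_pct <= 100))
  # seeded determinism
  a <- simulate_trajectory(list(model_id = "exp2p", params = c(5, 0.2),
                                timepoints = c(0, 1, 7), noise_sd = 2), seed = 9)
  b <- simulate_trajectory(list(model_id = "exp2p", params = c(5, 0.2),
                                timepoints = c(0, 1, 7), noise_sd = 2), seed = 9)
  expect_identical(a, b)
})

test_that("well event mixtures honor planted weights and determinism", {
  pops1 <- well_populations(c(singlet_live_G0 = 1))
  ev1 <- simulate_well_events(pops1, 1000, seed = 2)
  expect_equal(nrow(ev1), 1000)
  expect_true(all(ev1$true_pop == "singlet_live_G0"))

  pops2 <- well_populations(c(singlet_live_G0 = 0.9, singlet_dead = 0.1))
  ev2 <- simulate_well_events(pops2, 20000, seed = 5)
  dead_frac <- mean(ev2$true_pop == "singlet_dead")
  expect_lt(abs(dead_frac - 0.1), 0.01)
  # label counts conserve the event total
  expect_equal(sum(table(ev2$true_pop)), 20000)

  ev2b <- simulate_well_events(pops2, 20000, seed = 5)
  expect_identical(ev2, ev2b)
  expect_error(simulate_well_events(list(), 100), "empty population")
})

test_that("screen simulation produces one table per (strain, day) with truth", {
  cfg <- default_screen_config(n_strains = 1, n_events = 500)
  # 1 mutant + control over 6 days
  scr <- simulate_screen(cfg, seed = 4)
  expect_length(scr$wells, 12)
  expect_equal(nrow(scr$layout), 12)
  expect_length(scr$ground_truth$strains, 2)
  scr2 <- simulate_screen(cfg, seed = 5)
  expect_false(identical(scr$wells, scr2$wells))
  expect_identical(names(scr$ground_truth$strains),
                   names(scr2$ground_truth$strains))
})

test_that("planted dead weight follows the generating trajectory exactly", {
  cfg <- default_screen_config(n_strains = 1, n_events = 100,
                               timepoints = c(0, 1, 2), noise_sd = 0,
                               doublet_rate = 0)
  cfg$archetypes <- list(doubling = list(
    model_id = "exp2p", params = c(a = 12.5, b = log(2)),
    phase = list(day0 = c(0.1, 0.6, 0.3), day1 = c(0.7, 0.2, 0.1),
                 late = c(0.8, 0.15, 0.05))))
  cfg$strains <- data.frame(strain_id = "mutA", archetype = "doubling",
                            stringsAsFactors = FALSE)
  scr <- simulate_screen(cfg, seed = 1)
  wt <- scr$ground_truth$strains$mutA$wells[["2"]]
  expect_equal(wt$weights$singlet_dead, 0.5, tolerance = 1e-12)
  expect_equal(wt$model_mortality_pct, 50, tolerance = 1e-12)
  # mixture weights in truth always sum to 1
  for (day in names(scr$ground_truth$strains$mutA$wells)) {
    w <- unlist(scr$ground_truth$strains$mutA$wells[[day]]$weights)
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_error(
    {
      cfg2 <- cfg
      cfg2$strains <- rbind(cfg2$strains, cfg2$strains)
      simulate_screen(cfg2, seed = 1)
    },
    "duplicate")
})

test_that("substream seeds are deterministic, bounded and key-sensitive", {
  s1 <- derive_stream_seed(42, "mut001|7")
  expect_identical(s1, derive_stream_seed(42, "mut001|7"))
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
  expect_false(s1 == derive_stream_seed(42, "mut001|14"))
  expect_false(s1 == derive_stream_seed(43, "mut001|7"))
})

test_that("phenotype archetype simulation keeps planted separation", {
  ph <- simulate_phenotypes(7, 20, 6, seed = 3)
  expect_equal(nrow(ph), 140)
  expect_equal(sort(unique(ph$archetype)), 1:7)
  expect_identical(ph, simulate_phenotypes(7, 20, 6, seed = 3))
  # archetype centres stay at least ~separation apart in within-SD units
  feat_sd <- c(2.5, 1.8, 2.2, 2.5, 2.2)
  cent <- t(sapply(split(ph[, 3:7], ph$archetype), colMeans))
  cent <- sweep(cent, 2, feat_sd, "/")
  d <- as.matrix(dist(cent))
  expect_gt(min(d[upper.tri(d)]), 4.5)
})
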