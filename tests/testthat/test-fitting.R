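days6 <- c(0, 1, 7, 14, 21, 28)

test_that("noise-free exponential data are recovered to high precision", {
  y <- evaluate_model("exp2p", c(5, 0.1), days6)
  fit <- fit_model("exp2p", data.frame(day = days6, mortality_pct = y))
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["a"]] - 5), 1e-4)
  expect_lt(abs(fit$params[["b"]] - 0.1), 1e-4)
  expect_gte(fit$r2, 1 - 1e-10)
  # reported rss equals the residual sum of squares of the returned params
  resid <- evaluate_model("exp2p", fit$params, days6) - y
  expect_equal(fit$rss, sum(resid^2), tolerance = 1e-8)
})

test_that("constant data collapse to the zero-rate limit", {
  fit <- fit_model("exp2p", data.frame(day = days6, mortality_pct = rep(5, 6)))
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["b"]]), 1e-6)
  expect_lt(abs(fit$params[["a"]] - 5), 1e-6)
})

test_that("insufficient observations yield an honest non-converged fit", {
  short <- data.frame(day = c(0, 7, 14), mortality_pct = c(1, 5, 20))
  fit <- fit_model("logistic5p", short)
  expect_false(fit$converged)
  expect_match(fit$reason, "observations")
  # and never an exception from ill-conditioned data
  flat0 <- data.frame(day = days6, mortality_pct = rep(0, 6))
  expect_no_error(fit_all_models(flat0))
})

test_that("selection returns the generating model on noise-free data", {
  y <- evaluate_model("logistic3p", c(100, 0.5, 10), days6)
  sel <- select_model(fit_all_models(data.frame(day = days6,
                                                mortality_pct = y)))
  expect_equal(sel$model_id, "logistic3p")
  expect_gte(sel$r2, 1 - 1e-9)
  expect_false(sel$t99$censored)
})

test_that("models that cannot reach 99% are excluded by the second criterion", {
  # saturates at 80%: its own fit has top r2 but censored t99
  y <- evaluate_model("mech_growth", c(80, 0.98, 0.3), days6)
  fits <- fit_all_models(data.frame(day = days6, mortality_pct = y))
  expect_true(fits$mech_growth$t99$censored)
  expect_gte(fits$mech_growth$r2, 1 - 1e-9)
  sel <- select_model(fits)
  any_finite <- any(vapply(fits, function(f)
    isTRUE(f$converged) && !f$t99$censored, logical(1)))
  if (any_finite) {
    expect_false(sel$model_id == "mech_growth")
    expect_false(sel$t99$censored)
  } else {
    expect_true(sel$t99$censored)
  }
})

test_that("single candidates and unfittable strains are handled", {
  y <- evaluate_model("exp2p", c(5, 0.2), days6)
  fit <- fit_model("exp2p", data.frame(day = days6, mortality_pct = y))
  sel <- select_model(list(exp2p = fit))
  expect_equal(sel$model_id, "exp2p")
  expect_equal(sel$params, fit$params)

  bad <- fit_model("logistic5p",
                   data.frame(day = c(0, 7), mortality_pct = c(1, 2)))
  expect_null(select_model(list(logistic5p = bad)))
  ws <- data.frame(strain_id = "mutX", day = c(0, 7),
                   mortality_pct = c(1, 2), g0_pct = 50, g2_pct = 20,
                   g1m_pct = 10, qc_pass = TRUE)
  tab <- fit_screen(ws)
  expect_false(tab$fittable)
})

test_that("noise-free bootstrap intervals collapse and reruns are identical", {
  y <- evaluate_model("exp2p", c(5, 0.2), days6)
  traj <- data.frame(day = days6, mortality_pct = y)
  fit <- fit_model("exp2p", traj)
  ci <- halflife_confidence_interval(fit, traj, n_boot = 50, seed = 7)
  expect_lt(ci$high - ci$low, 1e-3)
  expect_false(ci$unreliable)
  ci2 <- halflife_confidence_interval(fit, traj, n_boot = 50, seed = 7)
  expect_identical(ci, ci2)
})

test_that("bootstrap intervals cover the true half-life at nominal rate", {
  true_t50 <- log(50 / 5) / 0.2
  hits <- 0L
  for (r in 1:50) {
    traj <- simulate_trajectory(list(model_id = "exp2p", params = c(5, 0.2),
                                     timepoints = days6, noise_sd = 2),
                                seed = 4000 + r)
    fit <- fit_model("exp2p", traj[, c("day", "mortality_pct")])
    ci <- halflife_confidence_interval(fit, traj, n_boot = 200,
                                       seed = 8000 + r)
    if (is.finite(ci$low) && ci$low <= true_t50 && true_t50 <= ci$high) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 45)
})

test_that("screen-level fitting drops QC-failed wells instead of imputing", {
  ws <- data.frame(
    strain_id = "mutA", day = days6,
    mortality_pct = evaluate_model("exp2p", c(5, 0.2), days6),
    g0_pct = 80, g2_pct = 10, g1m_pct = 5,
    qc_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  tab <- fit_screen(ws)
  expect_true(tab$fittable)
  expect_equal(tab$model_id, "exp2p")
  expect_lt(abs(tab$t50 - log(10) / 0.2), 0.05)
})
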