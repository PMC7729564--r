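# Nonlinear mortality-curve fitting: Levenberg-Marquardt least squares with a
# deterministic multi-start grid, rule-based model selection, threshold-time
# extrapolation and residual-resampling bootstrap confidence intervals.

#' Fitting options
#'
#' @param horizon Extrapolation horizon in days for T1/4, T1/2 and T99
#'   (default 1000); threshold times beyond it are censored at the horizon.
#' @param r2_tie_tol Fits whose R2 is within this of the best eligible R2 are
#'   treated as tied in model selection and broken by parsimony (fewest
#'   parameters), then by canonical model order. Needed because nested models
#'   (e.g. `exp3p` contains `exp2p`) reproduce a generating curve exactly.
#' @return A `fit_options` list.
#' @export
fit_options <- function(horizon = 1000, r2_tie_tol = 1e-6) {
  stopifnot(horizon > 0, r2_tie_tol >= 0)
  list(horizon = horizon, r2_tie_tol = r2_tie_tol)
}

# Minimum usable observations per model: parameter count + 1.
.min_obs <- function(model_id) model_arity(model_id) + 1L

# Deterministic start grid (8 starts per model) from data-range heuristics.
.starts_for <- function(model_id, t, y) {
  y1 <- y[1]; yend <- y[length(y)]
  ymin <- min(y); ymax <- max(y)
  tend <- max(t)
  # day at which y first crosses half its range (sigmoid midpoint guess)
  half <- (ymin + ymax) / 2
  cross <- which(y >= half)
  tmid <- if (length(cross) > 0) t[cross[1]] else tend / 2
  a_hi <- min(105, max(ymax * 1.1, 1))
  bhat <- if (y1 > 0 && yend > 0 && tend > 0) log(yend / y1) / tend else 0.05

  s <- switch(model_id,
    exp2p = {
      g <- expand.grid(a = c(max(y1, 0.1), max(mean(y), 0.1)),
                       b = c(0.01, 0.1, 0.3, bhat))
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i]))
    },
    exp3p = {
      g <- expand.grid(a = c(max(y1 * 0.8, 0), 0.1),
                       c = c(0.02, 0.08, 0.2, 0.4))
      lapply(seq_len(nrow(g)), function(i) {
        a <- g$a[i]; cc <- g$c[i]
        b <- (yend - a) / exp(cc * tend)
        c(a, b, cc)
      })
    },
    logistic3p = {
      g <- expand.grid(a = c(a_hi, 100), b = c(0.1, 0.4),
                       c = c(tmid, tend / 2))
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i], g$c[i]))
    },
    logistic5p = {
      # profile grid over the asymmetry exponent; e is pinned during the
      # first optimization pass and released afterwards (see fit_model)
      lapply(c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16), function(e)
        c(a_hi, 0.3, tmid, max(ymin * 0.9, 0), e))
    },
    gompertz3p = {
      g <- expand.grid(a = c(a_hi, 100), b = c(0.1, 0.4),
                       c = c(tmid, tend / 2))
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i], g$c[i]))
    },
    mech_growth = {
      g <- expand.grid(a = c(a_hi, 100), c = c(0.02, 0.05, 0.15, 0.4))
      lapply(seq_len(nrow(g)), function(i) {
        a <- g$a[i]
        c(a, 1 - y1 / a, g$c[i])
      })
    },
    probit4p = {
      g <- expand.grid(b = c(0.05, 0.15, 0.3, 0.6), c = c(tmid, tend / 2))
      lapply(seq_len(nrow(g)), function(i)
        c(a_hi, g$b[i], g$c[i], max(ymin * 0.9, 0)))
    },
    stop("unknown model_id '", model_id, "'")
  )
  s
}

.clamp_to_bounds <- function(p, lower, upper) pmin(pmax(p, lower), upper)

# Levenberg-Marquardt with box constraints handled by fit-then-project:
# an unconstrained run comes first (nls.lm's clamped steps can stall on an
# active bound), and only when its solution leaves the box is a bounded
# polish run from the projected point. Returns list(par, rss) or NULL.
.lm_fit <- function(resid_fn, start, lower, upper) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  grab <- function(res) {
    if (is.null(res) || !res$info %in% 1:4) return(NULL)
    rss <- sum(res$fvec^2)
    if (!is.finite(rss) || any(!is.finite(res$par))) return(NULL)
    list(par = as.numeric(res$par), rss = rss)
  }
  free <- grab(tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, control = ctrl),
    error = function(e) NULL))
  if (!is.null(free) &&
      all(free$par >= lower - 1e-9) && all(free$par <= upper + 1e-9)) {
    free$par <- .clamp_to_bounds(free$par, lower, upper)
    return(free)
  }
  from <- if (!is.null(free)) .clamp_to_bounds(free$par, lower, upper)
          else start
  bounded <- grab(tryCatch(
    minpack.lm::nls.lm(par = from, lower = lower, upper = upper,
                       fn = resid_fn, control = ctrl),
    error = function(e) NULL))
  bounded
}

#' Fit one kinetic model to a mortality trajectory
#'
#' Trust-region (Levenberg-Marquardt) nonlinear least squares via
#' [minpack.lm::nls.lm()] with box bounds, run from 8 deterministic starting
#' points derived from the data range; the best converged run is kept. Never
#' raises on ill-conditioned data: failures are reported through the
#' `converged` flag and `reason`.
#'
#' @param model_id One of the seven model identifiers (see
#'   [mortality_models]).
#' @param trajectory Data frame with columns `day` (strictly increasing) and
#'   `mortality_pct`.
#' @param options [fit_options()].
#' @return A `model_fit` list: `model_id`, named `params`, `rss`, `r2`,
#'   `converged`, `n_obs`, threshold times `t25`, `t50`, `t99` with censor
#'   flags, `horizon`, and `reason` when unusable.
#' @export
fit_model <- function(model_id, trajectory, options = fit_options()) {
  m <- .get_model(model_id)
  t <- trajectory$day
  y <- trajectory$mortality_pct
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (any(diff(t) <= 0)) stop("days must be strictly increasing")

  empty <- structure(list(model_id = model_id, params = NULL, rss = NA_real_,
                          r2 = NA_real_, converged = FALSE,
                          n_obs = length(t), t25 = NA, t50 = NA, t99 = NA,
                          horizon = options$horizon, fit_zscore = NA_real_,
                          reason = NA_character_),
                     class = "model_fit")
  if (length(t) < .min_obs(model_id)) {
    empty$reason <- sprintf("needs >= %d usable observations, got %d",
                            .min_obs(model_id), length(t))
    return(empty)
  }

  resid_fn <- function(p) m$fn(p, t) - y
  best <- NULL
  for (start in .starts_for(model_id, t, y)) {
    start <- .clamp_to_bounds(start, m$lower, m$upper)
    if (model_id == "logistic5p") {
      # profile pass: pin the asymmetry exponent, fit the other parameters,
      # then release all five from that solution (the full 5-parameter
      # surface has broad flat basins in e)
      e_fix <- start[5]
      pre <- .lm_fit(function(p4) resid_fn(c(p4, e_fix)), start[1:4],
                     m$lower[1:4], m$upper[1:4])
      if (!is.null(pre)) start <- c(pre$par, e_fix)
    }
    res <- .lm_fit(resid_fn, start, m$lower, m$upper)
    if (is.null(res)) next
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  if (is.null(best)) {
    empty$reason <- "no start converged"
    return(empty)
  }

  params <- stats::setNames(as.numeric(best$par), m$param_names)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else if (best$rss <= 1e-10) 1 else -Inf
  tt <- lapply(c(25, 50, 99), function(lv)
    threshold_time(model_id, params, lv, options$horizon))
  structure(list(
    model_id = model_id, params = params, rss = best$rss, r2 = r2,
    converged = TRUE, n_obs = length(t),
    t25 = tt[[1]], t50 = tt[[2]], t99 = tt[[3]],
    horizon = options$horizon, fit_zscore = NA_real_,
    reason = NA_character_), class = "model_fit")
}

#' Fit all seven kinetic models
#'
#' @inheritParams fit_model
#' @return Named list of `model_fit` objects, one per model (models with too
#'   few usable observations are returned non-converged with a reason).
#' @export
fit_all_models <- function(trajectory, options = fit_options()) {
  stats::setNames(lapply(MODEL_IDS, fit_model, trajectory = trajectory,
                         options = options), MODEL_IDS)
}

#' Select the optimal kinetic model
#'
#' Implements the two-criterion rule: (1) among converged fits, goodness of
#' fit is standardized across candidates (`fit_zscore`, the z-score of R2);
#' (2) the selected model must be able to predict a day of 99% mortality
#' within the horizon. Among fits meeting criterion (2), the highest z-score
#' wins; fits whose R2 is within `r2_tie_tol` of the best are tied and broken
#' by parsimony (fewest parameters), then canonical model order. If no fit
#' reaches 99% within the horizon, the best-R2 fit is returned with all
#' threshold times censored at the horizon.
#'
#' @param fits List of `model_fit` objects (e.g. [fit_all_models()]).
#' @param options [fit_options()].
#' @return The selected `model_fit` with `fit_zscore` filled in, or `NULL`
#'   when no candidate converged (the strain is then flagged unfittable by
#'   [fit_screen()] and excluded from clustering).
#' @export
select_model <- function(fits, options = fit_options()) {
  if (length(fits) == 0) stop("no candidate fits supplied")
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    return(NULL)
  }
  r2 <- vapply(conv, function(f) f$r2, numeric(1))
  z <- if (length(r2) > 1 && stats::sd(r2) > 0) {
    (r2 - mean(r2)) / stats::sd(r2)
  } else rep(0, length(r2))
  for (i in seq_along(conv)) conv[[i]]$fit_zscore <- z[i]

  eligible <- vapply(conv, function(f) !f$t99$censored, logical(1))
  pool <- if (any(eligible)) conv[eligible] else conv
  pr2 <- vapply(pool, function(f) f$r2, numeric(1))
  tied <- which(pr2 >= max(pr2) - options$r2_tie_tol)
  arity <- vapply(pool[tied], function(f) model_arity(f$model_id), integer(1))
  tied <- tied[arity == min(arity)]
  ord <- match(vapply(pool[tied], function(f) f$model_id, character(1)),
               MODEL_TIE_ORDER)
  chosen <- pool[[tied[which.min(ord)]]]

  if (!any(eligible)) {
    # criterion (2) unmet by every model: censor all threshold times
    for (slot in c("t25", "t50", "t99")) {
      chosen[[slot]] <- list(time = chosen$horizon, censored = TRUE,
                             horizon = chosen$horizon)
    }
  }
  chosen
}

#' Bootstrap confidence interval for a threshold time
#'
#' Residual-resampling bootstrap: residuals of the selected fit are resampled
#' with replacement onto the fitted curve, the model is refitted (single
#' start at the original estimate) and the threshold time recomputed;
#' the 95% interval is the percentile interval over converged, uncensored
#' replicates. Deterministic given `seed`.
#'
#' @param fit A converged `model_fit`.
#' @param trajectory The data the fit was produced from.
#' @param level Mortality level in percent (default 50, i.e. T1/2).
#' @param n_boot Number of bootstrap refits (default 200).
#' @param seed Integer seed.
#' @param options [fit_options()].
#' @return List with `low`, `high` (days), `level`, `n_effective` (usable
#'   replicates) and `unreliable` (`TRUE` when fewer than half the refits
#'   converged).
#' @export
halflife_confidence_interval <- function(fit, trajectory, level = 50,
                                         n_boot = 200, seed = 1,
                                         options = fit_options()) {
  stopifnot(isTRUE(fit$converged))
  m <- .get_model(fit$model_id)
  t <- trajectory$day
  y <- trajectory$mortality_pct
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  yhat <- m$fn(fit$params, t)
  resid <- y - yhat

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  times <- rep(NA_real_, n_boot)
  n_conv <- 0L
  for (b in seq_len(n_boot)) {
    yb <- yhat + sample(resid, length(resid), replace = TRUE)
    res <- .lm_fit(function(p) m$fn(p, t) - yb, as.numeric(fit$params),
                   m$lower, m$upper)
    if (is.null(res)) next
    n_conv <- n_conv + 1L
    tt <- threshold_time(fit$model_id, res$par, level, options$horizon)
    if (!tt$censored) times[b] <- tt$time
  }
  usable <- times[is.finite(times)]
  qs <- if (length(usable) > 0) {
    stats::quantile(usable, c(0.025, 0.975), names = FALSE, type = 7)
  } else c(NA_real_, NA_real_)
  list(low = qs[1], high = qs[2], level = level,
       n_effective = length(usable),
       unreliable = n_conv < n_boot / 2)
}

#' Fit and select models for every strain of a screen
#'
#' Applies [fit_all_models()] and [select_model()] per strain to a well-summary
#' table, dropping QC-failed wells (they propagate as missing time points, not
#' zeros).
#'
#' @param well_summaries Data frame from [summarize_screen()] (columns
#'   `strain_id`, `day`, `mortality_pct`, `qc_pass`).
#' @param options [fit_options()].
#' @param ci_boot Bootstrap replicates for the T1/2 confidence interval
#'   per strain (default 200; 0 skips the interval columns' computation).
#' @param seed Seed for the bootstrap substreams (one per strain).
#' @return Data frame with one row per strain: selected `model_id`, fitted
#'   `params` (serialized `name=value;...`), `r2`, `fit_zscore`, `t25`,
#'   `t50`, `t99`, censor flags, `t50_ci_low`/`t50_ci_high` (95% bootstrap
#'   bounds), and `fittable`; the numeric parameter vectors are also
#'   attached as the `"params"` attribute (named list).
#' @export
fit_screen <- function(well_summaries, options = fit_options(),
                       ci_boot = 200, seed = 1) {
  strains <- unique(well_summaries$strain_id)
  params_list <- list()
  rows <- lapply(strains, function(sid) {
    d <- well_summaries[well_summaries$strain_id == sid &
                          well_summaries$qc_pass &
                          is.finite(well_summaries$mortality_pct), ,
                        drop = FALSE]
    d <- d[order(d$day), ]
    traj <- data.frame(day = d$day, mortality_pct = d$mortality_pct)
    sel <- if (nrow(traj) >= 3) select_model(fit_all_models(traj, options),
                                             options) else NULL
    if (is.null(sel)) {
      return(data.frame(strain_id = sid, model_id = NA_character_,
                        params = NA_character_, r2 = NA_real_,
                        fit_zscore = NA_real_,
                        t25 = NA_real_, t50 = NA_real_, t99 = NA_real_,
                        t25_censored = NA, t50_censored = NA,
                        t99_censored = NA,
                        t50_ci_low = NA_real_, t50_ci_high = NA_real_,
                        fittable = FALSE, stringsAsFactors = FALSE))
    }
    params_list[[sid]] <<- sel$params
    ci <- c(NA_real_, NA_real_)
    if (ci_boot > 0 && !sel$t50$censored) {
      b <- halflife_confidence_interval(
        sel, traj, level = 50, n_boot = ci_boot,
        seed = derive_stream_seed(seed, paste0("boot:", sid)),
        options = options)
      if (!b$unreliable) ci <- c(b$low, b$high)
    }
    data.frame(strain_id = sid, model_id = sel$model_id,
               params = paste(sprintf("%s=%.6g", names(sel$params),
                                      sel$params), collapse = ";"),
               r2 = sel$r2, fit_zscore = sel$fit_zscore,
               t25 = sel$t25$time, t50 = sel$t50$time, t99 = sel$t99$time,
               t25_censored = sel$t25$censored,
               t50_censored = sel$t50$censored,
               t99_censored = sel$t99$censored,
               t50_ci_low = ci[1], t50_ci_high = ci[2],
               fittable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "params") <- params_list
  out
}
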