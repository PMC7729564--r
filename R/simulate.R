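# Synthetic plate-format cytometry: mixture-model event tables with known
# ground truth, emulating a nitrogen-starvation quiescence screen.

EVENT_CHANNELS <- c("FSC_A", "FSC_H", "SSC_A", "VIAB", "DNA_A", "DNA_W")
POPULATION_NAMES <- c("singlet_live_G0", "singlet_live_G2", "singlet_live_G1M",
                      "singlet_dead", "doublet")

#' Describe one planted event population
#'
#' A well is simulated as a finite mixture of particle populations. Each
#' population has per-channel log-normal intensity distributions given by a
#' location (mean) and a coefficient of variation. `FSC_H` is special-cased to
#' preserve the singlet/doublet pulse geometry: it is drawn as
#' `(mean_H / mean_A) * FSC_A * noise`, with `noise` log-normal at CV
#' `channel_cvs["FSC_H"]`, so singlets keep FSC-H proportional to FSC-A while
#' doublets (doubled FSC-A, unchanged FSC-H) sit at roughly half the
#' singlet H/A ratio.
#'
#' @param name Population label, one of `"singlet_live_G0"`,
#'   `"singlet_live_G2"`, `"singlet_live_G1M"`, `"singlet_dead"`, `"doublet"`.
#' @param channel_means Named numeric vector over the six channels
#'   (`FSC_A`, `FSC_H`, `SSC_A`, `VIAB`, `DNA_A`, `DNA_W`), all `> 0`
#'   (arbitrary fluorescence units).
#' @param channel_cvs Named numeric vector of per-channel coefficients of
#'   variation, all `> 0`.
#' @param weight Mixture fraction in `[0, 1]`.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, channel_means, channel_cvs, weight) {
  name <- match.arg(name, POPULATION_NAMES)
  stopifnot(all(EVENT_CHANNELS %in% names(channel_means)),
            all(EVENT_CHANNELS %in% names(channel_cvs)))
  channel_means <- channel_means[EVENT_CHANNELS]
  channel_cvs <- channel_cvs[EVENT_CHANNELS]
  if (any(channel_means <= 0)) stop("all channel means must be > 0")
  if (any(channel_cvs <= 0)) stop("all channel CVs must be > 0")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  structure(list(name = name, channel_means = channel_means,
                 channel_cvs = channel_cvs, weight = weight),
            class = "population_spec")
}

# Default channel geometry. DNA content in "C" units: G0 is 1C mononuclear
# (DNA_A 1, DNA_W 1), G2 is 2C mononuclear (DNA_A 2, DNA_W 1), G1/M is 2C
# binuclear (DNA_A 2, DNA_W 2: the pulse of two nuclei is wider). Dead cells
# carry a 10x viability-dye signal and arbitrary DNA values (they are gated
# out before DNA analysis). Doublets double FSC-A and DNA-A but keep FSC-H
# near the singlet level.
.default_channel_geometry <- function() {
  cvs <- c(FSC_A = 0.15, FSC_H = 0.08, SSC_A = 0.20,
           VIAB = 0.30, DNA_A = 0.12, DNA_W = 0.12)
  list(
    singlet_live_G0 = list(
      means = c(FSC_A = 100, FSC_H = 100, SSC_A = 80, VIAB = 1,
                DNA_A = 1, DNA_W = 1), cvs = cvs),
    singlet_live_G2 = list(
      means = c(FSC_A = 120, FSC_H = 120, SSC_A = 90, VIAB = 1,
                DNA_A = 2, DNA_W = 1), cvs = cvs),
    singlet_live_G1M = list(
      means = c(FSC_A = 120, FSC_H = 120, SSC_A = 90, VIAB = 1,
                DNA_A = 2, DNA_W = 2), cvs = cvs),
    singlet_dead = list(
      means = c(FSC_A = 90, FSC_H = 90, SSC_A = 85, VIAB = 10,
                DNA_A = 1.5, DNA_W = 1.2), cvs = cvs),
    doublet = list(
      means = c(FSC_A = 200, FSC_H = 100, SSC_A = 160, VIAB = 1,
                DNA_A = 3, DNA_W = 1.5), cvs = cvs)
  )
}

#' Build a well's population mixture from planted fractions
#'
#' @param weights Named numeric vector of mixture fractions over (a subset of)
#'   the five population names; must sum to 1 within 1e-9.
#' @param geometry Optional channel geometry (as returned by the package
#'   default); each element has `means` and `cvs` per channel.
#' @return List of [population_spec()] objects.
#' @export
well_populations <- function(weights, geometry = NULL) {
  if (is.null(geometry)) geometry <- .default_channel_geometry()
  if (length(weights) == 0) stop("at least one population required")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("population weights must sum to 1 (got ", sum(weights), ")")
  }
  lapply(names(weights), function(nm) {
    population_spec(nm, geometry[[nm]]$means, geometry[[nm]]$cvs, weights[[nm]])
  })
}

#' Simulate a mortality trajectory
#'
#' Evaluates a kinetic model at the sampling days and adds Gaussian
#' measurement noise, clamping the result to `[0, 100]` percent.
#'
#' @param spec List with `model_id`, `params`, `timepoints` (days, must start
#'   at 0 and be strictly increasing) and `noise_sd` (percentage points).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return Data frame with columns `day`, `mortality_pct` and `true_pct`
#'   (the noise-free model value).
#' @examples
#' simulate_trajectory(list(model_id = "exp2p", params = c(12.5, log(2)),
#'                          timepoints = c(0, 1, 2), noise_sd = 0), seed = 1)
#' @export
simulate_trajectory <- function(spec, seed = 1) {
  tp <- spec$timepoints
  if (length(tp) < 1 || tp[1] != 0) stop("timepoints must include day 0 first")
  bad <- which(diff(tp) <= 0)
  if (length(bad) > 0) {
    stop("timepoints must be strictly increasing; offending index ", bad[1] + 1)
  }
  true_pct <- evaluate_model(spec$model_id, spec$params, tp)
  noise_sd <- if (is.null(spec$noise_sd)) 0 else spec$noise_sd
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  obs <- true_pct + stats::rnorm(length(tp), 0, noise_sd)
  obs <- pmin(pmax(obs, 0), 100)
  data.frame(day = tp, mortality_pct = obs, true_pct = true_pct)
}

# Save/restore the global RNG state so seeded simulators do not perturb the
# caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive a reproducible per-well RNG substream seed
#'
#' Hashes a string key (e.g. `"strain:day"`) into `[0, 2^31 - 2]` and folds in
#' the global seed, so every well is independently reproducible from the
#' global seed alone.
#'
#' @param seed Global integer seed.
#' @param key Character key identifying the substream.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_stream_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer((h + (seed %% m)) %% m)
}

.rlnorm_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one well's event table
#'
#' Draws `n_events` particles from the population mixture. Channel intensities
#' are log-normal within each population; `FSC_H` is derived from the event's
#' own `FSC_A` (see [population_spec()]) so that the H/A ratio carries the
#' singlet/doublet discrimination.
#'
#' @param populations List of [population_spec()] objects; weights must sum
#'   to 1.
#' @param n_events Number of events to draw (`>= 1`).
#' @param seed Integer seed; identical inputs give identical tables.
#' @return Data frame with columns `event_id`, the six channels, and
#'   `true_pop` (the planted population label, dropped on export by
#'   [write_event_table()]).
#' @export
simulate_well_events <- function(populations, n_events, seed = 1) {
  if (length(populations) == 0) stop("empty population list")
  stopifnot(n_events >= 1)
  w <- vapply(populations, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("population weights must sum to 1")
  nms <- vapply(populations, function(p) p$name, character(1))

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  labels <- sample(seq_along(populations), n_events, replace = TRUE, prob = w)

  out <- matrix(NA_real_, nrow = n_events, ncol = length(EVENT_CHANNELS),
                dimnames = list(NULL, EVENT_CHANNELS))
  for (i in seq_along(populations)) {
    idx <- which(labels == i)
    if (length(idx) == 0) next
    p <- populations[[i]]
    fsc_a <- .rlnorm_cv(length(idx), p$channel_means[["FSC_A"]],
                        p$channel_cvs[["FSC_A"]])
    ratio <- p$channel_means[["FSC_H"]] / p$channel_means[["FSC_A"]]
    fsc_h <- ratio * fsc_a *
      .rlnorm_cv(length(idx), 1, p$channel_cvs[["FSC_H"]])
    out[idx, "FSC_A"] <- fsc_a
    out[idx, "FSC_H"] <- fsc_h
    for (ch in c("SSC_A", "VIAB", "DNA_A", "DNA_W")) {
      out[idx, ch] <- .rlnorm_cv(length(idx), p$channel_means[[ch]],
                                 p$channel_cvs[[ch]])
    }
  }
  cbind(data.frame(event_id = seq_len(n_events)), as.data.frame(out),
        data.frame(true_pop = nms[labels]))
}

#' Planted per-well population weights for a given mortality level
#'
#' Converts a mortality percentage (of singlets) and a live-cell phase profile
#' into mixture weights over the five populations, reserving `doublet_rate`
#' of all events for doublets.
#'
#' @param mortality_pct Percent dead among singlets, in `[0, 100]`.
#' @param phase Numeric length-3 vector `(g0, g2, g1m)` of live-singlet phase
#'   fractions summing to 1.
#' @param doublet_rate Fraction of all events that are doublets.
#' @return Named weight vector summing to 1.
#' @export
planted_weights <- function(mortality_pct, phase, doublet_rate = 0.05) {
  stopifnot(mortality_pct >= 0, mortality_pct <= 100,
            abs(sum(phase) - 1) < 1e-9, doublet_rate >= 0, doublet_rate < 1)
  singlet <- 1 - doublet_rate
  dead <- singlet * mortality_pct / 100
  live <- singlet - dead
  c(singlet_live_G0 = live * phase[1],
    singlet_live_G2 = live * phase[2],
    singlet_live_G1M = live * phase[3],
    singlet_dead = dead,
    doublet = doublet_rate)
}

#' Default screen simulation configuration
#'
#' Defines the study conditions the simulator emulates: six sampling days
#' (0, 1, 7, 14, 21, 28), about 20,000 events per well, a small doublet
#' contamination, 2 percentage points of measurement noise on mortality, and
#' seven phenotype archetypes spanning the behaviours seen in quiescence
#' screens — control-like slow mortality, graded fast-mortality phenotypes
#' with normal G0 entry, G0-entry defects of two severities, a high-G2
#' vegetative profile, and a miscellaneous mild class. Each archetype carries
#' a generating kinetic model and live-cell phase profiles for day 0, day 1
#' and later days (fractions G0/G2/G1M of live singlets).
#'
#' @param n_strains Number of mutant strains (cycled over archetypes);
#'   a `smt0_control` strain is always added.
#' @param n_events Events per well.
#' @param timepoints Sampling days; must start at 0.
#' @param noise_sd Mortality measurement noise (percentage points).
#' @param doublet_rate Doublet fraction per well.
#' @return A `screen_config` list.
#' @export
default_screen_config <- function(n_strains = 60, n_events = 20000,
                                  timepoints = c(0, 1, 7, 14, 21, 28),
                                  noise_sd = 2, doublet_rate = 0.05) {
  archetypes <- list(
    control_like = list(
      model_id = "exp2p", params = c(a = 2, b = 0.08),
      phase = list(day0 = c(0.02, 0.68, 0.30), day1 = c(0.75, 0.15, 0.10),
                   late = c(0.88, 0.08, 0.04))),
    mild_mortality = list(
      model_id = "exp2p", params = c(a = 3, b = 0.16),
      phase = list(day0 = c(0.02, 0.68, 0.30), day1 = c(0.72, 0.17, 0.11),
                   late = c(0.85, 0.10, 0.05))),
    strong_mortality = list(
      model_id = "exp2p", params = c(a = 5, b = 0.30),
      phase = list(day0 = c(0.02, 0.66, 0.32), day1 = c(0.78, 0.13, 0.09),
                   late = c(0.86, 0.09, 0.05))),
    entry_defect_strong = list(
      model_id = "logistic3p", params = c(a = 90, b = 0.35, c = 12),
      phase = list(day0 = c(0.02, 0.70, 0.28), day1 = c(0.20, 0.50, 0.30),
                   late = c(0.35, 0.40, 0.25))),
    entry_defect_mild = list(
      model_id = "gompertz3p", params = c(a = 70, b = 0.20, c = 14),
      phase = list(day0 = c(0.02, 0.69, 0.29), day1 = c(0.45, 0.35, 0.20),
                   late = c(0.60, 0.25, 0.15))),
    high_g2_day0 = list(
      model_id = "exp3p", params = c(a = 1, b = 1, c = 0.12),
      phase = list(day0 = c(0.01, 0.85, 0.14), day1 = c(0.70, 0.20, 0.10),
                   late = c(0.84, 0.11, 0.05))),
    miscellaneous_mild = list(
      model_id = "mech_growth", params = c(a = 45, b = 0.95, c = 0.10),
      phase = list(day0 = c(0.03, 0.60, 0.37), day1 = c(0.65, 0.22, 0.13),
                   late = c(0.78, 0.14, 0.08)))
  )
  strains <- data.frame(
    strain_id = sprintf("mut%03d", seq_len(n_strains)),
    archetype = names(archetypes)[((seq_len(n_strains) - 1) %% length(archetypes)) + 1],
    stringsAsFactors = FALSE
  )
  strains <- rbind(
    data.frame(strain_id = "smt0_control", archetype = "control_like",
               stringsAsFactors = FALSE),
    strains
  )
  structure(list(strains = strains, archetypes = archetypes,
                 timepoints = timepoints, n_events = n_events,
                 noise_sd = noise_sd, doublet_rate = doublet_rate,
                 control_strain = "smt0_control"),
            class = "screen_config")
}

.phase_for_day <- function(arch, day) {
  ph <- if (day == 0) arch$phase$day0 else if (day == 1) arch$phase$day1
        else arch$phase$late
  ph / sum(ph)
}

#' Simulate a whole screen
#'
#' Composes [simulate_trajectory()] and [simulate_well_events()] across a
#' plate layout: one well per (strain, day). Every well uses a substream seed
#' derived from the global seed and the `"strain:day"` key
#' ([derive_stream_seed()]), so outputs are reproducible well by well.
#'
#' @param config A `screen_config`, e.g. [default_screen_config()].
#' @param seed Global integer seed.
#' @return List with `wells` (named list of event tables, keys
#'   `"strain|day"`), `layout` (data frame `strain_id`, `well`, `day`) and
#'   `ground_truth` (per-strain generating model, true T1/2 and T1/4, and
#'   per-well planted weights and noise-free mortality).
#' @export
simulate_screen <- function(config, seed = 1) {
  strains <- config$strains
  if (anyDuplicated(strains$strain_id) > 0) {
    stop("duplicate strain ids in config")
  }
  wells <- list()
  layout <- list()
  truth_strains <- list()
  for (i in seq_len(nrow(strains))) {
    sid <- strains$strain_id[i]
    arch <- config$archetypes[[strains$archetype[i]]]
    traj <- simulate_trajectory(
      list(model_id = arch$model_id, params = arch$params,
           timepoints = config$timepoints, noise_sd = config$noise_sd),
      seed = derive_stream_seed(seed, paste0("traj:", sid))
    )
    well_truth <- list()
    for (j in seq_along(config$timepoints)) {
      day <- config$timepoints[j]
      key <- paste0(sid, "|", day)
      if (!is.null(wells[[key]])) stop("duplicate (strain, day) key: ", key)
      ph <- .phase_for_day(arch, day)
      w <- planted_weights(traj$mortality_pct[j], ph, config$doublet_rate)
      pops <- well_populations(w)
      wells[[key]] <- simulate_well_events(
        pops, config$n_events, seed = derive_stream_seed(seed, key))
      layout[[key]] <- data.frame(strain_id = sid, well = key, day = day,
                                  stringsAsFactors = FALSE)
      well_truth[[as.character(day)]] <-
        list(weights = as.list(w), mortality_pct = traj$mortality_pct[j],
             model_mortality_pct = traj$true_pct[j])
    }
    t50 <- threshold_time(arch$model_id, arch$params, 50)
    t25 <- threshold_time(arch$model_id, arch$params, 25)
    truth_strains[[sid]] <- list(
      archetype = strains$archetype[i], model_id = arch$model_id,
      params = as.list(arch$params),
      true_t50 = t50$time, t50_censored = t50$censored,
      true_t25 = t25$time, t25_censored = t25$censored,
      wells = well_truth)
  }
  list(wells = wells,
       layout = do.call(rbind, c(layout, list(make.row.names = FALSE))),
       ground_truth = list(seed = seed, strains = truth_strains))
}

#' Simulate a phenotype-feature matrix with planted archetypes
#'
#' Generates the five clustering features (T1/2, T1/4, G2% at day 0, G0% at
#' day 1 and day 7) directly at the feature level: archetype centres are
#' placed with a minimum pairwise separation of `separation` within-cluster
#' standard deviations in 5-D feature space, and strains scatter around their
#' centre with unit (per-feature) within-cluster SD. Used to validate the
#' clustering stage at scales where full event-level simulation is
#' unnecessary.
#'
#' @param n_archetypes Number of planted archetypes (2 to 7).
#' @param n_per Strains per archetype.
#' @param separation Centre separation in within-cluster SD units.
#' @param seed Integer seed.
#' @return Data frame with `strain_id`, `archetype`, and the five features
#'   `t50`, `t25`, `g2_day0`, `g0_day1`, `g0_day7`.
#' @export
simulate_phenotypes <- function(n_archetypes = 7, n_per = 20, separation = 6,
                                seed = 1) {
  p <- 5
  stopifnot(n_archetypes >= 2, n_archetypes <= p + 2)
  # unit-scale centre layout: origin, the p axis points, and a diagonal point;
  # minimum pairwise distance is exactly 1
  base <- rbind(rep(0, p), diag(p), rep(1 / sqrt(p), p))
  centers <- separation * base[seq_len(n_archetypes), , drop = FALSE]
  # rotate through a fixed orthogonal basis so the planted structure spreads
  # over all five features rather than aligning with feature axes
  # (per-feature z-scoring then preserves the geometry); distances between
  # centres are unchanged
  rot <- qr.Q(qr(diag(p) + 1))
  centers <- centers %*% t(rot)

  feat_mean <- c(t50 = 35, t25 = 22, g2_day0 = 50, g0_day1 = 55, g0_day7 = 60)
  feat_sd <- c(t50 = 2.5, t25 = 1.8, g2_day0 = 2.2, g0_day1 = 2.5, g0_day7 = 2.2)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  arch <- rep(seq_len(n_archetypes), each = n_per)
  z <- centers[arch, , drop = FALSE] +
    matrix(stats::rnorm(length(arch) * p), ncol = p)
  x <- sweep(sweep(z, 2, feat_sd, "*"), 2, feat_mean, "+")
  colnames(x) <- names(feat_mean)
  x[, 3:5] <- pmin(pmax(x[, 3:5], 0), 100)
  data.frame(strain_id = sprintf("s%03d", seq_along(arch)),
             archetype = arch, x, stringsAsFactors = FALSE)
}
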