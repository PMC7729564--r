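# Gating cascade: doublet exclusion on the FSC-H/FSC-A ratio, live/dead
# classification on the viability dye, DNA-content classification of live
# singlets into G0 / G2 / binuclear G1-M.

#' Gating parameters
#'
#' @param singlet_ratio_band Length-2 numeric: allowed `FSC_H / FSC_A`
#'   interval for singlets. With the default pulse geometry singlets sit near
#'   ratio 1 and doublets near 0.5.
#' @param viability_threshold `"auto"` (Otsu split on log dye intensity, with
#'   a bimodality guard) or a fixed dye cutoff; events above are dead.
#' @param viability_fallback Fixed cutoff used when `"auto"` finds no bimodal
#'   structure (flagged in the result).
#' @param dna_a_split `"auto"` or fixed 1C/2C boundary on `DNA_A`.
#' @param dna_a_fallback Fixed boundary used when `"auto"` degenerates;
#'   default `sqrt(2)`, the geometric midpoint of the 1C and 2C positions.
#' @param dna_w_split `"auto"` or fixed mono/binuclear boundary on `DNA_W`.
#' @param dna_w_fallback As `dna_a_fallback`, for `DNA_W`.
#' @param min_singlets QC cutoff: wells with fewer singlets fail QC
#'   (default 1000).
#' @param min_separation Bimodality guard for `"auto"` thresholds: required
#'   between-class mean separation in pooled within-class SD units on the log
#'   scale.
#' @return A `gate_params` list.
#' @export
gate_params <- function(singlet_ratio_band = c(0.7, 1.4),
                        viability_threshold = "auto",
                        viability_fallback = 3,
                        dna_a_split = "auto", dna_a_fallback = sqrt(2),
                        dna_w_split = "auto", dna_w_fallback = sqrt(2),
                        min_singlets = 1000, min_separation = 4) {
  stopifnot(length(singlet_ratio_band) == 2,
            singlet_ratio_band[1] < singlet_ratio_band[2],
            min_singlets >= 1, min_separation > 0)
  structure(list(singlet_ratio_band = singlet_ratio_band,
                 viability_threshold = viability_threshold,
                 viability_fallback = viability_fallback,
                 dna_a_split = dna_a_split, dna_a_fallback = dna_a_fallback,
                 dna_w_split = dna_w_split, dna_w_fallback = dna_w_fallback,
                 min_singlets = min_singlets, min_separation = min_separation),
            class = "gate_params")
}

#' Two-class intensity split (Otsu's method)
#'
#' Places a threshold on a numeric vector by minimizing the weighted
#' within-class variance over all possible two-class splits (equivalently,
#' maximizing between-class variance). Exact over the sorted sample, not a
#' histogram approximation.
#'
#' @param x Numeric vector, length `>= 2`.
#' @return List with `threshold` (midpoint between the two classes),
#'   `separation` (between-class mean distance in pooled within-SD units;
#'   `Inf` when both classes are constant) and the two class means.
#' @export
otsu_threshold <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 2)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  n1 <- k; n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  ss1 <- cs2[k] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[k]) - n2 * m2^2
  # cumulative-sum cancellation can leave tiny negative values
  within <- pmax(ss1 + ss2, 0)
  # skip splits between tied values (threshold would be ill-defined)
  valid <- x[k] < x[k + 1]
  if (!any(valid)) {
    return(list(threshold = x[1], separation = 0, m1 = m1[1], m2 = m2[1]))
  }
  within[!valid] <- Inf
  i <- which.min(within)
  pooled <- sqrt(within[i] / n)
  sep <- if (pooled == 0) Inf else (m2[i] - m1[i]) / pooled
  list(threshold = (x[i] + x[i + 1]) / 2, separation = sep,
       m1 = m1[i], m2 = m2[i])
}

# Resolve an "auto" threshold on log intensity with bimodality guard.
# Returns the threshold on the ORIGINAL scale plus a degenerate flag.
.resolve_auto <- function(x, setting, fallback, min_separation) {
  if (!identical(setting, "auto")) {
    return(list(threshold = as.numeric(setting), degenerate = FALSE))
  }
  pos <- x[x > 0]
  if (length(pos) < 2) {
    return(list(threshold = fallback, degenerate = TRUE))
  }
  o <- otsu_threshold(log(pos))
  if (!is.finite(o$separation) || o$separation < min_separation) {
    list(threshold = fallback, degenerate = TRUE)
  } else {
    list(threshold = exp(o$threshold), degenerate = FALSE)
  }
}

.check_event_table <- function(events) {
  miss <- setdiff(EVENT_CHANNELS, names(events))
  if (length(miss) > 0) {
    stop("event table lacks channel(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(events) < 1) stop("empty event table")
  invisible(events)
}

#' Doublet exclusion on the FSC-H/FSC-A ratio
#'
#' Events whose `FSC_H / FSC_A` ratio lies inside the singlet band are
#' singlets; all others (including any event with `FSC_A == 0`, which is also
#' counted as an anomaly) are doublets. The partition is exhaustive and
#' disjoint.
#'
#' @param events Event table (data frame with the six channels).
#' @param params [gate_params()].
#' @return List with `singlets`, `doublets` (row subsets of `events`) and
#'   `n_anomalies` (events with zero FSC_A).
#' @export
gate_singlets <- function(events, params = gate_params()) {
  .check_event_table(events)
  zero_a <- events$FSC_A == 0
  ratio <- ifelse(zero_a, NA_real_, events$FSC_H / events$FSC_A)
  in_band <- !is.na(ratio) &
    ratio >= params$singlet_ratio_band[1] &
    ratio <= params$singlet_ratio_band[2]
  list(singlets = events[in_band, , drop = FALSE],
       doublets = events[!in_band, , drop = FALSE],
       n_anomalies = sum(zero_a))
}

#' Live/dead classification on the viability dye
#'
#' Dead cells carry high amine-reactive dye intensity; events above the
#' threshold are dead. With `viability_threshold = "auto"` the cutoff is
#' placed by a two-class split of log dye intensity; if the distribution has
#' no bimodal structure (separation below `min_separation`) the configured
#' fixed fallback is used and the well is flagged.
#'
#' @param singlets Singlet event table (`>= 1` row).
#' @param params [gate_params()].
#' @return List with `live`, `dead` (row subsets), `mortality_pct`
#'   (`100 * dead / (dead + live)`), `threshold` and `degenerate` flag.
#' @export
gate_viability <- function(singlets, params = gate_params()) {
  if (nrow(singlets) < 1) stop("no singlet events")
  res <- .resolve_auto(singlets$VIAB, params$viability_threshold,
                       params$viability_fallback, params$min_separation)
  dead <- singlets$VIAB > res$threshold
  list(live = singlets[!dead, , drop = FALSE],
       dead = singlets[dead, , drop = FALSE],
       mortality_pct = 100 * sum(dead) / length(dead),
       threshold = res$threshold, degenerate = res$degenerate)
}

#' DNA-content classification of live singlets
#'
#' Quadrant rule on `(DNA_A, DNA_W)`: G0 is DNA-A low / DNA-W low (1C
#' mononuclear), G2 is DNA-A high / DNA-W low (2C mononuclear), G1/M is
#' DNA-A high / DNA-W high (2C binuclear). The DNA-A split separates 1C from
#' 2C; the DNA-W split (placed on the 2C subpopulation, where both mono- and
#' binuclear particles occur) separates mono- from binuclear pulses. Live
#' cells falling in no quadrant of interest (DNA-A low / DNA-W high) are left
#' unclassified and reported as the remainder.
#'
#' @param live_singlets Live singlet event table (`>= 1` row).
#' @param params [gate_params()].
#' @return List with `g0_pct`, `g2_pct`, `g1m_pct` (percent of live
#'   singlets), the two resolved splits, their degeneracy flags, and the
#'   per-event `class` factor (`G0`, `G2`, `G1M`, `unclassified`).
#' @export
gate_dna_content <- function(live_singlets, params = gate_params()) {
  if (nrow(live_singlets) < 1) stop("no live singlet events")
  a_res <- .resolve_auto(live_singlets$DNA_A, params$dna_a_split,
                         params$dna_a_fallback, params$min_separation)
  high_a <- live_singlets$DNA_A > a_res$threshold
  w_source <- if (sum(high_a) >= 2) live_singlets$DNA_W[high_a]
              else live_singlets$DNA_W
  w_res <- .resolve_auto(w_source, params$dna_w_split,
                         params$dna_w_fallback, params$min_separation)
  high_w <- live_singlets$DNA_W > w_res$threshold
  cls <- rep("unclassified", nrow(live_singlets))
  cls[!high_a & !high_w] <- "G0"
  cls[high_a & !high_w] <- "G2"
  cls[high_a & high_w] <- "G1M"
  n <- length(cls)
  list(g0_pct = 100 * sum(cls == "G0") / n,
       g2_pct = 100 * sum(cls == "G2") / n,
       g1m_pct = 100 * sum(cls == "G1M") / n,
       dna_a_split = a_res$threshold, dna_w_split = w_res$threshold,
       dna_a_degenerate = a_res$degenerate,
       dna_w_degenerate = w_res$degenerate,
       class = factor(cls, levels = c("G0", "G2", "G1M", "unclassified")))
}

#' Gate one well end to end
#'
#' Composes doublet exclusion, viability classification and DNA-content
#' classification, and applies the minimum-singlet QC cutoff (default 1000).
#' Fraction fields are reported even for QC-failing wells, flagged via
#' `qc_pass`.
#'
#' @param events Event table for one well.
#' @param params [gate_params()].
#' @return A `well_summary` list: counts (`n_events`, `n_singlets`, `n_live`,
#'   `n_dead`, `n_anomalies`), `mortality_pct`, `g0_pct`, `g2_pct`,
#'   `g1m_pct`, `qc_pass`, and the resolved thresholds.
#' @export
summarize_well <- function(events, params = gate_params()) {
  .check_event_table(events)
  sg <- gate_singlets(events, params)
  n_singlets <- nrow(sg$singlets)
  qc_pass <- n_singlets >= params$min_singlets
  if (n_singlets == 0) {
    return(structure(list(
      n_events = nrow(events), n_singlets = 0L, n_live = 0L, n_dead = 0L,
      n_anomalies = sg$n_anomalies, mortality_pct = NA_real_,
      g0_pct = NA_real_, g2_pct = NA_real_, g1m_pct = NA_real_,
      qc_pass = FALSE, thresholds = NULL), class = "well_summary"))
  }
  vb <- gate_viability(sg$singlets, params)
  if (nrow(vb$live) >= 1) {
    dna <- gate_dna_content(vb$live, params)
    g0 <- dna$g0_pct; g2 <- dna$g2_pct; g1m <- dna$g1m_pct
    thr <- list(viability = vb$threshold, dna_a = dna$dna_a_split,
                dna_w = dna$dna_w_split,
                viability_degenerate = vb$degenerate,
                dna_a_degenerate = dna$dna_a_degenerate,
                dna_w_degenerate = dna$dna_w_degenerate)
  } else {
    g0 <- g2 <- g1m <- NA_real_
    thr <- list(viability = vb$threshold,
                viability_degenerate = vb$degenerate)
  }
  structure(list(
    n_events = nrow(events), n_singlets = n_singlets,
    n_live = nrow(vb$live), n_dead = nrow(vb$dead),
    n_anomalies = sg$n_anomalies,
    mortality_pct = vb$mortality_pct,
    g0_pct = g0, g2_pct = g2, g1m_pct = g1m,
    qc_pass = qc_pass, thresholds = thr), class = "well_summary")
}

#' Summarize every well of a simulated or loaded screen
#'
#' @param wells Named list of event tables keyed `"strain|day"`.
#' @param layout Data frame with `strain_id`, `well`, `day` matching the
#'   keys.
#' @param params [gate_params()].
#' @return Data frame with one row per well: `strain_id`, `day`, counts,
#'   fractions and `qc_pass` (the well-summary table written by the
#'   pipeline).
#' @export
summarize_screen <- function(wells, layout, params = gate_params()) {
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    key <- layout$well[i]
    ws <- summarize_well(wells[[key]], params)
    data.frame(strain_id = layout$strain_id[i], day = layout$day[i],
               n_events = ws$n_events, n_singlets = ws$n_singlets,
               n_live = ws$n_live, n_dead = ws$n_dead,
               mortality_pct = ws$mortality_pct, g0_pct = ws$g0_pct,
               g2_pct = ws$g2_pct, g1m_pct = ws$g1m_pct,
               qc_pass = ws$qc_pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
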