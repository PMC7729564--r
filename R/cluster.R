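# Five-feature phenotype clustering: Ward's method on z-scored features with
# cluster-number selection by the Cubic Clustering Criterion (CCC).

PHENOTYPE_FEATURES <- c("t50", "t25", "g2_day0", "g0_day1", "g0_day7")

#' Assemble the phenotype matrix
#'
#' Builds one record per strain from the selected-model fit table and the
#' well summaries: extrapolated T1/2 and T1/4 (censored values enter at the
#' horizon, flagged), G2% at day 0, and G0% after 1 and 7 days of nitrogen
#' starvation. Strains missing any feature (unfittable, or QC-failed wells at
#' the required days) are excluded with a logged reason.
#'
#' @param fit_table Data frame from [fit_screen()].
#' @param well_summaries Data frame from [summarize_screen()].
#' @return Data frame with `strain_id`, the five features, and censor flags
#'   `t50_censored`, `t25_censored`; excluded strains are recorded in the
#'   `"exclusions"` attribute (`strain_id`, `reason`).
#' @export
build_phenotype_matrix <- function(fit_table, well_summaries) {
  recs <- list(); excl <- list()
  pick <- function(sid, day, col) {
    r <- well_summaries[well_summaries$strain_id == sid &
                          well_summaries$day == day &
                          well_summaries$qc_pass, col]
    r <- r[is.finite(r)]
    if (length(r) == 0) NA_real_ else mean(r)
  }
  for (i in seq_len(nrow(fit_table))) {
    sid <- fit_table$strain_id[i]
    if (!isTRUE(fit_table$fittable[i])) {
      excl[[sid]] <- "unfittable mortality trajectory"
      next
    }
    g2_0 <- pick(sid, 0, "g2_pct")
    g0_1 <- pick(sid, 1, "g0_pct")
    g0_7 <- pick(sid, 7, "g0_pct")
    if (!all(is.finite(c(g2_0, g0_1, g0_7)))) {
      excl[[sid]] <- "incomplete features"
      next
    }
    recs[[sid]] <- data.frame(
      strain_id = sid, t50 = fit_table$t50[i], t25 = fit_table$t25[i],
      g2_day0 = g2_0, g0_day1 = g0_1, g0_day7 = g0_7,
      t50_censored = fit_table$t50_censored[i],
      t25_censored = fit_table$t25_censored[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(strain_id = character(0), t50 = numeric(0),
                      t25 = numeric(0), g2_day0 = numeric(0),
                      g0_day1 = numeric(0), g0_day7 = numeric(0),
                      t50_censored = logical(0), t25_censored = logical(0))
  }
  attr(out, "exclusions") <- if (length(excl) > 0) {
    data.frame(strain_id = names(excl), reason = unlist(excl),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(strain_id = character(0), reason = character(0))
  out
}

#' Z-score feature columns
#'
#' Centers each column to mean 0 and scales to unit sample standard deviation
#' (n - 1 denominator). Zero-variance columns are left at 0 and reported in
#' the `"constant_features"` attribute.
#'
#' @param x Numeric matrix or a data frame containing the feature columns
#'   (non-numeric columns such as `strain_id` are dropped; for phenotype
#'   records the five canonical features are used).
#' @return Numeric matrix of z-scores with the input row order preserved.
#' @export
standardize_features <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(PHENOTYPE_FEATURES, names(x))
    if (length(cols) == 0) cols <- names(x)[vapply(x, is.numeric, logical(1))]
    rn <- if ("strain_id" %in% names(x)) x$strain_id else rownames(x)
    x <- as.matrix(x[, cols, drop = FALSE])
    rownames(x) <- rn
  }
  stopifnot(is.numeric(x), nrow(x) >= 2)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  z[, const] <- 0
  attr(z, "constant_features") <- colnames(x)[const]
  z
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering minimizing the increase in total within-cluster
#' sum of squares at each merge (Ward's criterion), on Euclidean distances.
#' Merge heights are on the `sqrt(2 * increase-in-ESS)` scale and are
#' nondecreasing.
#'
#' @param x Numeric matrix (rows = records); typically
#'   [standardize_features()] output.
#' @return An [stats::hclust] object.
#' @export
ward_cluster <- function(x) {
  stopifnot(nrow(x) >= 2, !anyNA(x))
  stats::hclust(stats::dist(x), method = "ward.D2")
}

# R-squared of the k-group partition of x: 1 - SS(within) / SS(total).
.partition_r2 <- function(x, groups) {
  xc <- sweep(x, 2, colMeans(x))
  sst <- sum(xc^2)
  ssw <- 0
  for (g in unique(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    ssw <- ssw + sum(sweep(xg, 2, colMeans(xg))^2)
  }
  if (sst == 0) 1 else 1 - ssw / sst
}

# Expected R^2 under the uniform-hypercube null of the SAS CCC formulation.
# The data cloud is idealized as uniform over a hyperbox with edge lengths
# proportional to the principal-component standard deviations s_j; a
# q-cluster partition cuts the box into q cells of edge c = (v*/q)^(1/p*),
# v* the product of the first p* s_j. Only dimensions with s_j >= c are
# divided, so the partitionable dimensionality p* depends on q and is found
# by iterating p* down from p until s_[p*] >= c (dimensions thinner than a
# cell edge stay whole and keep their full variance within clusters).
.ccc_pstar <- function(s, q) {
  for (pstar in rev(seq_along(s))) {
    cc <- (prod(s[seq_len(pstar)]) / q)^(1 / pstar)
    if (s[pstar] >= cc || pstar == 1) {
      return(list(pstar = pstar, c = cc))
    }
  }
}

.ccc_expected_r2 <- function(s, pstar, cc, n, q) {
  u <- s / cc
  num <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < length(u)) {
    tail_u <- u[(pstar + 1):length(u)]
    num <- num + sum(tail_u^2 / (n + tail_u))
  }
  1 - (num / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
}

#' Cubic Clustering Criterion across candidate cluster numbers
#'
#' For each candidate k the dendrogram is cut into k groups, the partition
#' R-squared is compared with its expectation under a uniform-hypercube null
#' (SAS formulation), and
#' `CCC = ln((1 - E(R2)) / (1 - R2)) * sqrt(n * pstar / 2) / (0.001 + E(R2))^1.2`.
#' The partitionable dimensionality `pstar` is determined per k from the
#' hypercube geometry: dimensions whose principal SD falls below the cell
#' edge are not divided. The chosen k maximizes CCC; a
#' partition with R-squared exactly 1 is reported as `Inf` and chosen.
#' CCC values above about 2 indicate real cluster structure; a maximum below
#' 2 over the whole range is the no-structure convention.
#'
#' @param x The clustered matrix (as passed to [ward_cluster()]).
#' @param hc The [stats::hclust] object from [ward_cluster()].
#' @param k_range Candidate cluster numbers (default `2:15`), within
#'   `[2, n - 1]`.
#' @return List with `ccc_by_k` (data frame `k`, `r2`, `expected_r2`, `ccc`),
#'   `chosen_k`, `pstar`, and `assignments` (cluster labels at `chosen_k`).
#' @export
compute_ccc <- function(x, hc, k_range = 2:15) {
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  stopifnot(length(k_range) > 0)
  xc <- sweep(x, 2, colMeans(x))
  ev <- svd(xc, nu = 0, nv = 0)$d^2 / (n - 1)
  s <- sqrt(ev)
  s <- s[s > .Machine$double.eps * max(s)]

  rows <- lapply(k_range, function(k) {
    groups <- stats::cutree(hc, k = k)
    r2 <- .partition_r2(x, groups)
    ps <- .ccc_pstar(s, k)
    er2 <- .ccc_expected_r2(s, ps$pstar, ps$c, n, k)
    ccc <- if (r2 >= 1) Inf else {
      log((1 - er2) / (1 - r2)) * sqrt(n * ps$pstar / 2) / (0.001 + er2)^1.2
    }
    data.frame(k = k, r2 = r2, expected_r2 = er2, ccc = ccc,
               pstar = ps$pstar)
  })
  tab <- do.call(rbind, rows)
  chosen_k <- tab$k[which.max(tab$ccc)]
  list(ccc_by_k = tab, chosen_k = chosen_k,
       pstar = tab$pstar[tab$k == chosen_k],
       assignments = stats::cutree(hc, k = chosen_k))
}

#' Compare a mutant to the control strain
#'
#' Welch's independent-samples two-sided t-test on the compared measurements
#' (e.g. per-time-point mortality, or replicate feature values).
#'
#' @param control Numeric vector of control measurements (`>= 2` values).
#' @param mutant Numeric vector of mutant measurements (`>= 2` values).
#' @return List with `t` (statistic, mutant minus control orientation
#'   follows [stats::t.test()]'s first-minus-second convention with the
#'   control first), `p` (two-sided), and `df`.
#' @export
compare_to_control <- function(control, mutant) {
  stopifnot(length(control) >= 2, length(mutant) >= 2)
  ht <- stats::t.test(control, mutant, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Permutation-adjusted cluster label agreement
#'
#' Fraction of records on which two labelings agree, maximized over all
#' relabelings of the assigned clusters (exhaustive over permutations; up to
#' 8 clusters).
#'
#' @param truth Vector of true group labels.
#' @param assigned Vector of assigned cluster labels (same length).
#' @return Agreement fraction in `[0, 1]`.
#' @export
cluster_label_agreement <- function(truth, assigned) {
  stopifnot(length(truth) == length(assigned))
  conf <- table(truth, assigned)
  k1 <- nrow(conf); k2 <- ncol(conf)
  if (max(k1, k2) > 8) stop("exhaustive matching supported up to 8 clusters")
  # pad to square so permutations cover unmatched labels
  k <- max(k1, k2)
  m <- matrix(0, k, k)
  m[seq_len(k1), seq_len(k2)] <- conf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    hit <- sum(m[cbind(seq_len(k), p)])
    if (hit > best) best <- hit
  }
  best / length(truth)
}

#' Cluster a phenotype table end to end
#'
#' Standardizes the five features (toggleable), runs Ward clustering and CCC
#' cluster-number selection.
#'
#' @param phenotypes Data frame from [build_phenotype_matrix()] (or any data
#'   frame carrying the five feature columns and `strain_id`).
#' @param k_range Candidate cluster numbers.
#' @param standardize Z-score features first (default `TRUE`).
#' @return List with `assignments` (data frame `strain_id`, `cluster`),
#'   `ccc_by_k`, `chosen_k`, `pstar`, `hclust`, and `matrix` (the clustered
#'   matrix).
#' @export
cluster_phenotypes <- function(phenotypes, k_range = 2:15,
                               standardize = TRUE) {
  z <- if (standardize) standardize_features(phenotypes) else {
    m <- as.matrix(phenotypes[, PHENOTYPE_FEATURES, drop = FALSE])
    rownames(m) <- phenotypes$strain_id
    m
  }
  hc <- ward_cluster(z)
  res <- compute_ccc(z, hc, k_range)
  list(assignments = data.frame(strain_id = phenotypes$strain_id,
                                cluster = unname(res$assignments),
                                stringsAsFactors = FALSE),
       ccc_by_k = res$ccc_by_k, chosen_k = res$chosen_k, pstar = res$pstar,
       hclust = hc, matrix = z)
}
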