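# Independent reference implementations used as oracles in tests. These stay
# deliberately naive (enumeration / O(n^3) search) and share no code with the
# package internals they check.

# Hypergeometric point probability by the combinatorial quotient
# choose(K, k) * choose(N - K, n - k) / choose(N, n); exact in doubles for
# the N <= 30 range it is used on.
hyper_point_comb <- function(k, n, K, N) {
  if (k > K || (n - k) > (N - K)) return(0)
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

# Hypergeometric point probability by full subset enumeration (N <= 12):
# draw every size-n subset of a labeled universe whose first K elements are
# category members and count those containing exactly k of them.
hyper_point_enum <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(s <= K) == k)
  mean(hits)
}

# Ward agglomeration by exhaustive O(n^3) search over cluster pairs,
# minimizing the increase in total within-cluster sum of squares at each
# merge. Returns merge heights on the sqrt(2 * delta-ESS) scale and the
# partition (assignment vector) after each merge, indexed by the number of
# clusters remaining.
ward_reference <- function(x) {
  n <- nrow(x)
  ess <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  clusters <- lapply(seq_len(n), identity)
  cluster_ess <- rep(0, n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n)
  assign_of <- function(cl) {
    a <- integer(n)
    for (i in seq_along(cl)) a[cl[[i]]] <- i
    a
  }
  partitions[[n]] <- assign_of(clusters)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        merged <- c(clusters[[i]], clusters[[j]])
        delta <- ess(merged) - cluster_ess[i] - cluster_ess[j]
        if (is.null(best) || delta < best$delta) {
          best <- list(i = i, j = j, delta = delta, members = merged)
        }
      }
    }
    heights[step] <- sqrt(2 * best$delta)
    clusters[[best$i]] <- best$members
    cluster_ess[best$i] <- ess(best$members)
    clusters[[best$j]] <- NULL
    cluster_ess <- cluster_ess[-best$j]
    partitions[[length(clusters)]] <- assign_of(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# Build a deterministic, hand-constructed event table where every event sits
# exactly at its population centroid (no sampling noise).
centroid_events <- function(n, means) {
  cols <- c("FSC_A", "FSC_H", "SSC_A", "VIAB", "DNA_A", "DNA_W")
  out <- as.data.frame(lapply(means[cols], rep, times = n))
  names(out) <- cols
  cbind(data.frame(event_id = seq_len(n)), out)
}

# Exact set-partition equality, label-agnostic: two labelings describe the
# same partition iff the pairing of labels is one-to-one.
same_partition <- function(a, b) {
  joint <- length(unique(paste(a, b)))
  joint == length(unique(a)) && joint == length(unique(b))
}

live_centroid <- c(FSC_A = 100, FSC_H = 100, SSC_A = 80, VIAB = 1,
                   DNA_A = 1, DNA_W = 1)
dead_centroid <- c(FSC_A = 90, FSC_H = 90, SSC_A = 85, VIAB = 10,
                   DNA_A = 1.5, DNA_W = 1.2)
doublet_centroid <- c(FSC_A = 200, FSC_H = 100, SSC_A = 160, VIAB = 1,
                      DNA_A = 3, DNA_W = 1.5)
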