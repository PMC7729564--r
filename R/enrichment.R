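# Cluster-wise category (protein-complex / GO) enrichment: fold enrichment
# and hypergeometric probabilities over a fixed background gene universe.

.check_counts <- function(k, n, K, N, require_positive = FALSE) {
  if (any(c(k, n, K, N) != floor(c(k, n, K, N))) || any(c(k, n, K, N) < 0)) {
    stop("counts must be nonnegative integers")
  }
  if (require_positive && (n < 1 || K < 1)) {
    stop("cluster size n and category size K must be >= 1")
  }
  if (n > N || K > N) stop("n and K cannot exceed the background size N")
  if (k > min(n, K)) stop("k cannot exceed min(n, K)")
  if (k < max(0, n + K - N)) stop("inconsistent counts: k below feasible minimum")
  invisible(TRUE)
}

#' Fold enrichment of a category in a cluster
#'
#' `(k / n) / (K / N)`: the category fraction within the cluster over the
#' category fraction in the background. Equals 1 when the cluster is a
#' random sample (or the whole) of the background.
#'
#' @param k Category genes in the cluster.
#' @param n Cluster size.
#' @param K Category size in the background.
#' @param N Background (analyzed gene universe) size.
#' @return Fold enrichment (`>= 0`).
#' @examples
#' fold_enrichment(3, 15, 9, 684)   # 15.2
#' fold_enrichment(5, 108, 10, 684) # 3.17
#' @export
fold_enrichment <- function(k, n, K, N) {
  .check_counts(k, n, K, N, require_positive = TRUE)
  (k / n) / (K / N)
}

#' Hypergeometric point probability
#'
#' `P(X = k)` for the number of category genes landing in a cluster of size
#' `n` drawn without replacement from a background of `N` genes of which `K`
#' belong to the category: `choose(K, k) * choose(N - K, n - k) /
#' choose(N, n)`, evaluated in log space.
#'
#' @inheritParams fold_enrichment
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_point(2, 108, 2, 684)  # 0.0247
#' @export
hypergeom_point <- function(k, n, K, N) {
  .check_counts(k, n, K, N)
  stats::dhyper(k, K, N - K, n)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)`, the classical one-sided enrichment p-value; equals 1 at
#' `k = 0`.
#'
#' @inheritParams fold_enrichment
#' @return Probability in `[0, 1]`, always `>=` [hypergeom_point()].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  .check_counts(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a category catalog
#'
#' Accepts either two-column delimited text (`category`, `gene_id`; header
#' optional, comma or tab separated) or GMT (`category<TAB>description<TAB>`
#' gene ids). The background universe is read from a one-column file when
#' given, otherwise it defaults to the union of category members.
#'
#' @param path Catalog file path.
#' @param background_path Optional one-column file of background gene ids.
#' @return A `category_catalog` list: `categories` (named list of gene-id
#'   vectors) and `background` (character vector).
#' @export
read_catalog <- function(path, background_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
    any(lengths(strsplit(lines, "\t")) > 3)
  if (is_gmt) {
    cats <- list()
    for (ln in lines) {
      f <- strsplit(ln, "\t")[[1]]
      cats[[f[1]]] <- unique(f[-(1:2)])
    }
  } else {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE, strip.white = TRUE)
    if (identical(tolower(tab[1, 1]), "category")) tab <- tab[-1, , drop = FALSE]
    cats <- split(tab[[2]], tab[[1]])
    cats <- lapply(cats, unique)
  }
  background <- if (!is.null(background_path)) {
    bg <- trimws(readLines(background_path))
    unique(bg[nzchar(bg) & !startsWith(bg, "#")])
  } else unique(unlist(cats))
  category_catalog(cats, background)
}

#' Construct a category catalog
#'
#' @param categories Named list of gene-id vectors.
#' @param background Character vector, the analyzed gene universe; every
#'   category member must belong to it.
#' @return A `category_catalog` list.
#' @export
category_catalog <- function(categories, background) {
  stopifnot(length(background) >= 1, length(categories) >= 1,
            !is.null(names(categories)))
  stray <- setdiff(unlist(categories), background)
  if (length(stray) > 0) {
    stop("category members missing from background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  structure(list(categories = lapply(categories, unique),
                 background = unique(background)),
            class = "category_catalog")
}

#' Category enrichment per cluster
#'
#' For every (cluster, category) pair with at least one shared gene, computes
#' the contingency counts, fold enrichment, the hypergeometric point
#' probability `P(X = k)` (the statistic that per-complex screen reports
#' conventionally print), the
#' upper tail `P(X >= k)`, and Benjamini-Hochberg adjusted point
#' probabilities across all reported pairs.
#'
#' @param assignments Data frame with `strain_id` (gene id) and `cluster`.
#' @param catalog A [category_catalog()].
#' @return Data frame sorted by `p_point` with columns `cluster`, `category`,
#'   `k`, `n`, `K`, `N`, `fold`, `p_point`, `p_tail`, `p_bh`.
#' @export
cluster_enrichment <- function(assignments, catalog) {
  stopifnot(all(c("strain_id", "cluster") %in% names(assignments)))
  stray <- setdiff(assignments$strain_id, catalog$background)
  if (length(stray) > 0) {
    stop("assigned genes missing from background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  N <- length(catalog$background)
  rows <- list()
  for (cl in sort(unique(assignments$cluster))) {
    members <- assignments$strain_id[assignments$cluster == cl]
    n <- length(members)
    for (cat in names(catalog$categories)) {
      genes <- catalog$categories[[cat]]
      K <- length(genes)
      k <- length(intersect(members, genes))
      if (k == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, category = cat, k = k, n = n, K = K, N = N,
        fold = fold_enrichment(k, n, K, N),
        p_point = hypergeom_point(k, n, K, N),
        p_tail = hypergeom_tail(k, n, K, N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    return(data.frame(cluster = integer(0), category = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold = numeric(0), p_point = numeric(0),
                      p_tail = numeric(0), p_bh = numeric(0)))
  }
  out$p_bh <- stats::p.adjust(out$p_point, method = "BH")
  out[order(out$p_point), , drop = FALSE]
}
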