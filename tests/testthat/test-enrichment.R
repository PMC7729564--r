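test_that("fold enrichment is the exact count ratio", {
  expect_equal(fold_enrichment(3, 15, 9, 684), 15.2)
  expect_equal(fold_enrichment(2, 108, 2, 684), 19 / 3)  # 6.333...
  # whole background in one cluster
  expect_equal(fold_enrichment(9, 684, 9, 684), 1)
  # proportional representation gives fold exactly 1
  expect_equal(fold_enrichment(5, 50, 20, 200), 1)
  expect_error(fold_enrichment(0, 0, 5, 100), ">= 1")
  expect_error(fold_enrichment(6, 10, 5, 100), "exceed")
})

test_that("hypergeometric point probability matches exhaustive enumeration", {
  # the documented tiny case: 1 of 2 category genes in a 2-gene cluster
  expect_equal(hypergeom_point(1, 2, 2, 4), 2 / 3, tolerance = 1e-12)
  expect_equal(hyper_point_enum(1, 2, 2, 4), 2 / 3)
  expect_equal(hypergeom_point(0, 0, 3, 10), 1)
  # full subset enumeration for small universes
  for (N in c(6, 9, 12)) {
    for (n in c(2, N %/% 2)) {
      for (K in c(1, 3)) {
        for (k in max(0, n + K - N):min(n, K)) {
          expect_equal(hypergeom_point(k, n, K, N),
                       hyper_point_enum(k, n, K, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("point and tail probabilities agree with the combinatorial form", {
  for (N in c(10, 17, 23, 30)) {
    for (n in 1:N) {
      for (K in c(1, 2, N %/% 3, N %/% 2)) {
        if (K < 1) next
        ks <- max(0, n + K - N):min(n, K)
        pts <- vapply(ks, function(k) hyper_point_comb(k, n, K, N), 1)
        for (i in seq_along(ks)) {
          expect_equal(hypergeom_point(ks[i], n, K, N), pts[i],
                       tolerance = 1e-12)
          expect_equal(hypergeom_tail(ks[i], n, K, N),
                       sum(pts[i:length(ks)]), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the point mass sums to one over the support", {
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(5:200, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    total <- sum(vapply(ks, function(k) hypergeom_point(k, n, K, N), 1))
    expect_equal(total, 1, tolerance = 1e-12)
    expect_equal(hypergeom_tail(ks[1], n, K, N), 1, tolerance = 1e-12)
    # tail dominates point everywhere
    for (k in ks) {
      expect_gte(hypergeom_tail(k, n, K, N) + 1e-15,
                 hypergeom_point(k, n, K, N))
    }
  }
})

test_that("cluster enrichment reports planted categories with exact stats", {
  background <- sprintf("g%03d", 1:200)
  clusters <- rep(1:10, each = 20)
  assignments <- data.frame(strain_id = background, cluster = clusters,
                            stringsAsFactors = FALSE)
  catalog <- category_catalog(
    list(planted = background[1:10],    # entirely inside cluster 1
         absent_elsewhere = background[21:24]),
    background)
  res <- cluster_enrichment(assignments, catalog)
  planted <- res[res$category == "planted", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$fold, 10)
  expect_equal(planted$p_tail,
               hyper_point_comb(10, 20, 10, 200), tolerance = 1e-12)
  # categories with k = 0 in a cluster do not appear for that cluster
  expect_false(any(res$category == "absent_elsewhere" & res$cluster != 2))
  expect_true(all(res$k >= 1))
  expect_true(!is.unsorted(res$p_point))
})

test_that("assignments outside the background are rejected by name", {
  catalog <- category_catalog(list(cat = c("a", "b")), c("a", "b", "c"))
  bad <- data.frame(strain_id = c("a", "zzz"), cluster = c(1, 1))
  expect_error(cluster_enrichment(bad, catalog), "zzz")
  expect_error(category_catalog(list(cat = c("a", "q")), c("a", "b")), "q")
})

test_that("catalogs round-trip through two-column and GMT formats", {
  tmp <- withr::local_tempdir()
  two_col <- file.path(tmp, "catalog.csv")
  writeLines(c("category,gene_id", "SAGA,spt20", "SAGA,gcn5", "RITS,ago1"),
             two_col)
  bg <- file.path(tmp, "background.txt")
  writeLines(c("spt20", "gcn5", "ago1", "other1", "other2"), bg)
  cat1 <- read_catalog(two_col, bg)
  expect_equal(sort(names(cat1$categories)), c("RITS", "SAGA"))
  expect_equal(sort(cat1$categories$SAGA), c("gcn5", "spt20"))
  expect_length(cat1$background, 5)

  gmt <- file.path(tmp, "catalog.gmt")
  writeLines(c("SAGA\tdesc\tspt20\tgcn5", "RITS\tdesc\tago1"), gmt)
  cat2 <- read_catalog(gmt, bg)
  expect_equal(cat2$categories$SAGA, cat1$categories$SAGA)
})
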