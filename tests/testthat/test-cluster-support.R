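test_that("ward.D2 merges match a brute-force Lance-Williams oracle", {
  # 1-D points: topology {(A,B), (C,D)} then root
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  hc <- ward_cluster(x)
  orc <- oracle_ward2(x)
  expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-10)
  sets <- teisig:::hclust_leaf_sets(hc)
  keys <- vapply(sets, paste, "", collapse = ",")
  expect_true(all(c("1,2", "3,4") %in% keys))

  # generic 2-D data, heights and leaf sets identical
  set.seed(8)
  y <- matrix(rnorm(14 * 3), 14, 3)
  hc2 <- ward_cluster(y)
  orc2 <- oracle_ward2(y)
  expect_equal(hc2$height, orc2$heights, tolerance = 1e-10)
  k1 <- sort(vapply(teisig:::hclust_leaf_sets(hc2), paste, "",
                    collapse = ","))
  k2 <- sort(vapply(orc2$sets, paste, "", collapse = ","))
  expect_identical(k1, k2)
})

test_that("identical items merge at height zero and trees are permutation-stable", {
  x <- rbind(c(1, 2), c(1, 2), c(5, 9))
  hc <- ward_cluster(x)
  expect_equal(min(hc$height), 0)

  set.seed(9)
  y <- matrix(rnorm(12 * 4), 12, 4)
  rownames(y) <- paste0("item", 1:12)
  perm <- sample(12)
  keys_of <- function(m) {
    hc <- ward_cluster(m)
    sort(vapply(teisig:::hclust_leaf_sets(hc), function(s)
      paste(sort(rownames(m)[s]), collapse = ","), ""))
  }
  expect_identical(keys_of(y), keys_of(y[perm, ]))
  expect_error(ward_cluster(rbind(c(1, NA), c(2, 3))), "missing")
})

planted_two_clusters <- function(n_per = 10, p = 50, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  rownames(x) <- paste0(rep(c("a", "b"), each = n_per), seq_len(n_per))
  x
}

test_that("planted clusters receive high AU support and the root is certain", {
  x <- planted_two_clusters(seed = 42)
  cs <- multiscale_bootstrap(x, bootstrap_config(nboot = 500, seed = 7))
  root <- cs$nodes[nrow(cs$nodes), ]
  expect_equal(root$bp, 1)
  expect_equal(root$au, 1)

  key1 <- paste(1:10, collapse = ",")
  key2 <- paste(11:20, collapse = ",")
  main <- cs$nodes[cs$nodes$members %in% c(key1, key2), ]
  expect_equal(nrow(main), 2L)
  expect_true(all(main$au >= 0.95))
  expect_true(all(main$bp >= 0.95))
})

test_that("full cluster support is bit-for-bit reproducible under a fixed seed", {
  x <- planted_two_clusters(n_per = 5, p = 20, sep = 3, seed = 5)
  a <- multiscale_bootstrap(x, bootstrap_config(nboot = 200, seed = 11))
  b <- multiscale_bootstrap(x, bootstrap_config(nboot = 200, seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$nodes, b$nodes)
})

test_that("BP at scale 1 agrees with a direct-count bootstrap oracle", {
  x <- planted_two_clusters(n_per = 5, p = 30, sep = 2.5, seed = 6)
  B <- 200
  cs <- multiscale_bootstrap(x, bootstrap_config(scales = c(0.8, 1, 1.2),
                                                 nboot = 3 * B, seed = 3))
  # pick a non-trivial internal node
  nd <- cs$nodes[cs$nodes$size > 2 & cs$nodes$size < 10, ][1, ]
  leaf <- as.integer(strsplit(nd$members, ",")[[1]])
  bp_o <- oracle_bp1(x, leaf, B = B, seed = 99)
  mc <- 2 * sqrt(bp_o * (1 - bp_o) / B) + 2 * sqrt(nd$bp * (1 - nd$bp) / B)
  expect_lt(abs(nd$bp - bp_o), max(mc, 0.02))
})

test_that("z-curve extrapolation reduces to BP in the flat-curve limit", {
  scales <- seq(0.5, 1.4, by = 0.1)
  fit <- teisig:::au_zcurve(rep(50, 10), B = 100, scales = scales)
  expect_equal(fit$au, 0.5, tolerance = 0.02)
  expect_lt(abs(fit$c), 0.2)

  # saturated counts: no curve, certainty reported directly
  expect_equal(teisig:::au_zcurve(rep(100, 10), 100, scales)$au, 1)
  expect_equal(teisig:::au_zcurve(rep(0, 10), 100, scales)$au, 0)
})

test_that("cluster support under two scales reports BP but no AU", {
  x <- planted_two_clusters(n_per = 4, p = 10, sep = 4, seed = 2)
  expect_warning(
    cs <- multiscale_bootstrap(x, bootstrap_config(scales = c(0.8, 1),
                                                   nboot = 100, seed = 1)),
    "3 scales")
  inner <- cs$nodes[-nrow(cs$nodes), ]
  expect_true(all(is.na(inner$au)))
  expect_true(all(!is.na(inner$bp)))
})

test_that("support-annotated trees export to newick with AU node labels", {
  x <- planted_two_clusters(n_per = 4, p = 20, sep = 6, seed = 4)
  cs <- multiscale_bootstrap(x, bootstrap_config(nboot = 200, seed = 2))
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cs, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(x))
  expect_true(any(phy$node.label == "1.000"))
})
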