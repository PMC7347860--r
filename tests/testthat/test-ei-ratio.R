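tei_table <- function(asum, gsum) {
  panels <- default_panels()
  a_genes <- panels$AMPAR$genes
  g_genes <- panels$GABAAR$genes
  n <- length(asum)
  vals <- cbind(outer(asum, rep(1 / 4, 4)),
                outer(gsum, rep(1 / 19, 19)))
  colnames(vals) <- c(a_genes, g_genes)
  fm <- data.frame(feature_id = colnames(vals),
                   gene_symbol = colnames(vals))
  sm <- data.frame(sample_id = paste0("s", seq_len(n)))
  rownames(vals) <- sm$sample_id
  expression_table(vals, "linear", fm, sm)
}

test_that("tE/I is the ratio of panel sums, scale-invariant and swap-equivariant", {
  tab <- tei_table(c(10, 20, 30), c(10, 10, 60))
  rec <- compute_tei(tab)
  expect_equal(rec$tei, c(1, 2, 0.5))
  expect_equal(rec$sum_ampar, c(10, 20, 30), tolerance = 1e-12)

  # global rescaling leaves the ratio unchanged
  tab_k <- tab; tab_k$values <- tab_k$values * 4.2
  expect_equal(compute_tei(tab_k)$tei, rec$tei, tolerance = 1e-12)

  # swapping panels maps tei -> 1/tei exactly
  panels <- default_panels()
  swapped <- list(AMPAR = panels$GABAAR, GABAAR = panels$AMPAR)
  expect_equal(compute_tei(tab, swapped)$tei, 1 / rec$tei,
               tolerance = 1e-12)

  # zero inhibitory sum: missing ratio with warning
  tab0 <- tei_table(c(5, 5), c(10, 0))
  expect_warning(r0 <- compute_tei(tab0), "zero")
  expect_true(is.na(r0$tei[2]))
})

test_that("per-type tE/I means recover the configured single-cell truth", {
  gen <- gen_single_cell(cell_sim_config(seed = 12))
  rec <- compute_tei(gen$table)
  summ <- ei_group_summary(rec, "cell_type")
  truth <- gen$truth$type_tei[summ$group]
  expect_true(all(abs(summ$mean - truth) <= 3 * summ$sem))
  expect_true(all(c("n", "mean", "sd", "sem") %in% names(summ)))
})

test_that("total-vs-total regression recovers constructed slopes", {
  # exactly collinear sums: r = 1, slope equals construction
  g <- seq(100, 200, length.out = 20)
  tab <- tei_table(3 * g, g)
  rec <- compute_tei(tab)
  fit <- regress_totals(rec)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 3, tolerance = 1e-10)

  # noisy per-group slopes recovered within 10% at n = 200/group
  set.seed(33)
  slopes <- c(s1 = 0.5, s2 = 1, s3 = 2)
  recs <- do.call(rbind, lapply(names(slopes), function(gr) {
    gs <- runif(200, 100, 300)
    as <- slopes[[gr]] * gs + rnorm(200, 0, 10)
    data.frame(group = gr, sum_ampar = as, sum_gabaar = gs)
  }))
  fits <- regress_totals(recs, "group")
  expect_equal(fits$slope, unname(slopes), tolerance = 0.1)
  expect_true(all(fits$p_value < 0.001))
})

test_that("Welch comparisons match the textbook formulas exactly", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9)
  rec <- data.frame(group = rep(c("x", "y"), c(length(a), length(b))),
                    tei = c(a, b))
  out <- compare_groups(rec, "group", "welch_two_sample")
  orc <- oracle_welch(a, b)
  expect_equal(out$t, orc$t, tolerance = 1e-10)
  expect_equal(out$df, orc$df, tolerance = 1e-10)
  expect_equal(out$p_value, orc$p, tolerance = 1e-10)

  # identical samples in both groups: t = 0, p = 1
  same <- data.frame(group = rep(c("x", "y"), each = 4),
                     tei = rep(c(1, 2, 3, 4), 2))
  out2 <- compare_groups(same, "group", "welch_two_sample")
  expect_equal(out2$t, 0)
  expect_equal(out2$p_value, 1)

  single <- data.frame(group = c("x", "x", "y"), tei = c(1, 2, 3))
  expect_error(compare_groups(single, "group"), "y")
})

test_that("Tukey-Kramer pairwise p-values match the studentized-range oracle", {
  set.seed(14)
  rec <- data.frame(group = rep(c("g1", "g2", "g3"), c(8, 12, 10)),
                    tei = c(rnorm(8, 1), rnorm(12, 1.5), rnorm(10, 4)))
  out <- compare_groups(rec, "group", "anova_tukey_kramer")
  orc <- oracle_tukey(rec$tei, rec$group)
  expect_equal(out$pairwise$p_adj, orc$p_adj, tolerance = 1e-10)
  expect_lt(out$omnibus$p_value, 0.01)
})

test_that("transporter ratios follow their closed forms", {
  genes <- c("SLC12A5", "SLC12A2", "SLC12A1")
  vals <- matrix(c(4, 4, 7, 8, 2, 0, 3, 0, 9), nrow = 3,
                 dimnames = list(NULL, genes))
  fm <- data.frame(feature_id = genes, gene_symbol = genes)
  sm <- data.frame(sample_id = paste0("s", 1:3))
  rownames(vals) <- sm$sample_id
  tab <- expression_table(vals, "linear", fm, sm)
  tr <- transporter_ratios(tab)
  expect_equal(tr$kcc2_nkcc1, c(4 / 8, 4 / 2, NA))

  # missing KCC2 gene: ratio missing throughout
  tab2 <- subset_table(tab, features = 2:3)
  tr2 <- transporter_ratios(tab2)
  expect_true(all(is.na(tr2$kcc2_nkcc1)))
})

test_that("trend fitting reproduces smooth truths and the pre/postnatal split", {
  # constant input -> constant curve
  suppressWarnings(ft <- fit_trend(rep(2, 10), seq(-0.5, 4, length.out = 10)))
  expect_equal(ft$grid$fitted, rep(2, nrow(ft$grid)), tolerance = 1e-6)

  # noiseless quadratic within 1e-3 RMS
  age <- seq(-0.5, 3, length.out = 60)
  y <- 1 + 0.5 * age - 0.2 * age^2
  ft2 <- fit_trend(y, age)
  truth <- 1 + 0.5 * ft2$grid$age - 0.2 * ft2$grid$age^2
  rms <- sqrt(mean((ft2$grid$fitted - truth)^2))
  expect_lt(rms, 1e-3)

  expect_error(fit_trend(c(1, 2), c(0, 1)), "points")

  # planted prenatal-only association between tE/I and KCC2/NKCC1
  gen <- gen_developmental(dev_sim_config(seed = 8))
  rec <- compute_tei(gen$table)
  tr <- transporter_ratios(gen$table)
  pp <- pre_post_correlation(rec$tei, tr$kcc2_nkcc1, rec$age)
  expect_lt(pp$r[pp$period == "prenatal"], -0.7)
  expect_lt(pp$p_value[pp$period == "prenatal"], 0.05)
  expect_gt(pp$p_value[pp$period == "postnatal"], 0.05)
})
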