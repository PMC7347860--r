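make_gene_table <- function(vals, meta_extra = NULL, scale = "log2") {
  fm <- data.frame(feature_id = colnames(vals),
                   gene_symbol = colnames(vals))
  sm <- data.frame(sample_id = rownames(vals) %||%
                     paste0("s", seq_len(nrow(vals))))
  if (!is.null(meta_extra)) sm <- cbind(sm, meta_extra)
  rownames(vals) <- sm$sample_id
  expression_table(vals, scale, fm, sm)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("age adjustment removes injected slopes and is idempotent", {
  # zero slope (noise-free, balanced design): adjusted values equal input
  cfg0 <- regional_sim_config(beta_age = 0, sigma = 0, subject_sd = 0,
                              seed = 31)
  gen0 <- gen_regional_microarray(cfg0)
  adj0 <- adjust_age(gen0$table)
  expect_equal(adj0$values, gen0$table$values, tolerance = 1e-8)

  # injected slope 0.05 log2/yr at ~600 samples: residual age correlation
  # collapses
  cfg <- regional_sim_config(beta_age = 0.05, n_subjects = 30, seed = 32)
  gen <- gen_regional_microarray(cfg)
  adj <- adjust_age(gen$table)
  age <- adj$sample_meta$age
  rs <- apply(adj$values, 2L, function(z) stats::cor(z, age))
  expect_lt(max(abs(rs)), 0.05)
  fit <- attr(adj, "age_fit")
  expect_lt(abs(mean(fit$slope) - 0.05), 0.01)

  # idempotence
  adj2 <- adjust_age(adj)
  expect_equal(adj2$values, adj$values, tolerance = 1e-10)
})

test_that("age adjustment passes through degenerate designs with a warning", {
  vals <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  tab <- make_gene_table(vals, data.frame(age = rep(30, 4)))
  expect_warning(out <- adjust_age(tab), "distinct ages")
  expect_equal(out$values, tab$values)
})

test_that("proportional contributions match hand arithmetic and sum to 100", {
  # log2 means (10, 11, 9, 10) -> linear (1024, 2048, 512, 1024)
  vals <- matrix(rep(c(10, 11, 9, 10), each = 6), nrow = 6,
                 dimnames = list(NULL, c("GRIA1", "GRIA2", "GRIA3", "GRIA4")))
  tab <- make_gene_table(vals)
  pc <- proportional_contribution(tab, default_panels()$AMPAR)
  expect_equal(pc$percent, 100 * c(1024, 2048, 512, 1024) / 4608,
               tolerance = 1e-9)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)

  # equal linear means -> 25% each; invariant to global rescaling
  lin <- matrix(7, 5, 4, dimnames = list(NULL, colnames(vals)))
  tab2 <- make_gene_table(lin, scale = "linear")
  pc2 <- proportional_contribution(tab2, default_panels()$AMPAR)
  expect_equal(pc2$percent, rep(25, 4))
  tab3 <- make_gene_table(lin * 13.7, scale = "linear")
  pc3 <- proportional_contribution(tab3, default_panels()$AMPAR)
  expect_equal(pc3$percent, pc2$percent, tolerance = 1e-12)
})

test_that("fold enrichment is a linear ratio of exponentiated log2 means", {
  sub <- rep(c("CA4", "other1", "other2", "other3"), each = 3)
  base <- matrix(8, 12, 1, dimnames = list(NULL, "GRIA1"))
  # CA4 log2 mean = global mean + log2(10) => fold 10 requires solving:
  # with x on CA4 rows and 8 elsewhere, fold = 2^x / 2^((3x + 72)/12);
  # x = 8 + (4/3) * log2(10) gives exactly fold 10
  x <- 8 + (4 / 3) * log2(10)
  base[sub == "CA4", 1] <- x
  tab <- make_gene_table(base, data.frame(structure = "HiF",
                                          substructure = sub))
  fe <- fold_enrichment(tab, gene_panel("A", "GRIA1"))
  expect_equal(fe$fold[fe$substructure == "CA4"], 10, tolerance = 1e-9)
  expect_equal(attr(fe, "top")$substructure, "CA4")

  # a level at the global mean has fold 1
  flat <- make_gene_table(matrix(5, 8, 1, dimnames = list(NULL, "GRIA1")),
                          data.frame(structure = "S",
                                     substructure = rep(c("a", "b"), 4)))
  fe2 <- fold_enrichment(flat, gene_panel("A", "GRIA1"))
  expect_equal(fe2$fold, c(1, 1))
})

test_that("five-number summaries follow type-7 quantiles and flag outliers", {
  vals <- matrix(1:9, 9, 1, dimnames = list(NULL, "GRIA1"))
  tab <- make_gene_table(vals)
  d <- describe_expression(tab, gene_panel("A", "GRIA1"))
  expect_equal(d$median, 5)
  expect_equal(d$q1, 3)
  expect_equal(d$q3, 7)
  expect_equal(nrow(attr(d, "outliers")), 0L)

  # constant vector: IQR 0, no outliers
  dc <- describe_expression(
    make_gene_table(matrix(4, 6, 1, dimnames = list(NULL, "GRIA1"))),
    gene_panel("A", "GRIA1"))
  expect_equal(dc$q3 - dc$q1, 0)
  expect_equal(nrow(attr(dc, "outliers")), 0L)

  # adding a far point flags it
  vals2 <- matrix(c(1:9, 100), 10, 1, dimnames = list(NULL, "GRIA1"))
  d2 <- describe_expression(make_gene_table(vals2), gene_panel("A", "GRIA1"))
  out <- attr(d2, "outliers")
  expect_equal(out$value, 100)
  expect_lte(d2$whisker_high, max(1:9))
})

nested_fixture <- function(n_struct = 3, n_sub = 4, n_rep = 6,
                           effect = 0, seed = 1) {
  set.seed(seed)
  meta <- expand.grid(rep = seq_len(n_rep),
                      substructure = paste0("b", seq_len(n_sub)),
                      structure = paste0("a", seq_len(n_struct)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$substructure <- paste(meta$structure, meta$substructure, sep = ".")
  y <- rnorm(nrow(meta)) +
    effect * as.integer(factor(meta$structure)) +
    effect * 0.5 * as.integer(factor(meta$substructure))
  vals <- matrix(y, ncol = 1, dimnames = list(NULL, "GRIA1"))
  make_gene_table(vals, meta[c("structure", "substructure")])
}

test_that("nested ANOVA matches the sequential-SS oracle and is additive", {
  tab <- nested_fixture(effect = 0.8, seed = 7)
  res <- nested_anova(tab, "GRIA1")

  y <- tab$values[, 1]
  A <- factor(tab$sample_meta$structure)
  B <- factor(tab$sample_meta$substructure)
  an <- stats::anova(stats::lm(y ~ A / B))
  expect_equal(res$ss, an$`Sum Sq`, tolerance = 1e-10)
  expect_equal(res$df, an$Df)

  # SS additivity
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(sum(res$ss), ss_tot, tolerance = 1e-8 * ss_tot)

  # F ratios per the nested decomposition
  expect_equal(res$f[1], res$ms[1] / res$ms[2], tolerance = 1e-12)
  expect_equal(res$f[2], res$ms[2] / res$ms[3], tolerance = 1e-12)
})

test_that("nested ANOVA handles flat data and saturated designs", {
  tab <- nested_fixture(seed = 3)
  tab$values[, 1] <- 5  # all cell means equal, zero error
  res <- nested_anova(tab, "GRIA1")
  expect_equal(res$ss[1:2], c(0, 0))

  sat <- nested_fixture(n_rep = 1, seed = 4)
  expect_error(nested_anova(sat, "GRIA1"), "saturated")
})
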