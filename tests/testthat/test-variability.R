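test_that("pairwise subunit distances follow the fixed pair order", {
  d <- subunit_distance_vector(c(GRIA1 = 1, GRIA2 = 2, GRIA3 = 4,
                                 GRIA4 = 8))
  expect_equal(unname(d), c(1, 3, 7, 2, 6, 4))
  expect_equal(names(d)[1:3], c("GRIA1-GRIA2", "GRIA1-GRIA3",
                                "GRIA1-GRIA4"))

  expect_equal(unname(subunit_distance_vector(c(a = 3, b = 3, c = 3))),
               c(0, 0, 0))
  # translation invariance
  x <- c(a = 1.2, b = 5.1, c = 0.4, d = 9)
  expect_equal(subunit_distance_vector(x), subunit_distance_vector(x + 17))
  # matrix units reduce to the scalar case for one row
  m <- matrix(c(1, 2, 4, 8), 1, dimnames = list(NULL, names(x)))
  expect_equal(unname(subunit_distance_vector(m)), c(1, 3, 7, 2, 6, 4))
  expect_error(subunit_distance_vector(c(a = 1)), ">= 2 genes")
})

test_that("consensus modes agree with their closed forms", {
  dmat <- rbind(u1 = c(1, 2, 3), u2 = c(3, 2, 1))
  expect_equal(consensus_distances(dmat), c(2, 2, 2))
  expect_equal(consensus_distances(dmat, "pooled_eq2"),
               sqrt(c(10, 8, 10)))
  # single unit: consensus equals that unit
  expect_equal(consensus_distances(dmat[1, , drop = FALSE]), c(1, 2, 3))
  # identical units: consensus equals the common vector
  same <- rbind(c(4, 5, 6), c(4, 5, 6))
  expect_equal(consensus_distances(same), c(4, 5, 6))
  expect_error(consensus_distances(dmat[0, , drop = FALSE]), "no units")
})

test_that("consensus correlations are exact on constructed vectors", {
  cons <- c(1, 2, 3, 4, 5, 6)
  dmat <- rbind(same = cons, anti = rev(cons), scaled = 2 * cons)
  res <- correlate_to_consensus(dmat, cons)
  r <- res$units$r
  # hand-arithmetic oracle for the anti-ordered vector
  r_anti <- sum((cons - 3.5) * (rev(cons) - 3.5)) /
    sqrt(sum((cons - 3.5)^2) * sum((rev(cons) - 3.5)^2))
  expect_equal(r[1], 1)
  expect_equal(r[2], r_anti, tolerance = 1e-12)
  expect_equal(r[3], 1)

  expect_warning(
    res0 <- correlate_to_consensus(rbind(flat = rep(2, 6)), cons),
    "zero-variance")
  expect_true(is.na(res0$units$r))
})

test_that("R is invariant to global positive rescaling of expression", {
  gen <- gen_regional_microarray(regional_sim_config(seed = 41))
  sel <- select_representative_probes(gen$table)
  tab <- sel$table
  dmat <- distance_vectors(tab, default_panels()$AMPAR,
                           c("subject_id", "substructure"))
  cons <- consensus_distances(dmat)
  r1 <- correlate_to_consensus(dmat, cons)$units$r

  tab2 <- tab
  tab2$values <- tab2$values * 3.7  # distances scale by 3.7
  dmat2 <- distance_vectors(tab2, default_panels()$AMPAR,
                            c("subject_id", "substructure"))
  r2 <- correlate_to_consensus(dmat2, consensus_distances(dmat2))$units$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("higher subject-effect variance lowers the consensus correlation", {
  mean_r_at <- function(subject_sd, seed) {
    cfg <- regional_sim_config(subject_sd = subject_sd, seed = seed)
    gen <- gen_regional_microarray(cfg)
    sel <- select_representative_probes(gen$table)
    dmat <- distance_vectors(sel$table, default_panels()$AMPAR,
                             c("subject_id", "substructure"))
    cons <- consensus_distances(dmat)
    res <- correlate_to_consensus(
      dmat, cons, group = attr(dmat, "units")$substructure)
    mean(res$summary$mean_r)
  }
  rs <- vapply(c(0.1, 1, 3), mean_r_at, 1, seed = 17)
  expect_true(all(diff(rs) < 0))
})

test_that("per-structure summaries expose mean and SD of R across subjects", {
  gen <- gen_regional_microarray(regional_sim_config(seed = 19))
  sel <- select_representative_probes(gen$table)
  dmat <- distance_vectors(sel$table, default_panels()$AMPAR,
                           c("subject_id", "substructure"))
  cons <- consensus_distances(dmat)
  res <- correlate_to_consensus(dmat, cons,
                                group = attr(dmat, "units")$substructure)
  expect_true(all(c("group", "mean_r", "sd_r", "n") %in%
                    names(res$summary)))
  expect_equal(unique(res$summary$n), 6L)
  expect_true(all(res$units$r >= -1 & res$units$r <= 1, na.rm = TRUE))
})
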