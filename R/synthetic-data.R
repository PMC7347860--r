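#' Synthetic regional microarray configuration
#'
#' Describes a regional log2 microarray simulation with the statistical
#' structure the downstream analysis assumes: several collinear probes per
#' gene generated by a single-factor model, substructure mean profiles that
#' cluster by ontogeny, an additive per-subject-and-gene offset shared
#' across regions (the source of the inter-individual variability the
#' distance-vector analysis quantifies), and optional linear age effects.
#'
#' The default emulates the anatomy of a whole-brain survey: two ontogeny
#' groups (telencephalic vs metencephalic), 2 regions x 2 structures x 5
#' substructures = 20 substructures, 6 subjects aged 24-57 years, and the
#' 17-probe AMPAR design (4 probes each for GRIA1-3, 5 for GRIA4) plus one
#' probe per GABA-A receptor subunit gene. The telencephalic profile is
#' GRIA2-high; the metencephalic profile is GRIA3-low with high GRIA2/4.
#'
#' Probe `j` of gene `g` in sample `s` is generated as
#' `lambda_j * F_gs + sqrt(1 - lambda_j^2) * eps + beta_age * age_s`, with
#' `F_gs` the substructure profile plus the subject offset and
#' `eps ~ N(0, sigma)`. The true representative probe of each gene is the
#' probe with maximal loading `lambda`.
#'
#' @param regions data.frame with columns `region`, `structure`,
#'   `substructure`, `ontogeny`
#' @param profiles genes x substructures matrix of mean log2 expression
#' @param probe_plan named list: per gene, a numeric vector of probe
#'   loadings in (0, 1] (its length is the probe count)
#' @param n_subjects number of subjects (>= 2)
#' @param age_range length-2 numeric, subject ages drawn uniformly (years)
#' @param beta_age per-gene age slope (log2 units / year); scalar or named
#'   vector
#' @param sigma probe noise SD (log2 units, >= 0)
#' @param subject_sd SD of the additive per-subject offset (log2 units)
#' @param seed RNG seed
#' @return a `regional_sim_config` list
#' @export
regional_sim_config <- function(regions = NULL, profiles = NULL,
                                probe_plan = NULL, n_subjects = 6,
                                age_range = c(24, 57), beta_age = 0,
                                sigma = 0.5, subject_sd = 0.3, seed = 1L) {
  if (is.null(regions)) {
    mk <- function(region, structure, ontogeny, k = 5)
      data.frame(region = region, structure = structure,
                 substructure = paste0(structure, "_s", seq_len(k)),
                 ontogeny = ontogeny, stringsAsFactors = FALSE)
    regions <- rbind(
      mk("telencephalon", "cerebral_cortex", "telencephalic"),
      mk("telencephalon", "hippocampal_formation", "telencephalic"),
      mk("metencephalon", "cerebellar_cortex", "metencephalic"),
      mk("metencephalon", "pons", "metencephalic")
    )
  }
  if (is.null(probe_plan)) {
    probe_plan <- list(GRIA1 = c(0.95, 0.85, 0.75, 0.65),
                       GRIA2 = c(0.95, 0.85, 0.75, 0.65),
                       GRIA3 = c(0.95, 0.85, 0.75, 0.65),
                       GRIA4 = c(0.95, 0.85, 0.75, 0.65, 0.55))
    for (g in default_panels()$GABAAR$genes) probe_plan[[g]] <- 1
  }
  genes <- names(probe_plan)
  if (is.null(profiles)) {
    base <- c(GRIA1 = 8, GRIA2 = 10, GRIA3 = 8, GRIA4 = 9)
    meten <- c(GRIA1 = 8, GRIA2 = 10.5, GRIA3 = 3.5, GRIA4 = 10)
    profiles <- matrix(7, nrow = length(genes), ncol = nrow(regions),
                       dimnames = list(genes, regions$substructure))
    for (g in intersect(genes, names(base))) {
      profiles[g, ] <- ifelse(regions$ontogeny == "metencephalic",
                              meten[[g]], base[[g]])
    }
    # deterministic within-structure gradients so substructures separate
    for (st in unique(regions$structure)) {
      idx <- which(regions$structure == st)
      step <- seq(-0.8, 0.8, length.out = length(idx))
      profiles[, idx] <- sweep(profiles[, idx, drop = FALSE], 2, step, "+")
    }
    # hippocampal-formation-like GRIA1 enrichment
    hip <- grep("hippocampal", regions$structure)
    if (length(hip) && "GRIA1" %in% genes)
      profiles["GRIA1", hip] <- profiles["GRIA1", hip] + 2
  }
  cfg <- list(regions = regions, profiles = profiles,
              probe_plan = probe_plan, n_subjects = n_subjects,
              age_range = age_range, beta_age = beta_age, sigma = sigma,
              subject_sd = subject_sd, seed = as.integer(seed))
  validate_regional_cfg(cfg)
  class(cfg) <- "regional_sim_config"
  cfg
}

validate_regional_cfg <- function(cfg) {
  if (nrow(cfg$regions) == 0L) stop("degenerate config: no regions")
  if (length(cfg$probe_plan) == 0L) stop("degenerate config: no probes")
  lam <- unlist(cfg$probe_plan)
  if (any(lam <= 0 | lam > 1)) stop("probe loadings must lie in (0, 1]")
  if (cfg$sigma < 0) stop("sigma must be >= 0")
  if (cfg$n_subjects < 2) stop("need n_subjects >= 2")
  if (!setequal(rownames(cfg$profiles), names(cfg$probe_plan)))
    stop("profiles rows must match probe_plan genes")
  invisible(TRUE)
}

#' Generate a synthetic regional microarray dataset
#'
#' A pure function of (config, seed): identical configs give identical
#' tables. Returns the log2 probe-level expression table, its sample
#' metadata and the ground truth needed by recovery tests (true profiles,
#' true representative probe per gene, true ontogeny partition, subject
#' offsets, age slopes).
#'
#' @param cfg a [regional_sim_config()]
#' @return list with elements `table` (log2 `expression_table`) and
#'   `truth`
#' @export
gen_regional_microarray <- function(cfg) {
  stopifnot(inherits(cfg, "regional_sim_config"))
  validate_regional_cfg(cfg)
  set.seed(cfg$seed)
  genes <- names(cfg$probe_plan)
  reg <- cfg$regions
  nsub <- cfg$n_subjects
  subjects <- sprintf("subj%02d", seq_len(nsub))
  ages <- stats::runif(nsub, cfg$age_range[1], cfg$age_range[2])
  sexes <- sample(c("M", "F"), nsub, replace = TRUE)
  # per-subject, per-gene offsets, shared across all regions of a subject:
  # the source of inter-individual variability in subunit organization
  offsets <- matrix(stats::rnorm(nsub * length(genes), 0, cfg$subject_sd),
                    nsub, length(genes),
                    dimnames = list(subjects, genes))

  beta <- cfg$beta_age
  if (length(beta) == 1L && is.null(names(beta)))
    beta <- stats::setNames(rep(beta, length(genes)), genes)

  grid <- expand.grid(subject = seq_len(nsub), sub = seq_len(nrow(reg)),
                      KEEP.OUT.ATTRS = FALSE)
  n_samples <- nrow(grid)
  probe_ids <- unlist(lapply(genes, function(g)
    paste0(g, "_p", seq_along(cfg$probe_plan[[g]]))))
  probe_gene <- rep(genes, vapply(cfg$probe_plan, length, 1L))
  lambda <- unlist(cfg$probe_plan, use.names = FALSE)

  vals <- matrix(NA_real_, n_samples, length(probe_ids))
  for (j in seq_along(probe_ids)) {
    g <- probe_gene[j]
    f <- cfg$profiles[g, grid$sub] + offsets[cbind(grid$subject, match(g, genes))]
    eps <- stats::rnorm(n_samples, 0, cfg$sigma)
    vals[, j] <- lambda[j] * f + sqrt(1 - lambda[j]^2) * eps +
      beta[[g]] * ages[grid$subject]
  }
  sm <- data.frame(
    sample_id = paste0(subjects[grid$subject], "_", reg$substructure[grid$sub]),
    subject_id = subjects[grid$subject],
    age = ages[grid$subject],
    sex = sexes[grid$subject],
    region = reg$region[grid$sub],
    structure = reg$structure[grid$sub],
    substructure = reg$substructure[grid$sub],
    stringsAsFactors = FALSE
  )
  rownames(vals) <- sm$sample_id
  fm <- data.frame(feature_id = probe_ids, gene_symbol = probe_gene,
                   stringsAsFactors = FALSE)
  tab <- expression_table(vals, "log2", fm, sm)

  true_probe <- vapply(genes, function(g) {
    lam <- cfg$probe_plan[[g]]
    paste0(g, "_p", which.max(lam))
  }, character(1))
  truth <- list(
    profiles = cfg$profiles,
    partition = stats::setNames(reg$ontogeny, reg$substructure),
    true_probe = true_probe,
    beta_age = beta,
    subject_offsets = offsets,
    ages = stats::setNames(ages, subjects)
  )
  list(table = tab, truth = truth)
}

#' Synthetic single-cell configuration
#'
#' Emulates a normalized (uTPM-style) single-cell dataset of phenotyped
#' GABAergic interneuron types with type-specific transcriptional E/I
#' ratios. Defaults are seven cortical interneuron types with tE/I means
#' and SDs of 0.66 +/- 0.13 (CCKC), 1.7 +/- 0.38 (CHC1), 1.0 +/- 0.43
#' (CHC2), 0.80 +/- 0.26 (ISC), 1.1 +/- 0.22 (LPC), 10 +/- 6.3 (MNC) and
#' 0.96 +/- 0.13 (PVBC) at cell counts 64, 80, 52, 63, 136, 62 and 127.
#'
#' Per cell, a total GABA-A receptor abundance is drawn lognormal and a
#' per-cell tE/I ratio is drawn lognormal with mean exactly `mu_tei` and
#' SD `dispersion`; the AMPAR total is their product, and both totals are
#' split across panel genes with fixed proportions, so the per-cell
#' ratio of sums equals the drawn tE/I exactly and its expectation is
#' `mu_tei`. `dispersion = 0` makes every cell's tE/I equal `mu_tei`.
#'
#' @param types data.frame with columns `cell_type`, `n_cells`, `mu_tei`
#'   (> 0), `dispersion` (>= 0)
#' @param gabaar_meanlog,gabaar_sdlog lognormal parameters of the per-cell
#'   total GABA-A receptor abundance
#' @param zero_inflation probability of zeroing an individual gene value
#'   (default 0; applied after ground truth is recorded)
#' @param seed RNG seed
#' @return a `cell_sim_config` list
#' @export
cell_sim_config <- function(types = NULL, gabaar_meanlog = log(100),
                            gabaar_sdlog = 0.4, zero_inflation = 0,
                            seed = 1L) {
  if (is.null(types)) {
    types <- data.frame(
      cell_type = c("CCKC", "CHC1", "CHC2", "ISC", "LPC", "MNC", "PVBC"),
      n_cells = c(64L, 80L, 52L, 63L, 136L, 62L, 127L),
      mu_tei = c(0.66, 1.7, 1.0, 0.80, 1.1, 10, 0.96),
      dispersion = c(0.13, 0.38, 0.43, 0.26, 0.22, 6.3, 0.13),
      stringsAsFactors = FALSE
    )
  }
  if (any(types$mu_tei <= 0)) stop("mu_tei must be > 0")
  if (any(types$n_cells < 2)) stop("need n_cells >= 2 per type")
  if (any(types$dispersion < 0)) stop("dispersion must be >= 0")
  structure(list(types = types, gabaar_meanlog = gabaar_meanlog,
                 gabaar_sdlog = gabaar_sdlog,
                 zero_inflation = zero_inflation, seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Generate a synthetic single-cell dataset
#'
#' @param cfg a [cell_sim_config()]
#' @return list with elements `table` (linear `expression_table`, cells as
#'   samples) and `truth` (per-type true tE/I means and the per-cell drawn
#'   ratios)
#' @export
gen_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "cell_sim_config"))
  set.seed(cfg$seed)
  panels <- default_panels()
  a_genes <- panels$AMPAR$genes
  g_genes <- panels$GABAAR$genes
  # fixed within-panel proportions (deterministic)
  a_prop <- c(0.2, 0.45, 0.1, 0.25)
  g_prop <- rep(1 / length(g_genes), length(g_genes))

  rows <- list(); meta <- list(); tei_cells <- list()
  for (i in seq_len(nrow(cfg$types))) {
    ty <- cfg$types[i, ]
    n <- ty$n_cells
    gtot <- stats::rlnorm(n, cfg$gabaar_meanlog, cfg$gabaar_sdlog)
    if (ty$dispersion > 0) {
      s2 <- log(1 + (ty$dispersion / ty$mu_tei)^2)
      tei <- ty$mu_tei * exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
    } else {
      tei <- rep(ty$mu_tei, n)
    }
    atot <- tei * gtot
    vals <- cbind(outer(atot, a_prop), outer(gtot, g_prop))
    rows[[i]] <- vals
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_c%03d", ty$cell_type, seq_len(n)),
      cell_type = ty$cell_type, stringsAsFactors = FALSE)
    tei_cells[[i]] <- tei
  }
  vals <- do.call(rbind, rows)
  sm <- do.call(rbind, meta)
  rownames(vals) <- sm$sample_id
  if (cfg$zero_inflation > 0) {
    z <- matrix(stats::runif(length(vals)) < cfg$zero_inflation,
                nrow(vals), ncol(vals))
    vals[z] <- 0
  }
  fm <- data.frame(feature_id = c(a_genes, g_genes),
                   gene_symbol = c(a_genes, g_genes),
                   stringsAsFactors = FALSE)
  tab <- expression_table(vals, "linear", fm, sm)
  truth <- list(
    type_tei = stats::setNames(cfg$types$mu_tei, cfg$types$cell_type),
    cell_tei = stats::setNames(unlist(tei_cells), sm$sample_id)
  )
  list(table = tab, truth = truth)
}

#' Synthetic developmental configuration
#'
#' Emulates a developmental (RPKM-style) cortical time course: total AMPAR
#' subunit expression stays constant at `ampar_level` while total GABA-A
#' receptor expression rises along a logistic curve, so the true tE/I
#' trajectory `A / logistic(t)` declines prenatally and plateaus after
#' birth. The default ceiling is `ampar_level / 0.31`, so the post-1-year
#' tE/I plateau sits at 0.31. KCC2 (SLC12A5) rises and NKCC1 (SLC12A2)
#' declines along logistic curves with midpoints near birth, planting a
#' negative prenatal association between tE/I and KCC2/NKCC1 and none
#' postnatally.
#'
#' Ages are in years with birth at 0; prenatal ages are negative (12
#' post-conception weeks is (12 - 40) * 7 / 365.25 = -0.537 y).
#'
#' @param ages numeric vector of subject ages (years); default spans 12
#'   post-conception weeks to 40 years
#' @param ampar_level constant total AMPAR expression `A` (> 0)
#' @param gabaar_floor,gabaar_ceiling,gabaar_midpoint,gabaar_rate logistic
#'   rise of total GABA-A receptor expression (ceiling > floor > 0,
#'   rate > 0); `gabaar_ceiling = NULL` sets it to `ampar_level / 0.31`
#' @param kcc2_floor,kcc2_ceiling,kcc2_midpoint,kcc2_rate logistic rise of
#'   KCC2 (SLC12A5)
#' @param nkcc1_high,nkcc1_low,nkcc1_midpoint,nkcc1_rate logistic decline
#'   of NKCC1 (SLC12A2)
#' @param noise_sd lognormal noise sdlog applied per gene (0 = noise-free)
#' @param seed RNG seed
#' @return a `dev_sim_config` list
#' @export
dev_sim_config <- function(ages = NULL, ampar_level = 100,
                           gabaar_floor = 60, gabaar_ceiling = NULL,
                           gabaar_midpoint = -0.2, gabaar_rate = 8,
                           kcc2_floor = 10, kcc2_ceiling = 100,
                           kcc2_midpoint = -0.2, kcc2_rate = 6,
                           nkcc1_high = 100, nkcc1_low = 30,
                           nkcc1_midpoint = -0.2, nkcc1_rate = 6,
                           noise_sd = 0.08, seed = 1L) {
  if (is.null(ages)) {
    pcw <- seq(12, 38, by = 2)
    ages <- c((pcw - 40) * 7 / 365.25,
              c(0.1, 0.25, 0.5, 0.75, 1, 2, 3, 4, 8, 11, 13, 15, 18, 21,
                25, 30, 36, 40))
  }
  if (is.null(gabaar_ceiling)) gabaar_ceiling <- ampar_level / 0.31
  if (!(gabaar_ceiling > gabaar_floor && gabaar_floor > 0))
    stop("need gabaar_ceiling > gabaar_floor > 0")
  if (gabaar_rate <= 0 || kcc2_rate <= 0 || nkcc1_rate <= 0)
    stop("logistic rates must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(ages = ages, ampar_level = ampar_level,
                 gabaar_floor = gabaar_floor, gabaar_ceiling = gabaar_ceiling,
                 gabaar_midpoint = gabaar_midpoint, gabaar_rate = gabaar_rate,
                 kcc2_floor = kcc2_floor, kcc2_ceiling = kcc2_ceiling,
                 kcc2_midpoint = kcc2_midpoint, kcc2_rate = kcc2_rate,
                 nkcc1_high = nkcc1_high, nkcc1_low = nkcc1_low,
                 nkcc1_midpoint = nkcc1_midpoint, nkcc1_rate = nkcc1_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dev_sim_config")
}

logistic_curve <- function(t, lo, hi, mid, rate)
  lo + (hi - lo) / (1 + exp(-rate * (t - mid)))

#' Generate a synthetic developmental dataset
#'
#' @param cfg a [dev_sim_config()]
#' @return list with elements `table` (linear `expression_table`, one
#'   sample per subject) and `truth` (data.frame of true per-age totals,
#'   tE/I and KCC2/NKCC1 ratios)
#' @export
gen_developmental <- function(cfg) {
  stopifnot(inherits(cfg, "dev_sim_config"))
  set.seed(cfg$seed)
  t <- cfg$ages
  n <- length(t)
  A <- rep(cfg$ampar_level, n)
  G <- logistic_curve(t, cfg$gabaar_floor, cfg$gabaar_ceiling,
                      cfg$gabaar_midpoint, cfg$gabaar_rate)
  kcc2 <- logistic_curve(t, cfg$kcc2_floor, cfg$kcc2_ceiling,
                         cfg$kcc2_midpoint, cfg$kcc2_rate)
  nkcc1 <- logistic_curve(t, cfg$nkcc1_high, cfg$nkcc1_low,
                          cfg$nkcc1_midpoint, cfg$nkcc1_rate)

  panels <- default_panels()
  a_genes <- panels$AMPAR$genes
  g_genes <- panels$GABAAR$genes
  a_prop <- c(0.2, 0.45, 0.1, 0.25)
  g_prop <- rep(1 / length(g_genes), length(g_genes))

  base <- cbind(outer(A, a_prop), outer(G, g_prop),
                SLC12A5 = kcc2, SLC12A2 = nkcc1, SLC12A1 = rep(15, n))
  if (cfg$noise_sd > 0) {
    s <- cfg$noise_sd
    noise <- matrix(exp(stats::rnorm(length(base), -s^2 / 2, s)),
                    nrow(base), ncol(base))
    base <- base * noise
  }
  genes <- c(a_genes, g_genes, "SLC12A5", "SLC12A2", "SLC12A1")
  sm <- data.frame(sample_id = sprintf("dev%02d", seq_len(n)),
                   subject_id = sprintf("dev%02d", seq_len(n)),
                   age = t, region = "cortex", stringsAsFactors = FALSE)
  rownames(base) <- sm$sample_id
  fm <- data.frame(feature_id = genes, gene_symbol = genes,
                   stringsAsFactors = FALSE)
  tab <- expression_table(base, "linear", fm, sm)
  truth <- data.frame(sample_id = sm$sample_id, age = t, ampar = A,
                      gabaar = G, tei = A / G, kcc2 = kcc2, nkcc1 = nkcc1,
                      kcc2_nkcc1 = kcc2 / nkcc1, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}
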