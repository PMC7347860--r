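#' Transcriptional E/I ratio per unit
#'
#' The tE/I ratio divides the summed expression of all AMPAR subunit genes
#' by the summed expression of all GABA-A receptor subunit genes, per
#' sample or per group of samples. Sums are taken on the linear scale by
#' default (log2 tables are exponentiated base 2 first); `sum_scale =
#' "log2"` sums the log2 values instead, as a sensitivity analysis.
#'
#' @param table an `expression_table`
#' @param panels list with `gene_panel` elements `AMPAR` and `GABAAR`
#'   (default [default_panels()])
#' @param group_by optional metadata keys: units become groups of samples
#'   (panel sums are averaged within the group before the ratio); `NULL`
#'   gives one record per sample
#' @param sum_scale `"linear"` (default) or `"log2"`
#' @param policy panel resolution policy (see [resolve_panel()])
#' @return data.frame of EI records: unit keys, `sum_ampar`,
#'   `sum_gabaar`, `tei` (missing where the GABA-A receptor sum is zero)
#' @export
compute_tei <- function(table, panels = default_panels(), group_by = NULL,
                        sum_scale = c("linear", "log2"),
                        policy = c("strict", "subset")) {
  sum_scale <- match.arg(sum_scale)
  policy <- match.arg(policy)
  ai <- resolve_panel(table, panels$AMPAR, policy)
  gi <- resolve_panel(table, panels$GABAAR, policy)
  if (length(ai) == 0L || length(gi) == 0L)
    stop("panels resolve to no features")
  v <- if (sum_scale == "linear") linear_values(table) else table$values
  sa <- rowSums(v[, ai, drop = FALSE])
  sg <- rowSums(v[, gi, drop = FALSE])
  if (is.null(group_by)) {
    rec <- cbind(table$sample_meta,
                 data.frame(sum_ampar = sa, sum_gabaar = sg))
  } else {
    key <- group_keys(table$sample_meta, group_by)
    sa <- tapply(sa, key, mean)
    sg <- tapply(sg, key, mean)
    meta <- unique(table$sample_meta[group_by])
    mkey <- as.character(group_keys(meta, group_by))
    meta <- meta[match(names(sa), mkey), , drop = FALSE]
    rec <- cbind(meta, data.frame(sum_ampar = as.numeric(sa),
                                  sum_gabaar = as.numeric(sg)))
  }
  rec$tei <- ifelse(rec$sum_gabaar > 0, rec$sum_ampar / rec$sum_gabaar,
                    NA_real_)
  if (anyNA(rec$tei))
    warning(sum(is.na(rec$tei)), " unit(s) with zero GABA-A receptor sum: ",
            "tE/I missing")
  rownames(rec) <- NULL
  rec
}

#' Group summaries of EI records
#'
#' n, mean, SD and SEM of the tE/I ratio per group, the table counterpart
#' of "mean +/- SEM/SD" figure annotations. SEM uses the number of units
#' (subjects or cells) in the group. Optionally summarizes the log2 of the
#' ratio.
#'
#' @param records data.frame from [compute_tei()]
#' @param by grouping column name(s) in `records`
#' @param value column to summarize (default `"tei"`)
#' @return data.frame: group, n, mean, sd, sem
#' @export
ei_group_summary <- function(records, by, value = "tei") {
  key <- group_keys(records, by)
  x <- records[[value]]
  agg <- split(x, key)
  data.frame(
    group = names(agg),
    n = vapply(agg, function(z) sum(!is.na(z)), 1L),
    mean = vapply(agg, function(z) mean(z, na.rm = TRUE), 1),
    sd = vapply(agg, function(z) stats::sd(z[!is.na(z)]), 1),
    sem = vapply(agg, function(z) {
      z <- z[!is.na(z)]; stats::sd(z) / sqrt(length(z))
    }, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-group regression of total AMPAR on total GABA-A receptor expression
#'
#' OLS of the AMPAR sum on the GABA-A receptor sum within each group, with
#' the Pearson correlation and its p-value; optionally on log2-transformed
#' sums (log2(x + 1), pseudo-count 1) to normalize skewed linear sums.
#'
#' @param records data.frame from [compute_tei()]
#' @param group_by grouping column name(s); `NULL` for a single fit
#' @param log2_transform fit on log2(sum + 1) instead of raw sums
#' @return data.frame: group, n, slope, intercept, r, p_value
#' @export
regress_totals <- function(records, group_by = NULL,
                           log2_transform = FALSE) {
  key <- group_keys(records, group_by)
  out <- lapply(levels(key), function(g) {
    d <- records[key == g, ]
    x <- d$sum_gabaar; y <- d$sum_ampar
    if (log2_transform) { x <- log2(x + 1); y <- log2(y + 1) }
    if (nrow(d) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("group '", g, "': degenerate regression input")
      return(data.frame(group = g, n = nrow(d), slope = NA_real_,
                        intercept = NA_real_, r = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    data.frame(group = g, n = nrow(d),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare tE/I between groups
#'
#' `welch_two_sample`: Welch's unequal-variance t test (Satterthwaite
#' degrees of freedom, two-tailed) for every pair of groups.
#' `anova_tukey_kramer`: one-way ANOVA omnibus F followed by all pairwise
#' comparisons against studentized-range critical values at unequal sample
#' sizes (Tukey-Kramer HSD).
#'
#' @param records data.frame from [compute_tei()]
#' @param group grouping column name in `records`
#' @param design `"welch_two_sample"` or `"anova_tukey_kramer"`
#' @param value column to compare (default `"tei"`)
#' @return for Welch, a data.frame of pairwise tests (group1, group2, t,
#'   df, p_value); for Tukey-Kramer, a list with `omnibus` (F, df, p) and
#'   `pairwise` (comparison, diff, lwr, upr, p_adj)
#' @export
compare_groups <- function(records, group,
                           design = c("welch_two_sample",
                                      "anova_tukey_kramer"),
                           value = "tei") {
  design <- match.arg(design)
  g <- factor(records[[group]])
  x <- records[[value]]
  keep <- !is.na(x)
  g <- droplevels(g[keep]); x <- x[keep]
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 units: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (nlevels(g) < 2L) stop("need >= 2 groups")

  if (design == "welch_two_sample") {
    pairs <- utils::combn(levels(g), 2L)
    out <- apply(pairs, 2L, function(p) {
      a <- x[g == p[1L]]; b <- x[g == p[2L]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        # identical degenerate samples: no evidence of difference
        return(data.frame(group1 = p[1L], group2 = p[2L], t = 0,
                          df = length(a) + length(b) - 2, p_value = 1,
                          stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group1 = p[1L], group2 = p[2L],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }

  fit <- stats::aov(x ~ g)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                         row.names = NULL)
  list(omnibus = data.frame(f = an$`F value`[1L], df1 = an$Df[1L],
                            df2 = an$Df[2L],
                            p_value = an$`Pr(>F)`[1L]),
       pairwise = pairwise)
}

#' Chloride-transporter expression and KCC2/NKCC1 ratio
#'
#' Per unit, the linear-scale expression of KCC2 (SLC12A5), NKCC1
#' (SLC12A2) and NKCC2 (SLC12A1) and the KCC2/NKCC1 ratio. Missing
#' transporter genes yield missing columns under the subset policy; the
#' ratio is missing when either gene is absent or the denominator is 0.
#'
#' @param table an `expression_table`
#' @param group_by optional metadata keys for unit aggregation (means)
#' @return data.frame: unit keys, `kcc2`, `nkcc1`, `nkcc2`, `kcc2_nkcc1`
#' @export
transporter_ratios <- function(table, group_by = NULL) {
  stopifnot(inherits(table, "expression_table"))
  lin <- linear_values(table)
  sym <- table$feature_meta$gene_symbol
  one <- function(gene) {
    i <- which(sym == gene)
    if (length(i) == 0L) return(rep(NA_real_, nrow(lin)))
    rowMeans(lin[, i, drop = FALSE])
  }
  kcc2 <- one("SLC12A5"); nkcc1 <- one("SLC12A2"); nkcc2 <- one("SLC12A1")
  if (is.null(group_by)) {
    rec <- cbind(table$sample_meta,
                 data.frame(kcc2 = kcc2, nkcc1 = nkcc1, nkcc2 = nkcc2))
  } else {
    key <- group_keys(table$sample_meta, group_by)
    agg <- function(z) as.numeric(tapply(z, key, mean))
    meta <- unique(table$sample_meta[group_by])
    mkey <- as.character(group_keys(meta, group_by))
    meta <- meta[match(levels(key), mkey), , drop = FALSE]
    rec <- cbind(meta, data.frame(kcc2 = agg(kcc2), nkcc1 = agg(nkcc1),
                                  nkcc2 = agg(nkcc2)))
  }
  rec$kcc2_nkcc1 <- ifelse(!is.na(rec$nkcc1) & rec$nkcc1 > 0,
                           rec$kcc2 / rec$nkcc1, NA_real_)
  rownames(rec) <- NULL
  rec
}

#' Smooth developmental trend with pre/postnatal linear fits
#'
#' Cubic smoothing spline of a value against age, with the smoothing
#' parameter chosen by generalized cross-validation unless `spar` is
#' given; the curve is evaluated on a grid spanning the observed age range
#' only. Alongside the smooth, simple linear fits and Pearson correlations
#' are computed within the prenatal (age < 0) and postnatal (age >= 0)
#' subsets, the split being birth at 40 post-conception weeks.
#'
#' @param values numeric response (e.g. tE/I per subject)
#' @param age numeric ages in years (negative = prenatal)
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]
#' @param grid_n number of grid points for the fitted curve
#' @return object of class `trend_fit`: `grid` data.frame (age, fitted),
#'   `spar`, `spline`, and `periods` data.frame with per-period n, slope,
#'   r and p
#' @export
fit_trend <- function(values, age, spar = NULL, grid_n = 200L) {
  keep <- !is.na(values) & !is.na(age)
  values <- values[keep]; age <- age[keep]
  if (length(values) < 5L || length(unique(age)) < 4L)
    stop("need >= 5 points over >= 4 distinct ages")
  fit <- if (is.null(spar)) {
    stats::smooth.spline(age, values, cv = FALSE)  # GCV
  } else {
    stats::smooth.spline(age, values, spar = spar)
  }
  grid <- seq(min(age), max(age), length.out = grid_n)
  pred <- stats::predict(fit, grid)
  periods <- do.call(rbind, lapply(
    list(prenatal = age < 0, postnatal = age >= 0), function(sel) {
      n <- sum(sel)
      if (n < 3L || stats::sd(age[sel]) == 0 || stats::sd(values[sel]) == 0)
        return(data.frame(n = n, slope = NA_real_, r = NA_real_,
                          p_value = NA_real_))
      lmfit <- stats::lm(values[sel] ~ age[sel])
      ct <- stats::cor.test(age[sel], values[sel])
      data.frame(n = n, slope = unname(stats::coef(lmfit)[2L]),
                 r = unname(ct$estimate), p_value = ct$p.value)
    }))
  periods <- cbind(period = rownames(periods), periods)
  rownames(periods) <- NULL
  structure(list(grid = data.frame(age = grid, fitted = pred$y),
                 spar = fit$spar, spline = fit, periods = periods),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 3, ...) {
  cat("<trend_fit> smoothing spline, spar = ", round(x$spar, digits),
      ", grid over [", round(min(x$grid$age), 2), ", ",
      round(max(x$grid$age), 2), "] years\n", sep = "")
  print(x$periods, row.names = FALSE)
  invisible(x)
}

#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$grid$age, x$grid$fitted, type = "l",
                 xlab = "age (years)", ylab = "fitted", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Correlation between two ratios split at birth
#'
#' Pearson correlation of `x` and `y` within the prenatal (age < 0) and
#' postnatal (age >= 0) subsets, for planted-association checks such as
#' tE/I against the KCC2/NKCC1 ratio across development.
#'
#' @param x,y numeric vectors
#' @param age numeric ages in years
#' @return data.frame: period, n, r, p_value
#' @export
pre_post_correlation <- function(x, y, age) {
  out <- lapply(list(prenatal = age < 0, postnatal = age >= 0),
                function(sel) {
    n <- sum(sel, na.rm = TRUE)
    if (n < 3L)
      return(data.frame(n = n, r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(x[sel], y[sel])
    data.frame(n = n, r = unname(ct$estimate), p_value = ct$p.value)
  })
  res <- do.call(rbind, out)
  cbind(period = rownames(res), res, row.names = NULL)
}
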