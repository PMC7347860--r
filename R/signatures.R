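#' Age-adjust an expression table
#'
#' Per feature, ordinary least squares of expression on age; the adjusted
#' value is the residual plus the fitted value at the cohort mean age, so
#' global expression levels are preserved. With fewer than three distinct
#' ages the design is degenerate and the table passes through unchanged
#' with a warning. The per-feature slope and p-value are attached as the
#' `"age_fit"` attribute.
#'
#' @param table an `expression_table` with `age` in its sample metadata
#' @param reference reference age; only `"cohort_mean_age"` is defined
#' @return an `expression_table` with age-adjusted values
#' @export
adjust_age <- function(table, reference = "cohort_mean_age") {
  stopifnot(inherits(table, "expression_table"))
  reference <- match.arg(reference)
  age <- table$sample_meta$age
  if (is.null(age)) stop("sample metadata has no 'age' column")
  if (length(unique(age)) < 3L) {
    warning("fewer than 3 distinct ages: age adjustment skipped")
    return(table)
  }
  mean_age <- mean(age)
  xc <- age - mean_age
  sxx <- sum(xc^2)
  v <- table$values
  slopes <- as.numeric(crossprod(xc, sweep(v, 2L, colMeans(v))) / sxx)
  adj <- v - outer(xc, slopes)
  n <- length(age)
  # per-feature t test on the slope
  rss <- colSums((adj - matrix(colMeans(v), n, ncol(v), byrow = TRUE))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slopes / se, NA_real_)
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- expression_table(adj, table$scale, table$feature_meta,
                          table$sample_meta)
  attr(out, "age_fit") <- data.frame(
    feature_id = table$feature_meta$feature_id,
    gene_symbol = table$feature_meta$gene_symbol,
    slope = slopes, p_value = pval, stringsAsFactors = FALSE)
  out
}

group_keys <- function(meta, group_by) {
  if (is.null(group_by)) return(factor(rep("all", nrow(meta))))
  interaction(meta[group_by], drop = TRUE, sep = "/", lex.order = TRUE)
}

#' Proportional subunit contributions
#'
#' Per group, each panel gene's percent share of the summed linear-scale
#' mean expression across the panel: log2 tables are exponentiated base 2
#' first, per-gene linear means are taken within the group, and each mean
#' is expressed as a percentage of the panel total. Rows sum to 100.
#'
#' @param table an `expression_table` (gene- or probe-level)
#' @param panel a `gene_panel`
#' @param group_by character vector of sample-metadata keys (`NULL` for a
#'   single global group)
#' @return data.frame: group keys, `gene`, `percent`, `n_samples`
#' @export
proportional_contribution <- function(table, panel, group_by = NULL) {
  idx <- resolve_panel(table, panel, "strict")
  lin <- linear_values(table)[, idx, drop = FALSE]
  genes <- attr(idx, "genes")
  key <- group_keys(table$sample_meta, group_by)
  out <- list()
  for (g in levels(key)) {
    rows <- key == g
    gm <- tapply(colMeans(lin[rows, , drop = FALSE]), genes, mean)
    gm <- gm[match(unique(genes), names(gm))]
    tot <- sum(gm)
    if (tot == 0) {
      warning("group '", g, "': all-zero panel expression; row omitted")
      next
    }
    df <- data.frame(group = g, gene = names(gm),
                     percent = 100 * as.numeric(gm) / tot,
                     n_samples = sum(rows), stringsAsFactors = FALSE)
    out[[g]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(group_by)) {
    keys <- do.call(rbind, strsplit(res$group, "/", fixed = TRUE))
    colnames(keys) <- group_by
    res <- cbind(as.data.frame(keys, stringsAsFactors = FALSE),
                 res[setdiff(names(res), "group")])
  }
  res
}

#' Fold enrichment of genes in substructures
#'
#' For each panel gene and each level of the ontology key, the linear-scale
#' ratio of the level's mean to the global mean: means are taken on the
#' log2 scale first and then exponentiated (ratio of exponentiated
#' means-of-log2), matching expression tables reported as per-region log2
#' averages. Also reports the top (argmax) level per gene.
#'
#' @param table an `expression_table`
#' @param panel a `gene_panel`
#' @param level ontology key, default `"substructure"`
#' @return data.frame: `gene`, `level`, `log2_mean`, `fold`; the per-gene
#'   argmax rows are attached as the `"top"` attribute
#' @export
fold_enrichment <- function(table, panel, level = "substructure") {
  idx <- resolve_panel(table, panel, "strict")
  lv <- log2_values(table)[, idx, drop = FALSE]
  genes <- attr(idx, "genes")
  labs <- table$sample_meta[[level]]
  if (is.null(labs)) stop("sample metadata has no '", level, "' column")
  keep <- !is.na(labs)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) without ", level, " label skipped")
    lv <- lv[keep, , drop = FALSE]; labs <- labs[keep]
  }
  out <- list()
  for (g in unique(genes)) {
    gv <- rowMeans(lv[, genes == g, drop = FALSE])
    global <- mean(gv)
    m <- tapply(gv, labs, mean)
    out[[g]] <- data.frame(gene = g, level = names(m),
                           log2_mean = as.numeric(m),
                           fold = 2^(as.numeric(m)) / 2^global,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(res)[names(res) == "level"] <- level
  top <- do.call(rbind, lapply(split(res, res$gene),
                               function(d) d[which.max(d$fold), ]))
  rownames(top) <- NULL
  attr(res, "top") <- top
  res
}

#' Five-number summaries with boxplot outliers
#'
#' Per gene and group: median, quartiles (linear-interpolation, type-7
#' quantiles), whiskers extending to the most extreme observations inside
#' the Q1 - 1.5 IQR and Q3 + 1.5 IQR fences, and the values falling
#' outside the fences flagged as outliers with their group label.
#'
#' @inheritParams proportional_contribution
#' @return data.frame of summaries; flagged outliers are attached as the
#'   `"outliers"` attribute (columns group, gene, sample_id, value)
#' @export
describe_expression <- function(table, panel, group_by = NULL) {
  idx <- resolve_panel(table, panel, "strict")
  v <- table$values[, idx, drop = FALSE]
  genes <- attr(idx, "genes")
  key <- group_keys(table$sample_meta, group_by)
  rows <- list(); outs <- list()
  for (g in unique(genes)) {
    gv <- rowMeans(v[, genes == g, drop = FALSE])
    for (lev in levels(key)) {
      x <- gv[key == lev]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      # whiskers reach the most extreme observation inside the fences
      lo <- min(x[x >= q[1] - 1.5 * iqr])
      hi <- max(x[x <= q[3] + 1.5 * iqr])
      rows[[paste(g, lev)]] <- data.frame(
        group = lev, gene = g, n = length(x), median = q[2],
        q1 = q[1], q3 = q[3], whisker_low = lo, whisker_high = hi,
        stringsAsFactors = FALSE)
      bad <- x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr
      if (any(bad)) {
        outs[[paste(g, lev)]] <- data.frame(
          group = lev, gene = g,
          sample_id = table$sample_meta$sample_id[key == lev][bad],
          value = x[bad], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- if (length(outs)) {
    o <- do.call(rbind, outs); rownames(o) <- NULL; o
  } else {
    data.frame(group = character(), gene = character(),
               sample_id = character(), value = numeric())
  }
  res
}

#' Two-level nested fixed-effects ANOVA
#'
#' Decomposes one gene's expression into structure and
#' substructure-within-structure effects:
#' `SS_total = SS_structure + SS_substructure(structure) + SS_error`,
#' with `F_structure = MS_structure / MS_substructure(structure)` (the
#' substructure mean square is the appropriate denominator when
#' substructure effects are present) and
#' `F_substructure = MS_substructure / MS_error`.
#'
#' @param table an `expression_table`
#' @param gene gene symbol to test (features of that gene are averaged)
#' @param structure_key,substructure_key sample-metadata keys of the two
#'   nesting levels
#' @return data.frame with one row per stratum (`structure`,
#'   `substructure`, `error`): `df`, `ss`, `ms`, `f`, `p_value`
#' @export
nested_anova <- function(table, gene, structure_key = "structure",
                         substructure_key = "substructure") {
  stopifnot(inherits(table, "expression_table"))
  sel <- table$feature_meta$gene_symbol == gene
  if (!any(sel)) stop("gene not in table: ", gene)
  y <- rowMeans(table$values[, sel, drop = FALSE])
  a <- factor(table$sample_meta[[structure_key]])
  b <- factor(table$sample_meta[[substructure_key]])
  if (nlevels(a) < 2L) stop("need >= 2 levels of ", structure_key)

  grand <- mean(y)
  cell <- interaction(a, b, drop = TRUE)
  ybar_a <- tapply(y, a, mean)[a]
  ybar_ab <- tapply(y, cell, mean)[cell]

  ss_a <- sum((ybar_a - grand)^2)
  ss_b <- sum((ybar_ab - ybar_a)^2)
  ss_e <- sum((y - ybar_ab)^2)

  n_sub <- tapply(as.character(b), a, function(z) length(unique(z)))
  df_a <- nlevels(a) - 1L
  df_b <- sum(n_sub - 1L)
  df_e <- length(y) - sum(n_sub)
  if (df_b < 1L)
    stop("saturated design: no substructure-within-", structure_key,
         " degrees of freedom")
  if (df_e < 1L)
    stop("saturated design: no residual degrees of freedom at the ",
         substructure_key, " level")

  ms_a <- ss_a / df_a; ms_b <- ss_b / df_b; ms_e <- ss_e / df_e
  f_a <- ms_a / ms_b; f_b <- ms_b / ms_e
  data.frame(
    stratum = c("structure", "substructure", "error"),
    df = c(df_a, df_b, df_e),
    ss = c(ss_a, ss_b, ss_e),
    ms = c(ms_a, ms_b, ms_e),
    f = c(f_a, f_b, NA),
    p_value = c(stats::pf(f_a, df_a, df_b, lower.tail = FALSE),
                stats::pf(f_b, df_b, df_e, lower.tail = FALSE), NA),
    stringsAsFactors = FALSE
  )
}
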