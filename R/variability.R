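#' Pairwise subunit Euclidean distance vector
#'
#' For one unit (a subject-by-structure cell, or a structure) with one
#' expression value per panel gene, the Euclidean distance between every
#' unordered gene pair: `sqrt((x - y)^2) = |x - y|` for scalar values.
#' When the unit carries several samples per gene (a matrix with samples
#' in rows), the same formula generalizes to the Euclidean distance
#' between the two gene columns. Pair order is fixed as
#' (1,2), (1,3), ..., (k-1,k).
#'
#' @param values named numeric vector (one value per gene) or numeric
#'   matrix (samples x genes)
#' @return named numeric vector of length choose(k, 2)
#' @examples
#' subunit_distance_vector(c(GRIA1 = 1, GRIA2 = 2, GRIA3 = 4, GRIA4 = 8))
#' @export
subunit_distance_vector <- function(values) {
  if (is.matrix(values)) {
    k <- ncol(values)
    if (k < 2L) stop("need >= 2 genes")
    if (anyNA(values)) stop("missing gene values")
    pairs <- utils::combn(k, 2L)
    d <- apply(pairs, 2L, function(p)
      sqrt(sum((values[, p[1L]] - values[, p[2L]])^2)))
    nm <- colnames(values) %||% paste0("g", seq_len(k))
  } else {
    k <- length(values)
    if (k < 2L) stop("need >= 2 genes")
    if (anyNA(values)) stop("missing gene values")
    pairs <- utils::combn(k, 2L)
    d <- abs(values[pairs[1L, ]] - values[pairs[2L, ]])
    nm <- names(values) %||% paste0("g", seq_len(k))
  }
  stats::setNames(as.numeric(d), paste0(nm[pairs[1L, ]], "-", nm[pairs[2L, ]]))
}

#' Per-unit distance vectors from an expression table
#'
#' Builds the matrix of pairwise-subunit distance vectors, one row per
#' unit, where a unit is defined by sample-metadata keys (e.g.
#' `c("subject_id", "substructure")` for subject-by-substructure units, or
#' `"substructure"` for structure-level units averaged over subjects).
#' Samples within a unit are averaged per gene before distances are taken.
#'
#' @param table gene-level `expression_table`
#' @param panel a `gene_panel`
#' @param unit_by character vector of sample-metadata keys defining units
#' @return matrix units x pairs with the unit key columns attached as the
#'   `"units"` attribute
#' @export
distance_vectors <- function(table, panel, unit_by) {
  idx <- resolve_panel(table, panel, "strict")
  genes <- attr(idx, "genes")
  v <- table$values[, idx, drop = FALSE]
  # average features per gene
  gv <- sapply(unique(genes), function(g)
    rowMeans(v[, genes == g, drop = FALSE]))
  key <- group_keys(table$sample_meta, unit_by)
  units <- levels(key)
  dmat <- t(vapply(units, function(u) {
    m <- colMeans(gv[key == u, , drop = FALSE])
    subunit_distance_vector(m)
  }, numeric(choose(ncol(gv), 2L))))
  rownames(dmat) <- units
  meta <- unique(table$sample_meta[unit_by])
  mkey <- group_keys(meta, unit_by)
  attr(dmat, "units") <- meta[match(units, as.character(mkey)), , drop = FALSE]
  dmat
}

#' Consensus distance vector
#'
#' Two readings of the consensus across units are supported:
#' `average_of_units` takes the elementwise mean of the per-unit distance
#' vectors (the default for subjects); `pooled_eq2` takes the elementwise
#' square root of the summed squared per-unit distances. When a
#' `reference` unit label is given, the consensus is built from the rows
#' matching that label only (e.g. a reference structure).
#'
#' @param dmat units x pairs distance matrix from [distance_vectors()]
#' @param mode `"average_of_units"` or `"pooled_eq2"`
#' @param reference optional regular expression selecting the reference
#'   rows by rowname (or a logical/integer row index)
#' @return numeric consensus vector, one entry per gene pair
#' @export
consensus_distances <- function(dmat, mode = c("average_of_units",
                                               "pooled_eq2"),
                                reference = NULL) {
  mode <- match.arg(mode)
  if (!is.null(reference)) {
    rows <- if (is.character(reference))
      grepl(reference, rownames(dmat)) else reference
    dmat <- dmat[rows, , drop = FALSE]
  }
  if (nrow(dmat) == 0L) stop("no units to build a consensus from")
  if (mode == "average_of_units") colMeans(dmat)
  else sqrt(colSums(dmat^2))
}

#' Correlate per-unit distance vectors to a consensus
#'
#' Per unit, the Pearson correlation between its pairwise-subunit distance
#' vector and the consensus vector; an optional grouping column of the
#' unit metadata yields group summaries (mean R, SD, n) so per-structure
#' "mean +/- SD" comparisons across subjects can be read off directly.
#'
#' @param dmat units x pairs distance matrix from [distance_vectors()]
#' @param consensus numeric consensus vector from [consensus_distances()]
#' @param group optional vector (or unit-metadata column name) grouping
#'   the units for the summary
#' @return object of class `consensus_result`: `units` data.frame with a
#'   column `r`, the `consensus` vector, and a `summary` data.frame
#' @export
correlate_to_consensus <- function(dmat, consensus, group = NULL) {
  if (ncol(dmat) < 3L) stop("need >= 3 distance pairs for a correlation")
  if (length(consensus) != ncol(dmat))
    stop("consensus length does not match distance pairs")
  r <- rep(NA_real_, nrow(dmat))
  const_cons <- stats::sd(consensus) == 0
  for (i in seq_len(nrow(dmat))) {
    if (stats::sd(dmat[i, ]) == 0 || const_cons) {
      warning("zero-variance distance vector: R undefined for unit ",
              rownames(dmat)[i] %||% i)
      next
    }
    r[i] <- stats::cor(dmat[i, ], consensus)
  }
  units <- attr(dmat, "units") %||%
    data.frame(unit = rownames(dmat) %||% seq_len(nrow(dmat)),
               stringsAsFactors = FALSE)
  units <- cbind(units, r = r)
  rownames(units) <- NULL
  if (is.character(group) && length(group) == 1L && group %in% names(units))
    group <- units[[group]]
  summary <- if (!is.null(group)) {
    agg <- split(r, group)
    data.frame(group = names(agg),
               mean_r = vapply(agg, function(z) mean(z, na.rm = TRUE), 1),
               sd_r = vapply(agg, function(z) stats::sd(z[!is.na(z)]), 1),
               n = vapply(agg, function(z) sum(!is.na(z)), 1L),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(group = "all", mean_r = mean(r, na.rm = TRUE),
               sd_r = stats::sd(r[!is.na(r)]), n = sum(!is.na(r)),
               stringsAsFactors = FALSE)
  }
  structure(list(units = units, consensus = consensus, summary = summary),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, digits = 3, ...) {
  cat("<consensus_result> ", nrow(x$units), " units\n", sep = "")
  s <- x$summary
  s$mean_r <- round(s$mean_r, digits); s$sd_r <- round(s$sd_r, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
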