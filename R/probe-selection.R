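#' Single-factor principal-axis factoring
#'
#' Iterative principal-axis extraction of one factor from a probe
#' correlation matrix, with no rotation. Communalities are initialized
#' with squared multiple correlations (1 - 1/diag(solve(corr))), the
#' diagonal of the correlation matrix is replaced by the current
#' communalities, the loading vector is the leading eigenvector scaled by
#' the square root of the leading eigenvalue, and communalities are
#' updated to the squared loadings until the largest communality change
#' falls below `tol` or `max_iter` is reached. Loadings are sign-flipped
#' so their sum is non-negative. Heywood cases (communality > 1) are
#' clipped to 1 - 1e-12 with a warning. If the correlation matrix is
#' singular the initial communalities fall back to each row's largest
#' absolute off-diagonal correlation.
#'
#' @param corr square symmetric correlation matrix with unit diagonal
#' @param tol convergence tolerance on the communality update
#' @param max_iter iteration cap
#' @return object of class `paf_fit`: `loadings`, `communalities`,
#'   `iterations`, `converged`
#' @examples
#' lam <- c(0.9, 0.8, 0.3)
#' r <- tcrossprod(lam); diag(r) <- 1
#' principal_axis_factor(r)$loadings  # recovers lam
#' @export
principal_axis_factor <- function(corr, tol = 1e-6, max_iter = 100L) {
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (p == 0L) stop("empty correlation matrix")
  if (p != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation matrix diagonal must be 1")

  if (p == 1L) {
    return(structure(list(loadings = 1, communalities = 1,
                          iterations = 0L, converged = TRUE),
                     class = "paf_fit"))
  }

  h2 <- tryCatch({
    inv <- solve(corr)
    1 - 1 / diag(inv)
  }, error = function(e) NULL)
  if (is.null(h2) || any(!is.finite(h2))) {
    warning("singular correlation matrix; initializing communalities ",
            "from max absolute off-diagonal correlations")
    off <- abs(corr); diag(off) <- 0
    h2 <- apply(off, 1L, max)
  }
  h2 <- pmin(pmax(h2, 0), 1 - 1e-12)

  loadings <- sqrt(h2)
  converged <- FALSE
  heywood <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- corr
    diag(r) <- h2
    e <- eigen(r, symmetric = TRUE)
    ev <- max(e$values[1L], 0)
    loadings <- e$vectors[, 1L] * sqrt(ev)
    h2_new <- loadings^2
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1 - 1e-12)
      loadings <- sign(loadings) * sqrt(h2_new)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (heywood) warning("Heywood case: communality > 1 clipped")
  if (sum(loadings) < 0) loadings <- -loadings
  structure(list(loadings = as.numeric(loadings),
                 communalities = as.numeric(h2),
                 iterations = iter, converged = converged),
            class = "paf_fit")
}

#' @export
print.paf_fit <- function(x, ...) {
  cat("<paf_fit> single principal-axis factor, ", length(x$loadings),
      " variables, ", x$iterations, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  print(round(data.frame(loading = x$loadings,
                         communality = x$communalities), 4))
  invisible(x)
}

#' Select one representative probe per gene
#'
#' For each gene with several probes, fits a single principal-axis factor
#' to the probe-by-probe Pearson correlation matrix computed across all
#' samples (whole-brain by default) and selects the probe with the largest
#' absolute loading. Ties (within `tie_tol`) are broken by higher mean
#' intensity, then by lexicographic probe id; single-probe genes select
#' their only probe. Zero-variance probes are excluded from the
#' correlation with a warning (selected only if they are the sole
#' candidate). The selection report carries the per-probe mean intensity
#' so the high-loading/high-intensity diagnostic can be reproduced.
#'
#' @param table probe-level `expression_table` with >= 2 samples
#' @param group_by optional sample-metadata key; when given, selection is
#'   run separately within each level and a per-group report is returned
#'   (no reduced table)
#' @param tol,max_iter passed to [principal_axis_factor()]
#' @param tie_tol absolute loading difference treated as a tie
#' @return for `group_by = NULL`, a list with `report` (data.frame: gene,
#'   probe, loading, communality, mean_intensity, tie_break_used) and
#'   `table`, the reduced gene-level `expression_table` (one selected
#'   probe per gene, features renamed to gene symbols); for grouped
#'   selection, a list of per-group reports
#' @export
select_representative_probes <- function(table, group_by = NULL,
                                         tol = 1e-6, max_iter = 100L,
                                         tie_tol = 1e-10) {
  stopifnot(inherits(table, "expression_table"))
  if (nrow(table$values) < 2L) stop("need >= 2 samples for correlations")
  if (!is.null(group_by)) {
    groups <- split(seq_len(nrow(table$values)),
                    table$sample_meta[[group_by]])
    return(lapply(groups, function(idx)
      select_representative_probes(subset_table(table, samples = idx),
                                   NULL, tol, max_iter, tie_tol)$report))
  }

  genes <- unique(table$feature_meta$gene_symbol)
  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    idx <- which(table$feature_meta$gene_symbol == g)
    ids <- table$feature_meta$feature_id[idx]
    vals <- table$values[, idx, drop = FALSE]
    means <- colMeans(vals)
    if (length(idx) == 1L) {
      rows[[k]] <- data.frame(gene = g, probe = ids, loading = 1,
                              communality = 1, mean_intensity = means,
                              tie_break_used = "single_probe",
                              stringsAsFactors = FALSE)
      next
    }
    vari <- apply(vals, 2L, stats::var)
    usable <- vari > 0
    if (!all(usable))
      warning("gene ", g, ": zero-variance probe(s) excluded: ",
              paste(ids[!usable], collapse = ", "))
    if (sum(usable) == 0L) {
      # all flat: fall back to intensity then id
      ord <- order(-means, ids)
      rows[[k]] <- data.frame(gene = g, probe = ids[ord[1L]], loading = NA,
                              communality = NA,
                              mean_intensity = means[ord[1L]],
                              tie_break_used = "mean_intensity",
                              stringsAsFactors = FALSE)
      next
    }
    uidx <- which(usable)
    fit <- principal_axis_factor(stats::cor(vals[, uidx, drop = FALSE]),
                                 tol, max_iter)
    al <- abs(fit$loadings)
    best <- max(al)
    tied <- which(al >= best - tie_tol)
    tie_break <- "none"
    if (length(tied) > 1L) {
      m <- means[uidx][tied]
      top <- which(m >= max(m) - tie_tol)
      if (length(top) > 1L) {
        pick <- tied[top[order(ids[uidx][tied][top])[1L]]]
        tie_break <- "probe_id"
      } else {
        pick <- tied[top[1L]]
        tie_break <- "mean_intensity"
      }
    } else {
      pick <- tied
    }
    sel <- uidx[pick]
    rows[[k]] <- data.frame(gene = g, probe = ids[sel],
                            loading = fit$loadings[pick],
                            communality = fit$communalities[pick],
                            mean_intensity = means[sel],
                            tie_break_used = tie_break,
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  keep <- match(report$probe, table$feature_meta$feature_id)
  vals <- table$values[, keep, drop = FALSE]
  fm <- data.frame(feature_id = report$gene, gene_symbol = report$gene,
                   stringsAsFactors = FALSE)
  reduced <- expression_table(vals, table$scale, fm, table$sample_meta)
  list(report = report, table = reduced)
}
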