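#' Ward hierarchical clustering (ward.D2, Euclidean)
#'
#' Agglomerative clustering of the rows of a numeric matrix using Ward's
#' minimum-variance criterion in its ward.D2 form (squared-Euclidean
#' Lance-Williams updates with square-root merge heights) on Euclidean
#' distances. Deterministic given the input; exact distance ties are
#' resolved by the agglomeration order of [stats::hclust()].
#'
#' @param x numeric matrix, items in rows, features in columns; no missing
#'   values
#' @return an [stats::hclust] tree
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 items to cluster")
  if (anyNA(x)) stop("missing values in clustering input")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

# leaf sets of every internal node of an hclust tree, as sorted integer
# vectors in merge order
hclust_leaf_sets <- function(hc) {
  m <- hc$merge
  sets <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    get <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(get(m[i, 1L]), get(m[i, 2L])))
  }
  sets
}

leaf_set_keys <- function(sets) vapply(sets, paste, "", collapse = ",")

#' Multiscale bootstrap configuration
#'
#' @param scales resampling scale factors r (fraction of the feature count
#'   drawn per resample); default 0.5 to 1.4 in steps of 0.1
#' @param nboot total number of bootstrap resamples, split evenly across
#'   the scales (default 10000)
#' @param seed RNG seed
#' @return a `bootstrap_config` list with the per-scale count `B`
#' @export
bootstrap_config <- function(scales = seq(0.5, 1.4, by = 0.1),
                             nboot = 10000L, seed = 1L) {
  if (any(scales <= 0)) stop("scales must be > 0")
  B <- max(1L, as.integer(round(nboot / length(scales))))
  structure(list(scales = scales, B = B, nboot = nboot,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Multiscale-bootstrap cluster support (AU and BP p-values)
#'
#' Assesses every internal node of the Ward dendrogram of `x` by
#' non-parametric bootstrap resampling of the feature axis at several
#' scales. For each scale `r`, `B` resamples of `round(r * n)` features
#' are drawn with replacement, the rows are reclustered, and the fraction
#' of resamples in which each reference cluster (identified by its leaf
#' set, irrespective of child order) recurs gives the per-scale bootstrap
#' probability. The naive bootstrap probability BP is the recurrence
#' fraction at the scale closest to 1. The approximately unbiased p-value
#' AU extrapolates across scales: the z-curve
#' `psi(r) = qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` (v the signed
#' distance, c the curvature term) is fit by weighted least squares
#' (binomial delta-method weights; unweighted fallback if any weight is
#' non-finite) and `AU = 1 - pnorm(v - c)`.
#' Counts of 0 or B are clamped by a 0.5/B continuity correction; a
#' cluster whose recurrence saturates at every scale (all counts B, or
#' all 0) leaves no curve to extrapolate and is reported with AU = 1 (or
#' 0) directly. The root, present in every resample by construction, is
#' reported with BP = AU = 1.
#'
#' With fewer than 3 scales the two-parameter fit is underdetermined: AU
#' is reported missing with a diagnostic and BP is still reported.
#'
#' To support clusters of features (e.g. genes clustered by their
#' regional expression), apply the same machinery to the transposed
#' matrix.
#'
#' @param x numeric matrix, items (to cluster) in rows, features (to
#'   resample) in columns; >= 2 features
#' @param cfg a [bootstrap_config()]
#' @return object of class `cluster_support`: the reference `hclust`
#'   tree, a `nodes` data.frame (node, size, members, bp, au, se_au, v,
#'   c), the per-scale count and bootstrap-probability matrices, and the
#'   config
#' @export
multiscale_bootstrap <- function(x, cfg = bootstrap_config()) {
  x <- as.matrix(x)
  stopifnot(inherits(cfg, "bootstrap_config"))
  n <- ncol(x)
  if (n < 2L) stop("need >= 2 features to resample")
  hc <- ward_cluster(x)
  sets <- hclust_leaf_sets(hc)
  keys <- leaf_set_keys(sets)
  n_nodes <- length(keys)
  scales <- cfg$scales
  B <- cfg$B

  set.seed(cfg$seed)
  counts <- matrix(0L, n_nodes, length(scales),
                   dimnames = list(NULL, paste0("r", scales)))
  for (si in seq_along(scales)) {
    m <- max(2L, as.integer(round(scales[si] * n)))
    for (b in seq_len(B)) {
      cols <- sample.int(n, m, replace = TRUE)
      bhc <- stats::hclust(stats::dist(x[, cols, drop = FALSE]),
                           method = "ward.D2")
      bkeys <- leaf_set_keys(hclust_leaf_sets(bhc))
      hit <- keys %in% bkeys
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }

  bp_scale <- counts / B
  near1 <- which.min(abs(scales - 1))

  nodes <- data.frame(node = seq_len(n_nodes),
                      size = lengths(sets),
                      members = keys,
                      bp = bp_scale[, near1],
                      au = NA_real_, se_au = NA_real_,
                      v = NA_real_, c = NA_real_,
                      stringsAsFactors = FALSE)
  root <- n_nodes
  au_ok <- length(scales) >= 3L
  if (!au_ok) warning("fewer than 3 scales: AU not identifiable, BP only")
  for (i in seq_len(n_nodes)) {
    if (i == root) {
      nodes$bp[i] <- 1; nodes$au[i] <- 1; nodes$se_au[i] <- 0
      nodes$v[i] <- 0; nodes$c[i] <- 0
      next
    }
    if (!au_ok) next
    fit <- au_zcurve(counts[i, ], B, scales)
    nodes$v[i] <- fit$v; nodes$c[i] <- fit$c
    nodes$au[i] <- fit$au; nodes$se_au[i] <- fit$se_au
  }

  structure(list(hclust = hc, nodes = nodes, counts = counts,
                 bp_scale = bp_scale, cfg = cfg),
            class = "cluster_support")
}

# z-curve extrapolation of per-scale recurrence counts to the AU p-value:
# psi(r) = qnorm(1 - BP_r) fit against (sqrt(r), 1/sqrt(r)) by WLS with
# binomial delta-method weights; counts clamped by 0.5/B
au_zcurve <- function(counts, B, scales) {
  # saturated recurrence: the cluster is (never) present in every resample
  # at every scale, so there is no z-curve to extrapolate
  if (all(counts == B))
    return(list(v = NA_real_, c = NA_real_, au = 1, se_au = 0))
  if (all(counts == 0))
    return(list(v = NA_real_, c = NA_real_, au = 0, se_au = 0))
  p <- pmin(pmax(counts, 0.5), B - 0.5) / B
  psi <- stats::qnorm(1 - p)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- B * stats::dnorm(psi)^2 / (p * (1 - p))
  if (any(!is.finite(w))) w <- rep(1, length(w))
  xtwx <- crossprod(X, X * w)
  fit <- tryCatch(solve(xtwx, crossprod(X, psi * w)),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(v = NA_real_, c = NA_real_, au = NA_real_,
                se_au = NA_real_))
  v <- fit[1L]; cc <- fit[2L]
  au <- 1 - stats::pnorm(v - cc)
  se_au <- NA_real_
  covb <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (!is.null(covb)) {
    var_vc <- covb[1, 1] + covb[2, 2] - 2 * covb[1, 2]
    se_au <- stats::dnorm(v - cc) * sqrt(max(var_vc, 0))
  }
  list(v = v, c = cc, au = au, se_au = se_au)
}

#' @export
print.cluster_support <- function(x, digits = 3, ...) {
  cat("<cluster_support> ", length(x$hclust$labels %||%
        seq_len(nrow(x$nodes) + 1L)), " items, ",
      nrow(x$nodes), " internal nodes, B = ", x$cfg$B, " x ",
      length(x$cfg$scales), " scales\n", sep = "")
  d <- x$nodes
  d$members <- ifelse(nchar(d$members) > 28,
                      paste0(substr(d$members, 1, 25), "..."), d$members)
  print(cbind(d[c("node", "size", "members")],
              round(d[c("bp", "au", "se_au")], digits)), row.names = FALSE)
  invisible(x)
}

#' Plot a dendrogram annotated with AU/BP support
#'
#' @param x a `cluster_support` object
#' @param ... passed to [plot.hclust()]
#' @export
plot.cluster_support <- function(x, ...) {
  hc <- x$hclust
  graphics::plot(hc, ...)
  ord <- order(hc$order)
  xs <- numeric(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pos <- function(j) if (j < 0) ord[-j] else xs[j]
    xs[i] <- mean(c(pos(hc$merge[i, 1]), pos(hc$merge[i, 2])))
  }
  graphics::text(xs, hc$height,
                 labels = sprintf("%.2f/%.2f", x$nodes$au, x$nodes$bp),
                 pos = 3, cex = 0.7, col = "red3", xpd = NA)
  invisible(x)
}

#' Export a support-annotated dendrogram to Newick
#'
#' Writes the reference tree with AU p-values as internal node labels.
#'
#' @param x a `cluster_support` object
#' @param path output file
#' @param label which support value to use as node labels (`"au"` or
#'   `"bp"`)
#' @return `path`, invisibly
#' @export
export_newick <- function(x, path, label = c("au", "bp")) {
  stopifnot(inherits(x, "cluster_support"))
  label <- match.arg(label)
  phy <- ape::as.phylo(x$hclust)
  ntip <- length(phy$tip.label)
  # leaf set per phylo internal node, matched against hclust node keys
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  edges <- phy$edge[order(phy$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; ch <- edges[k, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  labs <- if (is.null(x$hclust$labels)) as.integer(phy$tip.label)
          else match(phy$tip.label, x$hclust$labels)
  node_keys <- vapply((ntip + 1L):(ntip + phy$Nnode), function(nd)
    paste(sort(labs[desc[[nd]]]), collapse = ","), "")
  m <- match(node_keys, x$nodes$members)
  phy$node.label <- ifelse(is.na(m), "",
                           sprintf("%.3f", x$nodes[[label]][m]))
  ape::write.tree(phy, file = path)
  invisible(path)
}
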