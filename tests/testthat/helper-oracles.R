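# Independent brute-force oracles, written against the formulas rather than
# the package's code paths.

# Agglomerative ward.D2 by direct Lance-Williams updates on squared
# Euclidean distances, sqrt-heights; merges the pair with minimal criterion
# (first found on exact ties). Returns merge heights sorted ascending and
# the list of merged leaf sets.
oracle_ward2 <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  sets <- list()
  # ward.D2 objective on squared distances: merge cost d2[i,j] (already
  # holding the Lance-Williams-updated squared cluster distance)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestval <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d2[i, j] < bestval) { bestval <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestval))
    new_members <- sort(c(members[[i]], members[[j]]))
    sets[[length(sets) + 1L]] <- new_members
    # Lance-Williams update for ward.D2 (on squared distances)
    for (k in active) {
      if (k == i || k == j) next
      ai <- (sizes[i] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      aj <- (sizes[j] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      bk <- -sizes[k] / (sizes[i] + sizes[j] + sizes[k])
      d2[i, k] <- d2[k, i] <- ai * d2[i, k] + aj * d2[j, k] + bk * d2[i, j]
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- new_members
    active <- setdiff(active, j)
  }
  list(heights = heights, sets = sets)
}

# Welch two-sample t by the textbook formulas
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# Tukey-Kramer pairwise p-values from the studentized range distribution
oracle_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  df_e <- length(values) - k
  mse <- sum(tapply(values, groups, function(z)
    sum((z - mean(z))^2))) / df_e
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt(mse / 2 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    q <- abs(ms[[p[2]]] - ms[[p[1]]]) / se
    data.frame(group1 = p[1], group2 = p[2],
               p_adj = stats::ptukey(q, k, df_e, lower.tail = FALSE))
  })
  do.call(rbind, res)
}

# Direct enumeration of the leaf sets of an hclust tree, written
# independently of the package's recursion (iterative stack version)
oracle_tree_sets <- function(hc) {
  m <- hc$merge
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    stack <- c(m[i, 1], m[i, 2])
    leaves <- integer(0)
    while (length(stack)) {
      top <- stack[[1]]; stack <- stack[-1]
      if (top < 0) leaves <- c(leaves, -top)
      else stack <- c(stack, m[top, 1], m[top, 2])
    }
    out[[i]] <- sort(leaves)
  }
  out
}

# Naive bootstrap probability at scale 1 for a given leaf set, by direct
# resampling and counting
oracle_bp1 <- function(x, leaf_set, B, seed) {
  set.seed(seed)
  key <- paste(sort(leaf_set), collapse = ",")
  hits <- 0
  n <- ncol(x)
  for (b in seq_len(B)) {
    cols <- sample.int(n, n, replace = TRUE)
    hc <- stats::hclust(stats::dist(x[, cols, drop = FALSE]), "ward.D2")
    keys <- vapply(oracle_tree_sets(hc), paste, "", collapse = ",")
    if (key %in% keys) hits <- hits + 1
  }
  hits / B
}

# Rand index between two partitions
rand_index <- function(p1, p2) {
  n <- length(p1)
  same1 <- outer(p1, p1, "==")
  same2 <- outer(p2, p2, "==")
  agree <- (same1 == same2)
  (sum(agree) - n) / (n * (n - 1))
}

# small probe-level fixture: 4 samples x 17 probes with the 4/4/4/5
# GRIA1-4 multiplicity, written to a temp TSV
write_probe_fixture <- function(path, na_cell = FALSE) {
  set.seed(42)
  genes <- rep(c("GRIA1", "GRIA2", "GRIA3", "GRIA4"), c(4, 4, 4, 5))
  probes <- paste0(genes, "_p", unlist(lapply(c(4, 4, 4, 5), seq_len)))
  vals <- matrix(round(stats::rnorm(4 * 17, 8, 1), 4), nrow = 17,
                 dimnames = list(probes, paste0("s", 1:4)))
  df <- data.frame(feature_id = probes, gene_symbol = genes, vals,
                   check.names = FALSE)
  if (na_cell) df[3, "s2"] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
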