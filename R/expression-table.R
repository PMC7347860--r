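#' Expression table
#'
#' The central data container: a samples x features numeric matrix of
#' expression values together with per-feature gene mapping and per-sample
#' metadata. Features are microarray probes or genes; values are either
#' log2 intensities (`scale = "log2"`) or linear-scale abundances such as
#' FPKM/RPKM/uTPM (`scale = "linear"`). The scale is always declared, never
#' inferred, because silent mis-scaling corrupts every downstream ratio.
#'
#' Sample metadata must contain a `sample_id` column matching the matrix
#' rows; optional columns are `subject_id`, `age` (years; negative values
#' encode prenatal ages relative to birth at 40 post-conception weeks),
#' `sex` (`"M"`, `"F"` or `"unknown"`), the three-level anatomical ontology
#' `region` > `structure` > `substructure`, and `cell_type`. When ontology
#' labels are present their nesting is validated: a substructure maps to
#' exactly one structure and a structure to exactly one region.
#'
#' @param values numeric matrix, samples in rows, features in columns
#' @param scale `"log2"` or `"linear"`
#' @param feature_meta data.frame with columns `feature_id` (unique, one
#'   per matrix column) and `gene_symbol`
#' @param sample_meta data.frame with a `sample_id` column covering every
#'   matrix row
#' @return an object of class `expression_table`
#' @export
expression_table <- function(values, scale = c("log2", "linear"),
                             feature_meta, sample_meta) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)

  if (!all(c("feature_id", "gene_symbol") %in% names(feature_meta)))
    stop("feature_meta needs columns feature_id, gene_symbol")
  if (!"sample_id" %in% names(sample_meta))
    stop("sample_meta needs a sample_id column")
  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  feature_meta$gene_symbol <- as.character(feature_meta$gene_symbol)
  sample_meta$sample_id <- as.character(sample_meta$sample_id)

  if (nrow(feature_meta) != ncol(values))
    stop("feature_meta rows (", nrow(feature_meta),
         ") must match value columns (", ncol(values), ")")
  if (anyDuplicated(feature_meta$feature_id))
    stop("duplicate feature ids")
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample ids")
  if (anyNA(feature_meta$gene_symbol) || any(feature_meta$gene_symbol == ""))
    stop("every feature must map to exactly one gene symbol")

  if (is.null(rownames(values))) {
    if (nrow(values) != nrow(sample_meta))
      stop("sample_meta rows must match value rows when rows are unnamed")
    rownames(values) <- sample_meta$sample_id
  }
  if (!all(rownames(values) %in% sample_meta$sample_id))
    stop("expression rows without sample metadata: ",
         paste(utils::head(setdiff(rownames(values), sample_meta$sample_id)),
               collapse = ", "))
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  colnames(values) <- feature_meta$feature_id

  if (anyNA(values))
    stop("expression values contain missing entries; ",
         "apply a missing-data policy at read time")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale table contains negative values")

  validate_ontology(sample_meta)

  structure(
    list(values = values, scale = scale,
         feature_meta = feature_meta, sample_meta = sample_meta),
    class = "expression_table"
  )
}

# substructure -> structure -> region must nest consistently
validate_ontology <- function(meta) {
  levels <- c("region", "structure", "substructure")
  present <- levels[levels %in% names(meta)]
  if (length(present) < 2L) return(invisible(TRUE))
  for (i in seq_len(length(present) - 1L)) {
    child <- meta[[present[i + 1L]]]
    parent <- meta[[present[i]]]
    keep <- !is.na(child) & !is.na(parent)
    if (!any(keep)) next
    tab <- unique(data.frame(child = child[keep], parent = parent[keep]))
    bad <- tab$child[duplicated(tab$child)]
    if (length(bad) > 0L)
      stop("ontology nesting violated: ", present[i + 1L], " ",
           paste(unique(bad), collapse = ", "), " maps to multiple ",
           present[i], "s")
  }
  invisible(TRUE)
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", x$scale, ")\n", sep = "")
  genes <- unique(x$feature_meta$gene_symbol)
  cat("  genes: ", length(genes),
      if (length(genes) <= 8) paste0(" [", paste(genes, collapse = ", "), "]")
      else paste0(" [", paste(utils::head(genes, 6), collapse = ", "), ", ...]"),
      "\n", sep = "")
  meta_cols <- setdiff(names(x$sample_meta), "sample_id")
  if (length(meta_cols)) cat("  sample metadata:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

#' Subset an expression table
#'
#' @param x an `expression_table`
#' @param samples row (sample) index
#' @param features column (feature) index
#' @return an `expression_table`
#' @export
subset_table <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "expression_table"))
  v <- x$values
  fm <- x$feature_meta
  sm <- x$sample_meta
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]
    fm <- fm[features, , drop = FALSE]
  }
  expression_table(v, x$scale, fm, sm)
}

#' Read an expression table from TSV/CSV
#'
#' The dialect names the feature orientation, the declared scale, the
#' sample-id column and the missing-data policy. Files are UTF-8 with a
#' header row. With `orientation = "features_in_rows"` the first column
#' holds feature ids, an optional `gene_symbol` column the gene mapping,
#' and the remaining columns one sample each. With
#' `orientation = "features_in_columns"` the column named by `id_column`
#' holds sample ids and all other columns are features (a `gene_map` is
#' then required unless feature names are themselves gene symbols).
#'
#' @param path path to a TSV (default) or CSV file
#' @param scale declared value scale, `"log2"` or `"linear"` (never
#'   inferred)
#' @param orientation `"features_in_rows"` or `"features_in_columns"`
#' @param sample_meta data.frame or path to a TSV of sample metadata; if
#'   `NULL`, minimal metadata with only sample ids is created
#' @param gene_map optional data.frame or TSV path with columns
#'   `feature_id`, `gene_symbol`; if absent, a `gene_symbol` column in the
#'   file is used, else `gene_symbol = feature_id`
#' @param sep field separator; inferred from the file extension by default
#' @param id_column name of the sample-id column
#'   (features-in-columns only)
#' @param missing missing-data policy: `"error"` (default), `"drop_sample"`
#'   or `"drop_feature"`; drops are logged
#' @return an `expression_table`
#' @export
read_expression_table <- function(path,
                                  scale = c("log2", "linear"),
                                  orientation = c("features_in_rows",
                                                  "features_in_columns"),
                                  sample_meta = NULL,
                                  gene_map = NULL,
                                  sep = NULL,
                                  id_column = "sample_id",
                                  missing = c("error", "drop_sample",
                                              "drop_feature")) {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("malformed header: fewer than two columns")

  if (is.character(sample_meta)) {
    sample_meta <- utils::read.table(sample_meta, header = TRUE, sep = "\t",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
  }
  if (is.character(gene_map)) {
    gene_map <- utils::read.table(gene_map, header = TRUE, sep = "\t",
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
  }

  if (orientation == "features_in_rows") {
    feature_id <- as.character(raw[[1L]])
    gene_col <- names(raw)[tolower(names(raw)) == "gene_symbol"]
    value_cols <- setdiff(names(raw)[-1L], gene_col)
    gene_symbol <- if (length(gene_col)) as.character(raw[[gene_col[1L]]])
                   else NULL
    vals <- t(as.matrix(raw[, value_cols, drop = FALSE]))
    colnames(vals) <- feature_id
    rownames(vals) <- value_cols
    fm <- data.frame(feature_id = feature_id,
                     gene_symbol = gene_symbol %||% feature_id,
                     stringsAsFactors = FALSE)
  } else {
    if (!id_column %in% names(raw))
      stop("malformed header: no '", id_column, "' column")
    sid <- as.character(raw[[id_column]])
    value_cols <- setdiff(names(raw), id_column)
    vals <- as.matrix(raw[, value_cols, drop = FALSE])
    rownames(vals) <- sid
    fm <- data.frame(feature_id = value_cols, gene_symbol = value_cols,
                     stringsAsFactors = FALSE)
  }
  storage.mode(vals) <- "double"

  if (!is.null(gene_map)) {
    m <- match(fm$feature_id, as.character(gene_map$feature_id))
    if (anyNA(m))
      stop("gene_map lacks entries for: ",
           paste(utils::head(fm$feature_id[is.na(m)]), collapse = ", "))
    fm$gene_symbol <- as.character(gene_map$gene_symbol)[m]
  }

  dropped <- 0L
  if (anyNA(vals)) {
    n_missing <- sum(is.na(vals))
    if (missing == "error") {
      stop(n_missing, " missing expression values (policy = error)")
    } else if (missing == "drop_sample") {
      keep <- !apply(is.na(vals), 1L, any)
      dropped <- sum(!keep)
      warning("dropped ", dropped, " sample(s) with missing values")
      vals <- vals[keep, , drop = FALSE]
    } else {
      keep <- !apply(is.na(vals), 2L, any)
      dropped <- sum(!keep)
      warning("dropped ", dropped, " feature(s) with missing values")
      vals <- vals[, keep, drop = FALSE]
      fm <- fm[keep, , drop = FALSE]
    }
  }

  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = rownames(vals),
                              stringsAsFactors = FALSE)
  tab <- expression_table(vals, scale, fm, sample_meta)
  tei_log("read ", path, ": ", nrow(tab$values), " samples x ",
          ncol(tab$values), " features (", dropped, " dropped)")
  tab
}

#' Write an expression table to TSV
#'
#' Features-in-rows layout with `feature_id` and `gene_symbol` columns, one
#' column per sample; round-trips through [read_expression_table()] to
#' full printed precision. Sample metadata is written alongside when
#' `meta_path` is given.
#'
#' @param x an `expression_table`
#' @param path output TSV path
#' @param meta_path optional TSV path for the sample metadata
#' @return `path`, invisibly
#' @export
write_expression_table <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expression_table"))
  out <- data.frame(feature_id = x$feature_meta$feature_id,
                    gene_symbol = x$feature_meta$gene_symbol,
                    t(x$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
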