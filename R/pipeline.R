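#' Run the tE/I analysis pipeline
#'
#' Orchestrates the stages of the transcriptional E/I workflow on one
#' expression table: representative-probe selection, signatures (age
#' adjustment, proportional contributions, fold enrichment), bootstrap-
#' supported clustering, distance-vector variability, and the tE/I ratio.
#' Each enabled stage writes a TSV result table to the output directory
#' and a JSON manifest records the config hash, seed, stage list and
#' output checksums, so a rerun with the same config and seed is
#' bit-identical.
#'
#' The config is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{input}{either `list(simulate = "regional"|"single_cell"|
#'     "developmental")` to generate data, or `list(path =, scale =,
#'     orientation =, sample_meta =, gene_map =)` for
#'     [read_expression_table()]}
#'   \item{stages}{character vector among `probe_selection`,
#'     `signatures`, `clustering`, `variability`, `ei_ratio`}
#'   \item{outdir}{output directory (created if needed)}
#'   \item{seed}{integer RNG seed}
#'   \item{group_by}{metadata key for grouped summaries (default
#'     `"structure"` when present, else `"cell_type"`)}
#'   \item{nboot}{total bootstrap count for the clustering stage
#'     (default 1000)}
#' }
#'
#' Probe-level tables (several features per gene) must run
#' `probe_selection` before `clustering`, `variability` or `ei_ratio`;
#' violating the order is an error, as is an unknown stage name.
#'
#' @param config list or YAML path
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("probe_selection", "signatures", "clustering", "variability",
             "ei_ratio")
  stages <- config$stages %||% known
  bad <- setdiff(stages, known)
  if (length(bad) > 0L)
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  outdir <- config$outdir %||% stop("config needs an outdir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  inp <- config$input %||% stop("config needs an input")
  if (!is.null(inp$simulate)) {
    gen <- switch(inp$simulate,
      regional = gen_regional_microarray(regional_sim_config(seed = seed)),
      single_cell = gen_single_cell(cell_sim_config(seed = seed)),
      developmental = gen_developmental(dev_sim_config(seed = seed)),
      stop("unknown simulate kind: ", inp$simulate))
    table <- gen$table
  } else {
    table <- read_expression_table(
      inp$path, scale = inp$scale %||% "log2",
      orientation = inp$orientation %||% "features_in_rows",
      sample_meta = inp$sample_meta, gene_map = inp$gene_map,
      missing = inp$missing %||% "error")
  }

  probe_level <- anyDuplicated(table$feature_meta$gene_symbol) > 0L
  group_by <- config$group_by %||%
    (if ("structure" %in% names(table$sample_meta)) "structure"
     else if ("cell_type" %in% names(table$sample_meta)) "cell_type"
     else NULL)
  panels <- default_panels()
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs[[name]] <<- path
  }

  selected <- !probe_level
  for (stage in stages) {
    if (stage %in% c("clustering", "variability", "ei_ratio") && !selected)
      stop("ordering error: stage '", stage, "' needs a gene-level table; ",
           "run probe_selection first")
    switch(stage,
      probe_selection = {
        if (probe_level) {
          sel <- select_representative_probes(table)
          emit(sel$report, "probe_selection")
          table <- sel$table
        }
        selected <- TRUE
      },
      signatures = {
        tab <- table
        if ("age" %in% names(tab$sample_meta) &&
            length(unique(tab$sample_meta$age)) >= 3L)
          tab <- adjust_age(tab)
        ok <- tryCatch({
          pc <- proportional_contribution(tab, panels$AMPAR, group_by)
          emit(pc, "contributions"); TRUE
        }, error = function(e) FALSE)
        if (!ok) tei_log("signatures: AMPAR panel unresolved, stage skipped")
        if ("substructure" %in% names(tab$sample_meta) &&
            any(panels$AMPAR$genes %in% tab$feature_meta$gene_symbol)) {
          fe <- fold_enrichment(tab, panels$AMPAR)
          emit(fe, "enrichment")
        }
      },
      clustering = {
        if (is.null(group_by)) stop("clustering needs a grouping key")
        mat <- cluster_matrix(table, panels$AMPAR,
                              items = config$cluster_items %||%
                                "substructure")
        cs <- multiscale_bootstrap(
          mat, bootstrap_config(nboot = config$nboot %||% 1000L,
                                seed = seed))
        emit(cs$nodes, "cluster_support")
      },
      variability = {
        unit_by <- config$unit_by %||%
          intersect(c("subject_id", "substructure"),
                    names(table$sample_meta))
        dmat <- distance_vectors(table, panels$AMPAR, unit_by)
        cons <- consensus_distances(dmat)
        res <- correlate_to_consensus(dmat, cons)
        emit(res$units, "variability")
      },
      ei_ratio = {
        rec <- compute_tei(table, panels, policy = "subset")
        emit(rec, "ei_records")
        if (!is.null(group_by))
          emit(ei_group_summary(rec, group_by), "ei_summary")
      })
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "teisig",
    version = as.character(utils::packageVersion("teisig")),
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    stages = stages,
    outputs = lapply(outputs, function(p) unname(tools::md5sum(p)))
  )
  unlink(tmp)
  manifest_path <- file.path(outdir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path)
  tei_log("pipeline done: ", length(outputs), " tables in ", outdir)
  invisible(manifest)
}

#' Items-by-features matrix for bootstrap clustering
#'
#' Builds the matrix fed to [multiscale_bootstrap()]: rows are the units
#' to cluster (substructures by default), columns are (gene x subject)
#' expression values, so the bootstrap resamples gene-by-subject columns
#' rather than a handful of gene means.
#'
#' @param table gene-level `expression_table`
#' @param panel a `gene_panel`
#' @param items sample-metadata key naming the rows (default
#'   `"substructure"`)
#' @param within optional key for columns (default `"subject_id"` when
#'   present); when absent, columns are per-gene means
#' @return numeric matrix items x features
#' @export
cluster_matrix <- function(table, panel, items = "substructure",
                           within = NULL) {
  idx <- resolve_panel(table, panel, "strict")
  genes <- attr(idx, "genes")
  v <- table$values[, idx, drop = FALSE]
  it <- table$sample_meta[[items]]
  if (is.null(it)) stop("no '", items, "' column in sample metadata")
  within <- within %||%
    (if ("subject_id" %in% names(table$sample_meta)) "subject_id" else NULL)
  if (is.null(within)) {
    rows <- sort(unique(it))
    mat <- t(vapply(rows, function(u)
      colMeans(v[it == u, , drop = FALSE]), numeric(ncol(v))))
    colnames(mat) <- table$feature_meta$feature_id[idx]
    return(mat)
  }
  w <- table$sample_meta[[within]]
  rows <- sort(unique(it)); cols_w <- sort(unique(w))
  gene_ids <- table$feature_meta$feature_id[idx]
  mat <- matrix(NA_real_, length(rows), length(gene_ids) * length(cols_w),
                dimnames = list(rows, as.vector(outer(gene_ids, cols_w,
                                                      paste, sep = "."))))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols_w)) {
      sel <- it == rows[i] & w == cols_w[j]
      cell <- if (any(sel)) colMeans(v[sel, , drop = FALSE])
              else rep(NA_real_, length(gene_ids))
      mat[i, (j - 1L) * length(gene_ids) + seq_along(gene_ids)] <- cell
    }
  }
  if (anyNA(mat)) {
    drop <- apply(is.na(mat), 2L, any)
    warning("dropping ", sum(drop), " incomplete (gene x ", within,
            ") columns")
    mat <- mat[, !drop, drop = FALSE]
  }
  mat
}
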