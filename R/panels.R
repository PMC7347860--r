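#' Gene panels
#'
#' A gene panel is a named, ordered list of gene symbols that drives the
#' subunit sums and ratios throughout the package: the AMPA-receptor subunit
#' genes for the excitatory side, the GABA-A receptor subunit genes for the
#' inhibitory side, and the chloride transporters for the KCC2/NKCC1 ratio.
#'
#' @param name panel name
#' @param genes character vector of unique gene symbols (non-empty)
#' @return an object of class `gene_panel`
#' @examples
#' gene_panel("AMPAR", c("GRIA1", "GRIA2", "GRIA3", "GRIA4"))
#' @export
gene_panel <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene panel '", name, "' is empty")
  if (anyDuplicated(genes)) stop("gene panel '", name, "' has duplicate symbols")
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, " (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Default gene panels
#'
#' The four AMPAR subunit genes (GRIA1-4), the 19 GABA-A receptor subunit
#' genes of the GABR* family (including the rho subunits GABRR1-3, which are
#' configurable: drop them by passing a reduced panel to downstream
#' functions), and the three SLC12A chloride transporters (NKCC2, NKCC1,
#' KCC2).
#'
#' @return named list of `gene_panel` objects: `AMPAR`, `GABAAR`,
#'   `TRANSPORTERS`
#' @export
default_panels <- function() {
  list(
    AMPAR = gene_panel("AMPAR", c("GRIA1", "GRIA2", "GRIA3", "GRIA4")),
    GABAAR = gene_panel("GABAAR", c(
      "GABRA1", "GABRA2", "GABRA3", "GABRA4", "GABRA5", "GABRA6",
      "GABRB1", "GABRB2", "GABRB3",
      "GABRG1", "GABRG2", "GABRG3",
      "GABRD", "GABRE", "GABRP", "GABRQ",
      "GABRR1", "GABRR2", "GABRR3"
    )),
    TRANSPORTERS = gene_panel("TRANSPORTERS", c("SLC12A1", "SLC12A2", "SLC12A5"))
  )
}

#' Resolve a gene panel against an expression table
#'
#' Maps panel gene symbols to feature (probe/gene) column indices of the
#' table. Under `strict` policy every panel gene must be represented by at
#' least one feature; under `subset` the missing genes are logged and the
#' present ones returned.
#'
#' @param table an `expression_table`
#' @param panel a `gene_panel`
#' @param policy `"strict"` (default: error on any missing gene) or
#'   `"subset"`
#' @return integer vector of feature indices (possibly empty under
#'   `subset`), with a `genes` attribute giving the gene of each index
#' @export
resolve_panel <- function(table, panel, policy = c("strict", "subset")) {
  stopifnot(inherits(table, "expression_table"), inherits(panel, "gene_panel"))
  policy <- match.arg(policy)
  sym <- table$feature_meta$gene_symbol
  present <- panel$genes[panel$genes %in% sym]
  missing <- setdiff(panel$genes, present)
  if (length(missing) > 0L) {
    if (policy == "strict") {
      stop("panel '", panel$name, "': missing genes: ",
           paste(missing, collapse = ", "))
    }
    warning("panel '", panel$name, "': genes absent from table: ",
            paste(missing, collapse = ", "))
  }
  idx <- which(sym %in% present)
  # order-independent, deterministic: sorted feature index order
  idx <- sort(idx)
  attr(idx, "genes") <- sym[idx]
  idx
}
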