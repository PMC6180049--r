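#' Construct an annotated case/control expression matrix
#'
#' The central container of the pipeline: a genes x samples matrix of
#' log-scale normalized expression values with a per-sample group label
#' (\code{"case"} or \code{"control"}) and, optionally, a per-sample study
#' identifier for multi-study cohorts.
#'
#' Gene and sample identifiers are taken from the dimnames and must be
#' unique; they are treated as opaque, case-sensitive strings. Missing or
#' non-finite values are rejected: the upstream normalization this container
#' models produces complete matrices, and none of the downstream statistics
#' are defined for missing cells.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param group character or factor of length \code{ncol(values)} with
#'   values in \code{c("case", "control")}.
#' @param study optional character vector of per-sample study identifiers.
#' @return An object of class \code{"ExpressionMatrix"}: a list with
#'   elements \code{values}, \code{group} (factor with levels case/control)
#'   and \code{study} (character or NULL).
#' @examples
#' v <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(v, group = c("case", "case", "control", "control"))
#' dim(x$values)
#' @export
expression_matrix <- function(values, group, study = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must carry gene rownames and sample colnames")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite and non-missing")
  group <- factor(as.character(group), levels = c("case", "control"))
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample")
  if (anyNA(group))
    stop("group labels must be 'case' or 'control'")
  if (!is.null(study)) {
    study <- as.character(study)
    if (length(study) != ncol(values))
      stop("`study` must have one identifier per sample")
  }
  structure(list(values = values, group = group, study = study),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  if (!is.null(x$study))
    cat(sprintf("  %d studies\n", length(unique(x$study))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Restrict an ExpressionMatrix to a subset of samples
#'
#' @param x an \code{ExpressionMatrix}.
#' @param idx integer, logical or character index into the samples.
#' @return An \code{ExpressionMatrix} with the selected samples.
#' @export
subset_samples <- function(x, idx) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  expression_matrix(x$values[, idx, drop = FALSE],
                    group = x$group[idx],
                    study = if (!is.null(x$study)) x$study[idx])
}

#' Restrict an ExpressionMatrix to a subset of genes
#'
#' @param x an \code{ExpressionMatrix}.
#' @param genes character vector of gene symbols (all must be present).
#' @return An \code{ExpressionMatrix} with the selected genes, in the
#'   requested order.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[genes, , drop = FALSE],
                    group = x$group, study = x$study)
}
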