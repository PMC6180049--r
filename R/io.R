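#' Read an expression matrix and its phenotype table
#'
#' Reads a tab-separated genes x samples matrix (header row of sample IDs,
#' first column of gene symbols) together with a phenotype table mapping
#' every sample to its group (\code{case}/\code{control}) and, optionally,
#' its study of origin. Both files may be gzipped.
#'
#' The phenotype table must cover every sample in the matrix; samples
#' present in the matrix but absent from the phenotype file are an error.
#' Extra phenotype rows are ignored. Columns are matched by name
#' (\code{sample_id}, \code{group}, \code{study}) when present, otherwise
#' positionally.
#'
#' @param path path to the expression TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, phenotype_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("expression file needs a gene column and at least one sample column")
  gene_ids <- tab[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene symbol(s) in ", path, ": ", paste(dup, collapse = ", "))
  sample_ids <- colnames(tab)[-1]
  vals <- matrix(NA_real_, nrow(tab), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
                   col[bad[1]], gene_ids[bad[1]], bad[1], sample_ids[j]))
    vals[, j] <- num
  }

  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  sid_col <- if ("sample_id" %in% names(ph)) "sample_id" else names(ph)[1]
  grp_col <- if ("group" %in% names(ph)) "group" else names(ph)[2]
  std_col <- if ("study" %in% names(ph)) "study"
             else if (ncol(ph) >= 3) names(ph)[3] else NULL
  orphans <- setdiff(sample_ids, ph[[sid_col]])
  if (length(orphans))
    stop("sample(s) missing from phenotype table: ",
         paste(orphans, collapse = ", "))
  ord <- match(sample_ids, ph[[sid_col]])
  expression_matrix(vals,
                    group = ph[[grp_col]][ord],
                    study = if (!is.null(std_col)) ph[[std_col]][ord])
}

#' Write an expression matrix (and optionally its phenotype table)
#'
#' Values are written at full double precision so that
#' \code{read_expression(write_expression(x))} is an identity on the values.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path output TSV path for the matrix.
#' @param phenotype_path optional output TSV path for the phenotype table.
#' @return Invisibly, \code{x}.
#' @export
write_expression <- function(x, path, phenotype_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phenotype_path)) {
    ph <- data.frame(sample_id = colnames(x$values),
                     group = as.character(x$group),
                     stringsAsFactors = FALSE)
    if (!is.null(x$study)) ph$study <- x$study
    utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: \code{name TAB description TAB member TAB member ...}.
#' Empty member fields are dropped and members are de-duplicated within a
#' set. Gzipped files are accepted.
#'
#' @param path path to the GMT file.
#' @return An object of class \code{"GeneSetCollection"}: a list with
#'   \code{sets} (named list of character vectors) and \code{descriptions}
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)))
    name <- fields[1]
    if (name %in% names(sets))
      stop("duplicate gene-set name: ", name)
    members <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    sets[[name]] <- members
    descriptions[name] <- fields[2]
  }
  gene_set_collection(sets, descriptions)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members unique per set).
#' @param descriptions optional named character vector of descriptions.
#' @return A \code{"GeneSetCollection"}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s)")
  sets <- lapply(sets, unique)
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(x$sets), if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Write a gene-set collection in GMT format
#'
#' @param collection a \code{GeneSetCollection}.
#' @param path output path.
#' @return Invisibly, \code{collection}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a STRING-style interaction edge list
#'
#' Accepts a TSV with at least three columns (node, node, combined score)
#' with or without a header line. Both common score dialects are accepted:
#' reals in [0, 1], or the 0-999 integer export (detected when any score
#' exceeds 1, in which case the whole file is divided by 1000). Self-loops
#' are dropped, duplicate undirected edges are collapsed keeping the
#' maximum score, and edges below \code{min_score} are removed.
#'
#' @param path path to the edge TSV (may be gzipped).
#' @param min_score minimum combined score to retain an edge (default 0.4,
#'   the conventional medium-confidence cutoff).
#' @return A data.frame with columns \code{node_a}, \code{node_b},
#'   \code{combined_score}.
#' @export
read_edge_list <- function(path, min_score = 0.4) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(node_a = character(), node_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  first <- strsplit(lines[1], "[\t ]+")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "[\t ]+")
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop(sprintf("edge-list line %d has fewer than 3 fields",
                 short[1] + has_header))
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (anyNA(sc))
    stop("non-numeric combined score at line ",
         which(is.na(sc))[1] + has_header)
  if (any(sc > 1)) sc <- sc / 1000  # 0-999 integer dialect
  if (any(sc < 0 | sc > 1))
    stop("combined score outside [0, 1] after normalization")
  keep <- a != b
  a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  ord <- order(lo, hi, -sc)
  lo <- lo[ord]; hi <- hi[ord]; sc <- sc[ord]
  first_of_pair <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[first_of_pair]; hi <- hi[first_of_pair]; sc <- sc[first_of_pair]
  keep <- sc >= min_score
  data.frame(node_a = lo[keep], node_b = hi[keep],
             combined_score = sc[keep], stringsAsFactors = FALSE)
}

#' Serialize a dendrogram as a Newick string
#'
#' Converts a binary merge tree (an \code{\link[stats]{hclust}} object) to
#' Newick. The branch length of a child is its parent's merge height minus
#' its own merge height; leaves sit at height 0. Children are ordered
#' deterministically: leaves before internal nodes, each by ascending
#' index in the merge table.
#'
#' @param dendrogram an \code{hclust} object with leaf labels.
#' @param path optional file to write the string to.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly if \code{path} is given.
#' @export
write_newick <- function(dendrogram, path = NULL, digits = 10) {
  hc <- dendrogram
  if (!inherits(hc, "hclust"))
    stop("`dendrogram` must be an hclust object")
  n <- length(hc$labels)
  if (is.null(hc$labels))
    stop("dendrogram has no leaf labels")
  if (is.null(hc$merge) || nrow(hc$merge) != n - 1 || ncol(hc$merge) != 2)
    stop("dendrogram is not a binary merge tree with n - 1 merges")
  fmt <- function(len) sprintf("%.*g", digits, len)
  node_height <- function(ref) if (ref < 0) 0 else hc$height[ref]
  # sort key: leaves (negative refs) first by leaf index, then merges by row
  key <- function(ref) if (ref < 0) -ref else n + ref
  render <- function(ref, parent_height) {
    if (ref < 0) {
      paste0(hc$labels[-ref], ":", fmt(parent_height))
    } else {
      kids <- hc$merge[ref, ]
      kids <- kids[order(vapply(kids, key, numeric(1)))]
      inner <- paste(vapply(kids, render, character(1), hc$height[ref]),
                     collapse = ",")
      if (is.na(parent_height)) {
        paste0("(", inner, ")")
      } else {
        paste0("(", inner, "):", fmt(parent_height - hc$height[ref]))
      }
    }
  }
  out <- paste0(render(n - 1, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
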