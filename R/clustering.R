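#' Manhattan distances between samples on a gene subset
#'
#' d(i, j) = sum over genes of |x_gi - x_gj|, computed between sample
#' columns after optionally restricting the matrix to signature genes.
#'
#' @param x an \code{\link{expression_matrix}} (or plain numeric matrix,
#'   genes x samples).
#' @param genes optional character vector (or \code{gene_signature}) of
#'   genes to restrict to.
#' @return A \code{\link[stats]{dist}} object over samples.
#' @export
manhattan_distances <- function(x, genes = NULL) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (!is.null(genes)) {
    genes <- signature_genes(genes)
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  dist(t(v), method = "manhattan")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Lance-Williams Ward updates applied
#' directly to the supplied distances (\code{hclust} method
#' \code{"ward.D"}). Ward's criterion is derived for squared Euclidean
#' distances; applying the same updates to other metrics (here, Manhattan)
#' is a pragmatic, widely used combination rather than a theoretically
#' clean one, and is what this pipeline standardizes on.
#'
#' @param dist_matrix a \code{dist} object (or symmetric matrix).
#' @return An \code{\link[stats]{hclust}} object.
#' @export
ward_linkage <- function(dist_matrix) {
  if (is.matrix(dist_matrix)) dist_matrix <- as.dist(dist_matrix)
  if (!inherits(dist_matrix, "dist")) stop("`dist_matrix` must be a dist")
  if (attr(dist_matrix, "Size") < 2) stop("need at least 2 samples")
  hclust(dist_matrix, method = "ward.D")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the top \code{n_clusters - 1} merges.
#'
#' @param dendrogram an \code{hclust} object.
#' @param n_clusters number of clusters (default 2).
#' @return Named integer vector of cluster labels per sample.
#' @export
cut_k <- function(dendrogram, n_clusters = 2) {
  stopifnot(inherits(dendrogram, "hclust"))
  cutree(dendrogram, k = n_clusters)
}

#' Best-matching agreement between cluster labels and known groups
#'
#' The classification accuracy maximized over all assignments of cluster
#' labels to group labels; for two clusters against two groups this is
#' max(acc, 1 - acc). Chance level for balanced two-group data is 0.5.
#'
#' @param cluster_labels vector of cluster assignments.
#' @param true_groups vector of known group labels (same length).
#' @return Agreement in [0, 1].
#' @export
label_agreement <- function(cluster_labels, true_groups) {
  if (length(cluster_labels) != length(true_groups))
    stop("label vectors must have equal length")
  cl <- as.integer(factor(cluster_labels))
  gr <- as.integer(factor(true_groups))
  k <- max(cl); g <- max(gr)
  if (k > 7 || g > 7)
    stop("label_agreement supports at most 7 clusters/groups")
  tab <- table(factor(cl, 1:k), factor(gr, 1:g))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  # assign each cluster a group label (injectively over the larger side)
  if (k <= g) {
    best <- max(vapply(perms(seq_len(g)), function(p) {
      sum(tab[cbind(seq_len(k), p[seq_len(k)])])
    }, numeric(1)))
  } else {
    best <- max(vapply(perms(seq_len(k)), function(p) {
      sum(tab[cbind(p[seq_len(g)], seq_len(g))])
    }, numeric(1)))
  }
  best / length(cl)
}
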