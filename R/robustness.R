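#' Stratified subsample of a two-group cohort
#'
#' Draws exactly \code{n_per_group} sample indices per group, uniformly
#' without replacement within each group, using the current RNG state
#' (\code{\link{run_robustness}} seeds it deterministically per
#' subsample).
#'
#' @param group_labels factor or character vector of per-sample group
#'   labels.
#' @param n_per_group number of samples to draw from each group.
#' @return Integer vector of sample indices (grouped by label).
#' @export
stratified_subsample <- function(group_labels, n_per_group) {
  group_labels <- as.factor(group_labels)
  idx <- integer(0)
  for (lev in levels(group_labels)) {
    members <- which(group_labels == lev)
    if (length(members) < n_per_group)
      stop(sprintf("group '%s' has %d samples; cannot draw %d",
                   lev, length(members), n_per_group))
    idx <- c(idx, sample(members, n_per_group))
  }
  idx
}

#' Top-k genes by directional p-value
#'
#' Ranks genes by their smaller one-sided p, min(p_up, p_down), with ties
#' broken by |t| descending and then gene symbol ascending, and returns
#' the first k.
#'
#' @param deg a data.frame with \code{gene}, \code{t}, \code{p_up},
#'   \code{p_down}.
#' @param k list length (default 500).
#' @return Character vector of k gene symbols, most significant first.
#' @export
top_k <- function(deg, k = 500) {
  stopifnot(all(c("gene", "t", "p_up", "p_down") %in% names(deg)))
  if (k > nrow(deg))
    stop("k = ", k, " exceeds the number of genes (", nrow(deg), ")")
  p <- pmin(deg$p_up, deg$p_down)
  ord <- order(p, -abs(deg$t), deg$gene)
  deg$gene[ord[seq_len(k)]]
}

#' Overlap of two equal-length marker lists
#'
#' The fraction of shared features appearing on both lists,
#' |A intersect B| / k. Both lists must have the same length k; the
#' denominator is k, not the union size.
#'
#' @param list_a,list_b character vectors of equal length.
#' @return The overlap, in [0, 1].
#' @export
overlap <- function(list_a, list_b) {
  if (length(list_a) != length(list_b))
    stop("marker lists must have equal length (", length(list_a),
         " vs ", length(list_b), ")")
  if (!length(list_a)) stop("marker lists must be non-empty")
  length(intersect(list_a, list_b)) / length(list_a)
}

#' Stability of top-k differential gene lists under stratified subsampling
#'
#' The core robustness procedure: B times, draw a stratified subsample of
#' \code{n_per_group} samples per group, compute per-gene two-sample t
#' statistics and one-sided p-values on the subsample, and record the
#' top-k gene list. Selection counts are accumulated per gene, the
#' pairwise overlap statistic is computed for every pair of the B lists,
#' and its median summarizes signature stability.
#'
#' A master seed spawns B deterministic sub-seeds (returned in the
#' result), so any individual subsample can be reproduced in isolation.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param B number of subsamples (default 200).
#' @param n_per_group samples drawn per group (default 361, half of a
#'   723-case cohort's smaller group at full scale).
#' @param k length of each top list (default 500).
#' @param seed master integer seed.
#' @param variance_mode passed to \code{\link{t_statistics}}.
#' @param verbose print progress every 10 subsamples.
#' @return An object of class \code{"robustness_result"}: list with
#'   \code{B}, \code{k}, \code{n_per_group}, \code{selection_count}
#'   (named integer, sums to B * k), \code{overlap_values}
#'   (length B(B-1)/2), \code{median_overlap}, \code{subsample_seeds},
#'   and \code{top_lists}.
#' @export
run_robustness <- function(x, B = 200, n_per_group = 361, k = 500, seed,
                           variance_mode = c("pooled", "welch"),
                           verbose = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (missing(seed)) stop("`seed` is required")
  stopifnot(B >= 2, k >= 1, n_per_group >= 2)
  variance_mode <- match.arg(variance_mode)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, B))
  genes <- rownames(x$values)
  counts <- setNames(integer(length(genes)), genes)
  lists <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- withr::with_seed(sub_seeds[b],
                            stratified_subsample(x$group, n_per_group))
    deg <- directional_pvalues(
      t_statistics(subset_samples(x, idx), variance_mode))
    lists[[b]] <- top_k(deg, k)
    counts[lists[[b]]] <- counts[lists[[b]]] + 1L
    if (verbose && b %% 10 == 0)
      message("subsample ", b, "/", B)
  }
  pairs <- combn(B, 2)
  ov <- vapply(seq_len(ncol(pairs)), function(j) {
    overlap(lists[[pairs[1, j]]], lists[[pairs[2, j]]])
  }, numeric(1))
  structure(list(B = B, k = k, n_per_group = n_per_group,
                 selection_count = counts,
                 overlap_values = ov,
                 median_overlap = median(ov),
                 subsample_seeds = sub_seeds,
                 top_lists = lists),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(paste0("robustness_result: B = %d subsamples of %d per group,",
                     " k = %d\n  median pairwise overlap = %.3f\n"),
              x$B, x$n_per_group, x$k, x$median_overlap))
  invisible(x)
}

#' Genes repeatedly selected across subsamples
#'
#' The robust gene set: genes whose selection count reaches
#' \code{min_fraction * B}.
#'
#' @param result a \code{robustness_result}.
#' @param min_fraction minimum fraction of subsamples a gene must be
#'   selected in (default 0.9).
#' @return Character vector of robust gene symbols.
#' @export
robust_set <- function(result, min_fraction = 0.9) {
  stopifnot(inherits(result, "robustness_result"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must lie in (0, 1]")
  counts <- result$selection_count
  names(counts)[counts >= min_fraction * result$B]
}

#' Intersect the full-cohort signature with the robust gene set
#'
#' The final robust signature: signature genes that are also robust,
#' preserving each gene's direction and rank order from the input
#' signature.
#'
#' @param robust character vector of robust genes (from
#'   \code{\link{robust_set}}).
#' @param signature a \code{gene_signature} from
#'   \code{\link{select_signature}}.
#' @return A \code{gene_signature} restricted to robust genes.
#' @export
final_signature <- function(robust, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  structure(list(up = signature$up[signature$up %in% robust],
                 down = signature$down[signature$down %in% robust]),
            class = "gene_signature")
}
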