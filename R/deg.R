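#' Two-sample t statistics for every gene
#'
#' Computes, per gene, the case-minus-control t statistic. With
#' \code{variance_mode = "pooled"} the classical equal-variance statistic
#' is used (df = n1 + n2 - 2); with \code{"welch"} the unequal-variance
#' statistic with Satterthwaite degrees of freedom.
#'
#' Degenerate genes are handled explicitly: zero variance in both groups
#' with equal means gives t = 0; zero variance with unequal means gives
#' t = +/-Inf and is flagged in the \code{zero_variance} column.
#'
#' @param x an \code{\link{expression_matrix}} with both groups present
#'   and at least two samples per group.
#' @param variance_mode \code{"pooled"} (default) or \code{"welch"}.
#' @return A data.frame (one row per gene) with columns \code{gene},
#'   \code{mean_case}, \code{mean_control}, \code{t}, \code{df},
#'   \code{zero_variance}.
#' @examples
#' v <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(v) <- paste0("s", 1:6)
#' x <- expression_matrix(v, rep(c("case", "control"), each = 3))
#' t_statistics(x)$t  # (2 - 5) / sqrt(1 * 2/3) = -3.674
#' @export
t_statistics <- function(x, variance_mode = c("pooled", "welch")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  variance_mode <- match.arg(variance_mode)
  case <- x$values[, x$group == "case", drop = FALSE]
  ctrl <- x$values[, x$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2)
    stop("both groups need at least 2 samples (have ", n1, " case, ",
         n2, " control)")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (variance_mode == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[se == 0] <- n1 + n2 - 2  # degenerate; df is irrelevant there
  }
  zero_var <- se == 0
  t <- ifelse(zero_var, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  data.frame(gene = rownames(x$values),
             mean_case = m1, mean_control = m2,
             t = t, df = df, zero_variance = zero_var,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided p-values in each direction
#'
#' Adds \code{p_up} = P(T >= t), the evidence that a gene is up-regulated
#' in cases, and \code{p_down} = P(T <= t). For a continuous reference
#' distribution these always sum to one.
#'
#' @param deg a data.frame with \code{t} and \code{df} columns, as from
#'   \code{\link{t_statistics}}.
#' @return The input with \code{p_up} and \code{p_down} columns added.
#' @export
directional_pvalues <- function(deg) {
  stopifnot(all(c("t", "df") %in% names(deg)))
  deg$p_up <- pt(deg$t, deg$df, lower.tail = FALSE)
  deg$p_down <- pt(deg$t, deg$df)
  deg
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The standard step-up FDR adjustment:
#' q_(i) = min over j >= i of (m * p_(j) / j), capped at 1 and mapped back
#' to the input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

#' Linear-scale fold changes from log-scale means
#'
#' FC = base^(mean_case - mean_control): the geometric-mean expression
#' ratio of case over control. Genes down-regulated in cases have FC < 1.
#'
#' @param x an \code{ExpressionMatrix} on a log scale.
#' @param log_base base of the log scale (default 2).
#' @return Named numeric vector of per-gene fold changes.
#' @export
fold_changes <- function(x, log_base = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  m1 <- rowMeans(x$values[, x$group == "case", drop = FALSE])
  m2 <- rowMeans(x$values[, x$group == "control", drop = FALSE])
  setNames(log_base^(m1 - m2), rownames(x$values))
}

#' Full per-gene differential-expression table
#'
#' Convenience wrapper chaining \code{\link{t_statistics}},
#' \code{\link{directional_pvalues}}, \code{\link{bh_adjust}} (applied
#' separately within each direction) and \code{\link{fold_changes}}.
#'
#' @inheritParams t_statistics
#' @param log_base base of the log scale for fold changes.
#' @return A data.frame with columns \code{gene}, \code{t}, \code{df},
#'   \code{p_up}, \code{p_down}, \code{q_up}, \code{q_down},
#'   \code{fold_change} (plus group means and the degeneracy flag).
#' @export
deg_table <- function(x, variance_mode = c("pooled", "welch"), log_base = 2) {
  deg <- directional_pvalues(t_statistics(x, variance_mode))
  deg$q_up <- bh_adjust(deg$p_up)
  deg$q_down <- bh_adjust(deg$p_down)
  deg$fold_change <- unname(fold_changes(x, log_base))
  deg
}

#' Select the top-fraction/FDR differential signature
#'
#' Within each direction, candidate genes are those whose directional
#' q-value clears \code{fdr_threshold}; candidates are ranked by ascending
#' directional p (ties by |t| descending, then gene symbol) and at most
#' \code{ceiling(top_fraction / 2 * n_genes)} are kept per direction, so
#' the signature holds at most the top \code{top_fraction} of all genes
#' and possibly fewer. A gene can appear in only one direction; the
#' smaller directional p wins.
#'
#' @param deg a data.frame from \code{\link{deg_table}} (needs \code{p_up},
#'   \code{p_down}, \code{q_up}, \code{q_down}, \code{t}, \code{gene}).
#' @param top_fraction overall fraction of genes the signature may hold
#'   (split evenly between directions; default 0.01).
#' @param fdr_threshold directional FDR cutoff (default 0.001).
#' @return An object of class \code{"gene_signature"}: a list with
#'   \code{up} and \code{down} character vectors, most significant first.
#' @export
select_signature <- function(deg, top_fraction = 0.01, fdr_threshold = 0.001) {
  stopifnot(all(c("gene", "t", "p_up", "p_down", "q_up", "q_down") %in%
                  names(deg)))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must lie in (0, 1]")
  cap <- ceiling(top_fraction / 2 * nrow(deg))
  pick <- function(direction) {
    p <- deg[[paste0("p_", direction)]]
    q <- deg[[paste0("q_", direction)]]
    other <- deg[[paste0("p_", setdiff(c("up", "down"), direction))]]
    cand <- which(q < fdr_threshold & p <= other)
    cand <- cand[order(p[cand], -abs(deg$t[cand]), deg$gene[cand])]
    deg$gene[head(cand, cap)]
  }
  structure(list(up = pick("up"), down = pick("down")),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up, %d down\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Flatten a gene signature to a character vector
#'
#' @param signature a \code{gene_signature} (or character vector, returned
#'   unchanged).
#' @return Character vector, up-regulated genes first.
#' @export
signature_genes <- function(signature) {
  if (inherits(signature, "gene_signature"))
    c(signature$up, signature$down)
  else as.character(signature)
}
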