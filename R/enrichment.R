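#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= overlap) where X is the number of signature genes falling in a
#' set of size \code{set_size} when \code{signature_size} genes are drawn
#' without replacement from a universe of \code{universe_size}.
#'
#' @param signature_size number of signature genes (in the universe).
#' @param set_size number of set members (in the universe).
#' @param overlap observed number of shared genes.
#' @param universe_size size of the testable gene universe.
#' @return The upper-tail probability.
#' @export
hypergeometric_p <- function(signature_size, set_size, overlap,
                             universe_size) {
  if (any(c(signature_size, set_size, overlap, universe_size) < 0))
    stop("counts must be non-negative")
  if (signature_size > universe_size || set_size > universe_size)
    stop("signature and set must fit inside the universe")
  if (overlap > min(signature_size, set_size))
    stop("overlap exceeds min(signature size, set size)")
  if (overlap < signature_size + set_size - universe_size)
    stop("overlap below the minimum forced by the margins")
  phyper(overlap - 1, set_size, universe_size - set_size, signature_size,
         lower.tail = FALSE)
}

#' Over-representation analysis of a signature against a collection
#'
#' Tests each set for enrichment of signature genes by the upper-tail
#' hypergeometric test. The universe should be the population of genes
#' that could have entered the signature (typically all genes on the
#' expression matrix, not all genes annotated in the collection); sets
#' and signature are intersected with it before testing.
#'
#' @param signature a \code{gene_signature} or character vector.
#' @param collection a \code{GeneSetCollection}.
#' @param universe character vector of testable genes.
#' @return A data.frame per set: \code{set}, \code{set_size} (within the
#'   universe), \code{overlap_count}, \code{expected_count},
#'   \code{p_hyper}, \code{overlap_genes} (comma-separated), ascending
#'   in p.
#' @export
ora <- function(signature, collection, universe) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  sig <- unique(signature_genes(signature))
  outside <- setdiff(sig, universe)
  if (length(outside))
    stop("signature gene(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  U <- length(unique(universe))
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    hit <- intersect(sig, members)
    data.frame(set = nm,
               set_size = length(members),
               overlap_count = length(hit),
               expected_count = length(sig) * length(members) / U,
               p_hyper = hypergeometric_p(length(sig), length(members),
                                          length(hit), U),
               overlap_genes = paste(hit, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hyper, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation-based FDR for over-representation analysis
#'
#' Runs \code{\link{ora}} on the observed signature, then on
#' \code{n_perm} random signatures of the same size drawn from the
#' universe. Each set's FDR is the mean number of permutation set-level
#' p-values at or below its observed p, divided by the observed number of
#' sets at or below that p, capped at 1 (the standard
#' permutation-plug-in FDR).
#'
#' @inheritParams ora
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed.
#' @param fdr_threshold significance threshold recorded in the
#'   \code{significant} column (default 0.05).
#' @return The \code{\link{ora}} table with \code{fdr} and
#'   \code{significant} columns added.
#' @export
permutation_fdr <- function(signature, collection, universe,
                            n_perm = 1000, seed, fdr_threshold = 0.05) {
  if (missing(seed)) stop("`seed` is required")
  obs <- ora(signature, collection, universe)
  sig_size <- length(unique(signature_genes(signature)))
  uni <- unique(universe)
  U <- length(uni)
  member_idx <- lapply(collection$sets,
                       function(s) which(uni %in% s))
  set_sizes <- lengths(member_idx)
  # spawn an internal sub-seed so the permutation stream cannot collide
  # with a generator that consumed the same user seed upstream
  perm_seed <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, 2)[2])
  perm_p <- withr::with_seed(perm_seed, {
    vapply(seq_len(n_perm), function(b) {
      in_sig <- logical(U)
      in_sig[sample.int(U, sig_size)] <- TRUE
      ov <- vapply(member_idx, function(ix) sum(in_sig[ix]), integer(1))
      phyper(ov - 1, set_sizes, U - set_sizes, sig_size,
             lower.tail = FALSE)
    }, numeric(length(member_idx)))
  })
  pooled <- sort(as.vector(perm_p))
  obs$fdr <- vapply(obs$p_hyper, function(p) {
    null_hits <- findInterval(p, pooled) / n_perm
    obs_hits <- sum(obs$p_hyper <= p)
    min(1, null_hits / obs_hits)
  }, numeric(1))
  obs$significant <- obs$fdr < fdr_threshold
  obs
}
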