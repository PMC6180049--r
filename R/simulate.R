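# Normal(mean, sd) conditioned on being positive, by inverse CDF (exact,
# one uniform per draw, so deterministic under a seed).
rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= 0) stop("effect distribution has no positive mass")
    return(rep(mean, n))
  }
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, lo, 1), mean, sd)
}

#' Simulate a multi-study case/control expression cohort with planted
#' differential genes
#'
#' Generates a log2-like normalized expression matrix for a two-group
#' cohort assembled from several studies, with a planted set of up- and
#' down-regulated genes. Background expression is Gaussian noise; each
#' planted gene receives a fixed additive shift of its case mean, with
#' magnitude drawn once per gene from a truncated normal; each sample is
#' assigned a study uniformly at random and every (study, gene) pair gets
#' an additive batch offset shared by all samples of that study.
#'
#' Defaults describe the scaled study cohort used throughout the package's
#' tests: 2,000 genes, 200 + 200 samples, 200 genes planted in each
#' direction with a heavy-tailed effect spectrum (mean 1.5, sd 2.0 on the
#' log2 scale, truncated at zero), unit noise, and five studies with mild
#' additive batch structure.
#'
#' @param n_genes number of genes.
#' @param n_case,n_control group sizes.
#' @param n_up,n_down numbers of planted up- and down-regulated genes
#'   (disjoint; \code{n_up + n_down <= n_genes}).
#' @param effect_mean,effect_sd location and scale of the planted log2
#'   effect magnitude, drawn from Normal(effect_mean, effect_sd) truncated
#'   at zero.
#' @param noise_sd sd of the background Gaussian noise.
#' @param n_studies number of studies samples are assigned to.
#' @param batch_sd sd of the additive per-(study, gene) batch offsets.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A list with elements \code{matrix} (an
#'   \code{\link{expression_matrix}}) and \code{truth} (class
#'   \code{"SimulationTruth"}: planted gene sets, signed effect sizes,
#'   batch offsets, all gene IDs, and the seed).
#' @examples
#' sim <- simulate_expression(n_genes = 100, n_case = 10, n_control = 10,
#'                            n_up = 5, n_down = 5, seed = 1)
#' sim$matrix
#' @export
simulate_expression <- function(n_genes = 2000, n_case = 200, n_control = 200,
                                n_up = 200, n_down = 200,
                                effect_mean = 1.5, effect_sd = 2.0,
                                noise_sd = 1.0, n_studies = 5,
                                batch_sd = 0.25, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1,
            n_up >= 0, n_down >= 0, n_studies >= 1,
            noise_sd >= 0, batch_sd >= 0, effect_sd >= 0)
  if (n_up + n_down > n_genes)
    stop("n_up + n_down exceeds n_genes")
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    samples <- c(sprintf("case_%0*d", nchar(n_case), seq_len(n_case)),
                 sprintf("ctrl_%0*d", nchar(n_control), seq_len(n_control)))
    group <- rep(c("case", "control"), c(n_case, n_control))
    n <- n_case + n_control
    vals <- matrix(rnorm(n_genes * n, 0, noise_sd), n_genes, n,
                   dimnames = list(genes, samples))
    planted <- sample(n_genes, n_up + n_down)
    up_idx <- planted[seq_len(n_up)]
    down_idx <- planted[n_up + seq_len(n_down)]
    eff_up <- rtruncnorm_pos(n_up, effect_mean, effect_sd)
    eff_down <- rtruncnorm_pos(n_down, effect_mean, effect_sd)
    case_cols <- which(group == "case")
    if (n_up)
      vals[up_idx, case_cols] <- vals[up_idx, case_cols] + eff_up
    if (n_down)
      vals[down_idx, case_cols] <- vals[down_idx, case_cols] - eff_down
    study <- sprintf("study%d", sample.int(n_studies, n, replace = TRUE))
    offsets <- matrix(rnorm(n_genes * n_studies, 0, batch_sd),
                      n_genes, n_studies,
                      dimnames = list(genes, sprintf("study%d",
                                                     seq_len(n_studies))))
    vals <- vals + offsets[, study]
    effect_sizes <- setNames(c(eff_up, -eff_down),
                             genes[c(up_idx, down_idx)])
    truth <- structure(list(de_genes_up = genes[up_idx],
                            de_genes_down = genes[down_idx],
                            effect_sizes = effect_sizes,
                            batch_offsets = offsets,
                            genes = genes,
                            seed = as.integer(seed)),
                       class = "SimulationTruth")
    list(matrix = expression_matrix(vals, group, study), truth = truth)
  })
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("SimulationTruth: %d genes, %d up + %d down planted, seed %d\n",
              length(x$genes), length(x$de_genes_up),
              length(x$de_genes_down), x$seed))
  invisible(x)
}

#' Simulate right-censored survival times from a proportional-hazards model
#'
#' Event times are exponential with rate
#' \code{baseline_rate * exp(x' beta)}; an independent exponential
#' censoring time with rate \code{censor_rate} is drawn per subject, the
#' observed time is the minimum and the event indicator marks whether the
#' event preceded censoring. \code{censor_rate = 0} disables censoring.
#'
#' @param n number of subjects; must match \code{nrow(covariates)} if
#'   covariates are supplied.
#' @param covariates optional numeric matrix or data.frame (subjects x
#'   covariates).
#' @param coefs numeric vector of planted log-hazard coefficients, aligned
#'   to the covariate columns.
#' @param baseline_rate baseline hazard rate (> 0).
#' @param censor_rate censoring hazard rate (>= 0).
#' @param seed integer seed.
#' @return A data.frame (class \code{"survival_table"}) with columns
#'   \code{sample_id}, \code{time}, \code{event} and the covariates, and a
#'   \code{"coefs"} attribute holding the planted coefficients.
#' @export
simulate_survival <- function(n, covariates = NULL, coefs = NULL,
                              baseline_rate = 0.1, censor_rate = 0.05,
                              seed) {
  if (missing(seed)) stop("`seed` is required")
  if (baseline_rate <= 0) stop("`baseline_rate` must be positive")
  if (censor_rate < 0) stop("`censor_rate` must be non-negative")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("`covariates` must have `n` rows")
    if (is.null(coefs) || length(coefs) != ncol(covariates))
      stop("`coefs` must align with the covariate columns")
  }
  withr::with_seed(as.integer(seed), {
    lp <- if (is.null(covariates)) rep(0, n)
          else as.vector(covariates %*% coefs)
    event_time <- rexp(n, rate = baseline_rate * exp(lp))
    censor_time <- if (censor_rate > 0) rexp(n, rate = censor_rate)
                   else rep(Inf, n)
    out <- data.frame(sample_id = sprintf("s%0*d", nchar(n), seq_len(n)),
                      time = pmin(event_time, censor_time),
                      event = as.integer(event_time <= censor_time),
                      stringsAsFactors = FALSE)
    if (!is.null(covariates)) {
      cn <- colnames(covariates)
      if (is.null(cn)) cn <- sprintf("x%d", seq_len(ncol(covariates)))
      out[cn] <- as.data.frame(covariates)
    }
    attr(out, "coefs") <- coefs
    attr(out, "time_unit") <- "months"
    class(out) <- c("survival_table", "data.frame")
    out
  })
}

#' Simulate a protein-interaction edge list with planted hubs
#'
#' Each of the first \code{n_hubs} nodes is connected to \code{hub_degree}
#' distinct random partners; every remaining unordered pair is edged
#' independently with probability \code{background_edge_prob}. Combined
#' scores are drawn uniformly from [0.4, 1], i.e. all edges clear the
#' conventional medium-confidence cutoff.
#'
#' @param n_nodes number of nodes.
#' @param n_hubs number of planted hub nodes.
#' @param hub_degree planted hub degree (\code{< n_nodes}).
#' @param background_edge_prob background edge probability.
#' @param seed integer seed.
#' @return A data.frame with columns \code{node_a}, \code{node_b},
#'   \code{combined_score}, plus a \code{"hub_nodes"} attribute naming the
#'   planted hubs.
#' @export
simulate_ppi <- function(n_nodes, n_hubs = 1, hub_degree = 10,
                         background_edge_prob = 0.01, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_nodes >= 2, n_hubs >= 0, hub_degree >= 1,
            background_edge_prob >= 0, background_edge_prob <= 1)
  if (hub_degree >= n_nodes)
    stop("`hub_degree` must be smaller than `n_nodes`")
  withr::with_seed(as.integer(seed), {
    nodes <- sprintf("node%0*d", nchar(n_nodes), seq_len(n_nodes))
    hubs <- nodes[seq_len(n_hubs)]
    a <- character(0); b <- character(0)
    for (h in seq_len(n_hubs)) {
      partners <- sample(setdiff(seq_len(n_nodes), h), hub_degree)
      a <- c(a, rep(nodes[h], hub_degree))
      b <- c(b, nodes[partners])
    }
    if (background_edge_prob > 0) {
      pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
      hit <- rbinom(nrow(pairs), 1, background_edge_prob) == 1
      a <- c(a, nodes[pairs[hit, 1]])
      b <- c(b, nodes[pairs[hit, 2]])
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi, sep = "\r"))
    lo <- lo[keep]; hi <- hi[keep]
    out <- data.frame(node_a = lo, node_b = hi,
                      combined_score = runif(length(lo), 0.4, 1.0),
                      stringsAsFactors = FALSE)
    attr(out, "hub_nodes") <- hubs
    out
  })
}

#' Simulate a gene-set collection containing the planted signature
#'
#' Builds a collection holding the planted up-regulated genes as one set,
#' the planted down-regulated genes as another, and \code{n_decoy_sets}
#' random decoy sets drawn from the simulated gene universe. Used to
#' exercise the over-representation machinery against a known answer.
#'
#' @param truth a \code{SimulationTruth} from
#'   \code{\link{simulate_expression}}.
#' @param n_decoy_sets number of random decoy sets.
#' @param set_size size of each decoy set.
#' @param seed integer seed.
#' @return A \code{GeneSetCollection}.
#' @export
simulate_gene_sets <- function(truth, n_decoy_sets = 50, set_size = 50,
                               seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(inherits(truth, "SimulationTruth"))
  if (set_size > length(truth$genes))
    stop("`set_size` exceeds the number of genes")
  withr::with_seed(as.integer(seed), {
    sets <- list(planted_up = truth$de_genes_up,
                 planted_down = truth$de_genes_down)
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy%03d", i)]] <- sample(truth$genes, set_size)
    }
    desc <- setNames(c("planted up-regulated genes",
                       "planted down-regulated genes",
                       rep("random decoy set", n_decoy_sets)),
                     names(sets))
    gene_set_collection(sets, desc)
  })
}
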