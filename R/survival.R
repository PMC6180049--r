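#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), where d_i is
#' the number of events and n_i the number at risk at t_i. Censored
#' subjects leave the risk set without contributing a factor.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event observed, 0 = censored).
#' @return An object of class \code{"km_curve"}: list with \code{time}
#'   (distinct event times, ascending), \code{surv}, \code{n_risk},
#'   \code{n_event}.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (length(times) != length(events))
    stop("`times` and `events` must have equal length")
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survfit(Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep],
                 surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep]),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times, S(last) = %.3f\n",
              length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Median split into high and low expression groups
#'
#' High means value >= median (the standard midpoint median), low means
#' value < median. If every value is identical the split is degenerate:
#' all samples are high and a warning is emitted.
#'
#' @param values numeric vector (n >= 2).
#' @return Factor with levels \code{low}, \code{high}, same length and
#'   names as \code{values}; the cutoff is attached as attribute
#'   \code{"cutoff"}.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  med <- median(values)
  if (all(values == values[1]))
    warning("all values identical; every sample assigned to 'high'")
  out <- factor(ifelse(values >= med, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(values)
  attr(out, "cutoff") <- med
  out
}

#' Two-group log-rank test
#'
#' The classical test: at each distinct event time the observed number of
#' events in group 1 is compared with its hypergeometric expectation given
#' the risk sets, and the standardized sum of differences is referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level grouping vector; both groups must be
#'   non-empty.
#' @return List with \code{chi_square}, \code{p}, \code{observed} and
#'   \code{expected} events in the first group.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2)
    stop("exactly 2 non-empty groups required (got ", nlevels(groups), ")")
  if (length(unique(c(length(times), length(events), length(groups)))) != 1)
    stop("times, events and groups must have equal length")
  g1 <- groups == levels(groups)[1]
  event_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (tt in event_times) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi,
       p = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Multivariate proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson (via
#' \code{\link[survival]{coxph}}), with Breslow tie handling by default
#' (Efron available). Reports, per covariate, the coefficient, its
#' standard error from the observed information, the hazard ratio
#' exp(coefficient), the two-sided Wald p-value, and the 95% confidence
#' interval exp(coefficient -/+ 1.96 se).
#'
#' @param covariates numeric matrix or data.frame (subjects x covariates);
#'   no covariate may be constant.
#' @param times non-negative follow-up times.
#' @param events event indicators; at least as many events as covariates.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param max_iter Newton-Raphson iteration cap.
#' @param tol convergence tolerance.
#' @return An object of class \code{"cox_fit"}: a data.frame with columns
#'   \code{term}, \code{coefficient}, \code{se}, \code{hazard_ratio},
#'   \code{p}, \code{ci_low}, \code{ci_high}; attributes \code{score}
#'   (score test statistic at beta = 0), \code{iter}, \code{loglik}.
#' @export
cox_fit <- function(covariates, times, events,
                    ties = c("breslow", "efron"),
                    max_iter = 25, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (nrow(X) != length(times) || length(times) != length(events))
    stop("covariates, times and events must agree in length")
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(X)[const], collapse = ", "))
  if (sum(events) < ncol(X))
    stop("fewer events (", sum(events), ") than covariates (", ncol(X), ")")
  dat <- data.frame(.time = times, .event = events, X, check.names = FALSE)
  fit <- coxph(Surv(.time, .event) ~ ., data = dat, ties = ties,
               control = coxph.control(iter.max = max_iter, eps = tol))
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    warning("monotone partial likelihood suspected: ",
            "some coefficient estimates are extreme or non-finite")
  co <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(co),
                    coefficient = unname(co),
                    se = unname(se),
                    hazard_ratio = exp(unname(co)),
                    p = 2 * pnorm(-abs(unname(co) / unname(se))),
                    ci_low = exp(unname(co) - 1.96 * unname(se)),
                    ci_high = exp(unname(co) + 1.96 * unname(se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "score") <- unname(fit$score)
  attr(out, "iter") <- fit$iter
  attr(out, "loglik") <- fit$loglik
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Coefficient-weighted risk score with median-cutoff stratification
#'
#' The per-sample risk score is the linear predictor
#' sum over genes of coefficient_g * expression_g. Samples at or above
#' the median score form the high-risk group, the rest the low-risk
#' group; if survival data are supplied the two groups are compared by
#' log-rank.
#'
#' @param fit a \code{cox_fit} (terms are gene symbols) or a named numeric
#'   vector of gene coefficients.
#' @param x an \code{\link{expression_matrix}} (or genes x samples
#'   matrix) containing every scored gene.
#' @param times,events optional survival data for the log-rank comparison
#'   of the two risk groups.
#' @return An object of class \code{"risk_model"}: list with
#'   \code{coefficients}, \code{score} (named per-sample), \code{cutoff}
#'   (median score), \code{group} (factor low/high) and \code{logrank}
#'   (or NULL).
#' @export
risk_model <- function(fit, x, times = NULL, events = NULL) {
  coefs <- if (inherits(fit, "cox_fit"))
    setNames(fit$coefficient, fit$term)
  else fit
  if (is.null(names(coefs)))
    stop("coefficients must be named by gene symbol")
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  missing <- setdiff(names(coefs), rownames(v))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  score <- as.vector(coefs %*% v[names(coefs), , drop = FALSE])
  names(score) <- colnames(v)
  cutoff <- median(score)
  if (all(score == score[1]))
    warning("degenerate risk split: all scores identical")
  group <- factor(ifelse(score >= cutoff, "high", "low"),
                  levels = c("low", "high"))
  names(group) <- colnames(v)
  lr <- NULL
  if (!is.null(times) && !is.null(events) && nlevels(droplevels(group)) == 2)
    lr <- logrank_test(times, events, group)
  structure(list(coefficients = coefs, score = score, cutoff = cutoff,
                 group = group, logrank = lr),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model: %d genes, median cutoff %.3f (%d high / %d low)\n",
              length(x$coefficients), x$cutoff,
              sum(x$group == "high"), sum(x$group == "low")))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank chi-square %.2f, p = %.3g\n",
                x$logrank$chi_square, x$logrank$p))
  invisible(x)
}

#' Univariate median-split prognostic screen
#'
#' For each gene, samples are split at the median expression into high
#' and low groups and the two survival curves are compared by log-rank.
#' No multiple-testing correction is applied; this mirrors the common
#' single-gene screening practice where genes at p < 0.05 are carried
#' into a multivariate model.
#'
#' @param x an \code{\link{expression_matrix}} (samples must match the
#'   survival data order).
#' @param times,events survival data, one entry per sample of \code{x}.
#' @param genes optional subset of genes to screen (default all).
#' @return A data.frame \code{(gene, cutoff, chi_square, p)}, ascending
#'   in p.
#' @export
prognostic_screen <- function(x, times, events, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    genes <- signature_genes(genes)
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) != length(times))
    stop("survival data must cover every sample")
  rows <- lapply(rownames(v), function(g) {
    split <- suppressWarnings(median_split(v[g, ]))
    if (nlevels(droplevels(split)) < 2)
      return(data.frame(gene = g, cutoff = attr(split, "cutoff"),
                        chi_square = NA_real_, p = NA_real_))
    lr <- logrank_test(times, events, split)
    data.frame(gene = g, cutoff = attr(split, "cutoff"),
               chi_square = lr$chi_square, p = lr$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
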