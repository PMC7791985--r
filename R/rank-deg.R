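#' Find stable gene pairs in control samples
#'
#' A stable pair is an ordered pair of genes (low, high) whose within-sample
#' ordering `expr(low) < expr(high)` holds in at least a fraction
#' `min_consistency` of the control samples. Ties count against
#' consistency, and at most one orientation of an unordered pair is kept
#' (at the degenerate threshold 0.5 where both orientations could qualify,
#' neither is kept). Because only within-sample comparisons are used, the
#' pair set is invariant under any strictly increasing per-sample transform
#' of the data — the property that makes the downstream test robust to
#' batch effects and normalisation choices.
#'
#' @param controls an `expr_matrix` of control samples (>= 2 samples),
#'   already restricted to the integrated gene universe.
#' @param min_consistency required consistency fraction in \[0.5, 1\];
#'   default 0.99.
#' @return An object of class `stable_pair_set`: list with integer vectors
#'   `low`, `high` (indices into `genes`), the `genes` character vector,
#'   `min_consistency`, and `n_controls`.
#' @export
find_stable_pairs <- function(controls, min_consistency = 0.99) {
  stopifnot(inherits(controls, "expr_matrix"))
  if (min_consistency < 0.5 || min_consistency > 1) {
    stop("min_consistency must be in [0.5, 1]", call. = FALSE)
  }
  v <- controls$values
  n <- ncol(v)
  if (n < 2) stop("need at least 2 control samples for stable pairs",
                  call. = FALSE)
  g <- nrow(v)
  # counts[a, b] = number of controls with expr(a) < expr(b); ties count
  # toward neither orientation
  counts <- matrix(0L, g, g)
  for (j in seq_len(n)) {
    counts <- counts + outer(v[, j], v[, j], "<")
  }
  need <- min_consistency * n
  ok <- counts >= need & counts > t(counts)
  idx <- which(ok, arr.ind = TRUE, useNames = FALSE)
  structure(list(low = idx[, 1], high = idx[, 2],
                 genes = rownames(v),
                 min_consistency = min_consistency,
                 n_controls = n),
            class = "stable_pair_set")
}

#' @export
print.stable_pair_set <- function(x, ...) {
  cat("stable_pair_set: ", length(x$low), " pairs over ",
      length(x$genes), " genes (consistency >= ", x$min_consistency,
      " in ", x$n_controls, " controls)\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher exact p for reversal 2x2 tables, vectorised
#'
#' For each gene the table is `[[u, U-u], [d, D-d]]`: reversed versus
#' preserved stable pairs, stratified by whether the gene sits on the low
#' or high side of the pair in controls. The two-sided p sums, over all
#' tables with the observed margins, the hypergeometric probabilities not
#' exceeding that of the observed table (the same definition
#' `stats::fisher.test` uses). Values are floored at the smallest positive
#' double.
#'
#' @param u,U,d,D integer vectors of equal length: reversals supporting
#'   up-regulation out of `U` low-side pairs, and supporting
#'   down-regulation out of `D` high-side pairs.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
fisher_reversal_p <- function(u, U, d, D) {
  stopifnot(length(u) == length(U), length(d) == length(D),
            length(u) == length(d))
  if (any(u > U) || any(d > D) || any(u < 0) || any(d < 0)) {
    stop("need 0 <= u <= U and 0 <= d <= D", call. = FALSE)
  }
  k <- u + d                       # column margin (total reversals)
  lo <- pmax(0L, k - D)
  hi <- pmin(k, U)
  len <- hi - lo + 1L
  idx <- rep.int(seq_along(u), len)
  xs <- sequence(len) - 1L + rep.int(lo, len)
  dens <- stats::dhyper(xs, U[idx], D[idx], k[idx])
  obs <- stats::dhyper(u, U, D, k)
  keep <- dens <= obs[idx] * (1 + 1e-7)
  # every index appears (len >= 1), so rowsum rows align with 1..n
  p <- unname(rowsum(dens * keep, idx, reorder = TRUE)[, 1])
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Per-sample reversal test for every gene
#'
#' Scores one disease sample against the control stable-pair background.
#' For each gene, `u` of its `U` low-side pairs are reversed (the gene now
#' exceeds its partner: evidence for up-regulation) and `d` of its `D`
#' high-side pairs are reversed (evidence for down-regulation); ties in the
#' disease sample are not counted as reversals. Fisher's exact test asks
#' whether up- and down-supporting reversals are balanced; direction is the
#' side with the larger reversal rate. Significance is flagged by
#' Benjamini-Hochberg within the sample at `sample_fdr`. Genes with no
#' stable partners are untestable (p = 1, direction "none").
#'
#' @param sample_values numeric vector of expression values named by, or
#'   ordered as, `pairs$genes`.
#' @param pairs a `stable_pair_set`.
#' @param sample_fdr within-sample BH level for the `significant` flag.
#' @return data.frame with columns `gene`, `u`, `U`, `d`, `D`, `fisher_p`,
#'   `direction` (`"up"`, `"down"`, `"none"`), `significant`, `testable`.
#' @export
sample_reversal_test <- function(sample_values, pairs, sample_fdr = 0.05) {
  g <- length(pairs$genes)
  if (!is.null(names(sample_values))) {
    if (!all(pairs$genes %in% names(sample_values))) {
      stop("sample does not cover all genes in the stable-pair set",
           call. = FALSE)
    }
    sample_values <- sample_values[pairs$genes]
  } else if (length(sample_values) != g) {
    stop("unnamed sample vector must match the pair set's gene count",
         call. = FALSE)
  }
  x <- as.numeric(sample_values)
  rev_pair <- x[pairs$low] > x[pairs$high]
  U <- tabulate(pairs$low, nbins = g)
  D <- tabulate(pairs$high, nbins = g)
  u <- tabulate(pairs$low[rev_pair], nbins = g)
  d <- tabulate(pairs$high[rev_pair], nbins = g)
  p <- fisher_reversal_p(u, U, d, D)
  testable <- (U + D) > 0L
  p[!testable] <- 1
  up_rate <- ifelse(U > 0L, u / U, 0)
  down_rate <- ifelse(D > 0L, d / D, 0)
  direction <- rep("none", g)
  direction[testable & up_rate > down_rate] <- "up"
  direction[testable & down_rate > up_rate] <- "down"
  q <- bh_adjust(p)
  data.frame(gene = pairs$genes, u = u, U = U, d = d, D = D,
             fisher_p = p, direction = direction,
             significant = q < sample_fdr & direction != "none",
             testable = testable,
             stringsAsFactors = FALSE)
}

#' Reversal calls for all disease samples
#'
#' Applies [sample_reversal_test()] to each column of a disease-sample
#' matrix and collects the per-gene, per-sample calls.
#'
#' @param cases an `expr_matrix` of disease samples on the same gene
#'   universe as `pairs`.
#' @param pairs a `stable_pair_set`.
#' @param sample_fdr within-sample BH level.
#' @return A list of class `sample_call_table`: `genes`, `samples`,
#'   `direction` (gene x sample character matrix), `significant` (logical
#'   matrix), `fisher_p` (numeric matrix).
#' @export
reversal_calls <- function(cases, pairs, sample_fdr = 0.05) {
  stopifnot(inherits(cases, "expr_matrix"), inherits(pairs, "stable_pair_set"))
  if (!all(pairs$genes %in% genes(cases))) {
    stop("case matrix does not cover the stable-pair gene universe",
         call. = FALSE)
  }
  v <- cases$values[pairs$genes, , drop = FALSE]
  m <- ncol(v)
  g <- length(pairs$genes)
  dir_mat <- matrix("none", g, m, dimnames = list(pairs$genes, colnames(v)))
  sig_mat <- matrix(FALSE, g, m, dimnames = dimnames(dir_mat))
  p_mat <- matrix(1, g, m, dimnames = dimnames(dir_mat))
  for (j in seq_len(m)) {
    res <- sample_reversal_test(v[, j], pairs, sample_fdr = sample_fdr)
    dir_mat[, j] <- res$direction
    sig_mat[, j] <- res$significant
    p_mat[, j] <- res$fisher_p
  }
  structure(list(genes = pairs$genes, samples = colnames(v),
                 direction = dir_mat, significant = sig_mat,
                 fisher_p = p_mat),
            class = "sample_call_table")
}

#' Subpopulation-level DEG test
#'
#' Counts, per gene and direction, the disease samples that called it
#' significantly in that direction, takes the direction with the larger
#' support (ties excluded), and tests the support count against a binomial
#' null: `binom_p = P(X >= k)` with `X ~ Binomial(m, null_rate)`.
#' Benjamini-Hochberg across genes flags DEGs at `fdr_threshold`.
#'
#' @param calls a `sample_call_table` from [reversal_calls()].
#' @param null_rate null per-sample call probability (default 0.05, the
#'   per-sample false-call level implied by the within-sample FDR).
#' @param fdr_threshold BH threshold for `is_deg` (default 0.05).
#' @return data.frame of class `deg_table` with columns `gene`, `direction`
#'   (`"up"`, `"down"`, or `NA` for ties), `k_support`, `m_samples`,
#'   `binom_p`, `bh_q`, `is_deg`.
#' @export
population_deg_test <- function(calls, null_rate = 0.05, fdr_threshold = 0.05) {
  stopifnot(inherits(calls, "sample_call_table"))
  if (null_rate <= 0 || null_rate >= 1) {
    stop("null_rate must be in (0, 1)", call. = FALSE)
  }
  m <- length(calls$samples)
  if (m < 1) stop("need at least one disease sample", call. = FALSE)
  k_up <- rowSums(calls$significant & calls$direction == "up")
  k_down <- rowSums(calls$significant & calls$direction == "down")
  if (any(k_up + k_down > m)) stop("support counts exceed sample count",
                                   call. = FALSE)
  k <- pmax(k_up, k_down)
  direction <- ifelse(k_up > k_down, "up",
                      ifelse(k_down > k_up, "down", NA_character_))
  binom_p <- stats::pbinom(k - 1L, m, null_rate, lower.tail = FALSE)
  binom_p <- pmin(pmax(binom_p, .Machine$double.xmin), 1)
  bh_q <- bh_adjust(binom_p)
  out <- data.frame(gene = calls$genes, direction = direction,
                    k_support = k, m_samples = m,
                    binom_p = binom_p, bh_q = bh_q,
                    is_deg = bh_q < fdr_threshold & !is.na(direction),
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`: inputs
#' must be probabilities in (0, 1], and the output preserves input order.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return Adjusted values in (0, 1], same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' One-shot rank-based DEG detection for one case group
#'
#' Convenience wrapper: stable pairs from the controls, reversal calls on
#' the cases, then the subpopulation binomial test.
#'
#' @param cases,controls `expr_matrix` objects on a common gene universe.
#' @param min_consistency stable-pair consistency threshold.
#' @param sample_fdr within-sample BH level for per-sample calls.
#' @param null_rate binomial null per-sample call probability.
#' @param fdr_threshold BH threshold for the final DEG flag.
#' @return A `deg_table` (see [population_deg_test()]); the stable-pair set
#'   and per-sample calls are attached as attributes `pairs` and `calls`.
#' @export
rankcomp_deg <- function(cases, controls, min_consistency = 0.99,
                         sample_fdr = 0.05, null_rate = 0.05,
                         fdr_threshold = 0.05) {
  common <- intersect(genes(cases), genes(controls))
  if (!length(common)) stop("cases and controls share no genes", call. = FALSE)
  common <- sort(common)
  pairs <- find_stable_pairs(subset_genes(controls, common), min_consistency)
  calls <- reversal_calls(subset_genes(cases, common), pairs,
                          sample_fdr = sample_fdr)
  degs <- population_deg_test(calls, null_rate = null_rate,
                              fdr_threshold = fdr_threshold)
  attr(degs, "pairs") <- pairs
  attr(degs, "calls") <- calls
  degs
}
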