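#' Group summary for effect-size estimation
#'
#' @param x numeric vector of log2 expression values for one group.
#' @return A list of class `group_summary` with `mean`, `variance`
#'   (unbiased, n-1 denominator), and `n`.
#' @export
group_summary <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need n >= 2 per group", call. = FALSE)
  structure(list(mean = mean(x), variance = stats::var(x), n = length(x)),
            class = "group_summary")
}

#' Heteroscedastic standardized effect size (Kulinskaya)
#'
#' For two normal groups with unequal variances, the standardized mean
#' difference is `delta = (mu_i - mu_j) / sigma` with
#' `sigma^2 = (q * s_i^2 + (1-q) * s_j^2) / (q * (1-q))`, `q = n_j / n`,
#' `n = n_i + n_j`. Equivalently `sigma^2 / n = s_i^2/n_i + s_j^2/n_j`, so
#' `sqrt(n) * delta` is exactly the Welch t statistic.
#'
#' @param group_i,group_j [group_summary()] objects (i is conventionally
#'   the metastasis group, j the control group).
#' @return A list of class `effect_size_result`: `delta`, `pooled_sigma`,
#'   `q`, `n`, `t_welch`, and `infinite` (TRUE when both variances are zero
#'   but the means differ, in which case `delta` is a signed `Inf`
#'   sentinel).
#' @export
kulinskaya_delta <- function(group_i, group_j) {
  stopifnot(inherits(group_i, "group_summary"), inherits(group_j, "group_summary"))
  if (group_i$n < 2 || group_j$n < 2) stop("need n >= 2 per group", call. = FALSE)
  n <- group_i$n + group_j$n
  q <- group_j$n / n
  num <- group_i$mean - group_j$mean
  s2 <- (q * group_i$variance + (1 - q) * group_j$variance) / (q * (1 - q))
  if (s2 == 0) {
    if (num == 0) {
      delta <- 0
      infinite <- FALSE
    } else {
      delta <- sign(num) * Inf
      infinite <- TRUE
    }
    sigma <- 0
  } else {
    sigma <- sqrt(s2)
    delta <- num / sigma
    infinite <- FALSE
  }
  structure(list(delta = delta, pooled_sigma = sigma, q = q, n = n,
                 t_welch = sqrt(n) * delta, infinite = infinite),
            class = "effect_size_result")
}

#' Per-gene effect sizes between metastasis and control groups
#'
#' Computes the Kulinskaya delta for each requested gene, pooling samples
#' across datasets within each role group. Because absolute intensities
#' are not comparable across arrays (datasets carry additive offsets the
#' rank stage is immune to but means are not), each sample is
#' median-centered first by default.
#'
#' @param mat an `expr_matrix` containing both roles.
#' @param genes_wanted character vector of genes to score.
#' @param center `"median"` (default) to subtract each sample's median
#'   before computing group summaries, or `"none"`.
#' @return data.frame with columns `gene`, `delta`, `t_welch`.
#' @export
effect_sizes <- function(mat, genes_wanted, center = c("median", "none")) {
  center <- match.arg(center)
  stopifnot(inherits(mat, "expr_matrix"))
  missing <- setdiff(toupper(genes_wanted), genes(mat))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  v <- mat$values
  if (center == "median") {
    v <- sweep(v, 2, apply(v, 2, stats::median))
  }
  is_case <- mat$annotations$tissue_role == "metastasis"
  if (!any(is_case) || !any(!is_case)) {
    stop("matrix must contain both metastasis and control samples",
         call. = FALSE)
  }
  vi <- v[toupper(genes_wanted), is_case, drop = FALSE]
  vj <- v[toupper(genes_wanted), !is_case, drop = FALSE]
  res <- lapply(seq_len(nrow(vi)), function(r)
    kulinskaya_delta(group_summary(vi[r, ]), group_summary(vj[r, ])))
  data.frame(gene = toupper(genes_wanted),
             delta = vapply(res, `[[`, numeric(1), "delta"),
             t_welch = vapply(res, `[[`, numeric(1), "t_welch"),
             stringsAsFactors = FALSE)
}

#' Screen a DEG table by effect size
#'
#' Retains DEGs whose standardized effect size between the metastasis and
#' control groups reaches `threshold` in magnitude (boundary inclusive)
#' and whose rank-based direction agrees with the sign of delta; genes
#' with a direction conflict are dropped and counted in the
#' `n_direction_conflict` attribute.
#'
#' @param degs a `deg_table` (rows with `is_deg = TRUE` are screened;
#'   others are dropped).
#' @param mat the integrated `expr_matrix` with the same groups the DEGs
#'   were called on.
#' @param threshold minimum |delta| (default 0.5, a medium effect).
#' @param center passed to [effect_sizes()].
#' @return The filtered `deg_table` with added columns `delta`, `t_welch`;
#'   attributes `n_direction_conflict` and `n_below_threshold` record the
#'   drops.
#' @export
filter_by_effect_size <- function(degs, mat, threshold = 0.5,
                                  center = c("median", "none")) {
  stopifnot(inherits(degs, "deg_table"))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  center <- match.arg(center)
  hits <- degs[degs$is_deg, , drop = FALSE]
  if (!nrow(hits)) {
    out <- cbind(hits, delta = numeric(0), t_welch = numeric(0))
    class(out) <- c("deg_table", "data.frame")
    attr(out, "n_direction_conflict") <- 0L
    attr(out, "n_below_threshold") <- 0L
    return(out)
  }
  es <- effect_sizes(mat, hits$gene, center = center)
  hits$delta <- es$delta
  hits$t_welch <- es$t_welch
  big <- abs(hits$delta) >= threshold
  agree <- (hits$direction == "up" & hits$delta > 0) |
    (hits$direction == "down" & hits$delta < 0)
  out <- hits[big & agree, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  attr(out, "n_direction_conflict") <- sum(big & !agree)
  attr(out, "n_below_threshold") <- sum(!big)
  out
}
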