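#' Univariate Cox screen of a gene list
#'
#' Fits, for each gene separately, a Cox proportional-hazards model of
#' metastasis-free survival on that gene's expression (Efron tie
#' handling), and reports the coefficient and Wald p. Zero-variance genes
#' are skipped with a warning. The summary attributes give the fraction of
#' genes with raw p < 0.05 and with BH-adjusted p < 0.05.
#'
#' @param cohort a `survival_cohort` (see [simulate_survival_cohort()]),
#'   or any list with `patients` (`id`, `time`, `event`) and `expression`
#'   (gene x patient matrix).
#' @param genes_wanted character vector of genes to screen.
#' @param standardize scale each gene to unit SD first (default FALSE).
#' @return data.frame with `gene`, `beta`, `se`, `p`, `q` (BH); attributes
#'   `frac_significant_raw`, `frac_significant_bh`, `skipped` (character
#'   vector of constant genes).
#' @export
univariate_cox_screen <- function(cohort, genes_wanted, standardize = FALSE) {
  pt <- cohort$patients
  if (sum(pt$event) < 2) stop("need at least 2 events", call. = FALSE)
  expr <- cohort$expression
  missing <- setdiff(genes_wanted, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from cohort expression: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  expr <- expr[genes_wanted, pt$id, drop = FALSE]
  surv <- survival::Surv(pt$time, pt$event)
  rows <- vector("list", length(genes_wanted))
  skipped <- character(0)
  for (i in seq_along(genes_wanted)) {
    x <- expr[i, ]
    if (stats::var(x) == 0) {
      skipped <- c(skipped, genes_wanted[i])
      next
    }
    if (standardize) x <- x / stats::sd(x)
    fit <- survival::coxph(surv ~ x, ties = "efron")
    s <- summary(fit)$coefficients
    rows[[i]] <- data.frame(gene = genes_wanted[i], beta = s[1, "coef"],
                            se = s[1, "se(coef)"], p = s[1, "Pr(>|z|)"],
                            stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped constant gene(s): ", paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable gene", call. = FALSE)
  out$q <- bh_adjust(pmin(pmax(out$p, .Machine$double.xmin), 1))
  rownames(out) <- NULL
  attr(out, "frac_significant_raw") <- mean(out$p < 0.05)
  attr(out, "frac_significant_bh") <- mean(out$q < 0.05)
  attr(out, "skipped") <- skipped
  out
}

#' Per-patient risk index
#'
#' Linear combination of gene expression weighted by Cox coefficients:
#' `risk(patient) = sum_g beta_g * expr_g(patient)`.
#'
#' @param betas named numeric vector of per-gene coefficients.
#' @param expression gene x patient matrix covering all of `names(betas)`.
#' @return Named numeric vector of per-patient scores.
#' @export
risk_index <- function(betas, expression) {
  missing <- setdiff(names(betas), rownames(expression))
  if (length(missing)) {
    stop("gene(s) missing from expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(crossprod(expression[names(betas), , drop = FALSE], betas))
}

#' Median-split log-rank test
#'
#' Splits patients at the median risk index (ties to the low-risk group),
#' and compares metastasis-free survival between the groups with the
#' two-group log-rank test.
#'
#' @param scores named per-patient risk scores.
#' @param cohort a cohort with `patients` (`id`, `time`, `event`).
#' @return A list: `group` (factor "low"/"high" per patient), `chisq`,
#'   `logrank_p`, `cutoff`, and `degenerate` (TRUE when all scores are
#'   equal; no test is run then and `logrank_p` is NA).
#' @export
median_split_logrank <- function(scores, cohort) {
  pt <- cohort$patients
  scores <- scores[pt$id]
  if (anyNA(scores)) stop("scores missing for some patients", call. = FALSE)
  cutoff <- stats::median(scores)
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(scores)) == 1 || min(table(group)) < 2) {
    return(list(group = group, chisq = NA_real_, logrank_p = NA_real_,
                cutoff = cutoff, degenerate = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(pt$time, pt$event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(group = group, chisq = sd$chisq, logrank_p = p, cutoff = cutoff,
       degenerate = FALSE)
}

#' Pathway risk models over a signature
#'
#' For each pathway, takes its signature genes, screens them with
#' univariate Cox fits, builds the risk index from the fitted
#' coefficients, and runs the median-split log-rank test — one row per
#' pathway with >= `min_genes` signature genes in the cohort.
#'
#' @param cohort a survival cohort (see [univariate_cox_screen()]).
#' @param signature_genes character vector (e.g. `shared_up` plus
#'   `shared_down` of an `organ_signature`).
#' @param collection a `gene_set_collection`.
#' @param min_genes minimum pathway signature genes (default 2).
#' @return data.frame with `pathway`, `n_genes`, `logrank_p`, `chisq`,
#'   `cutoff`; the per-pathway models (betas, scores, groups) are in the
#'   `models` attribute.
#' @export
pathway_risk_models <- function(cohort, signature_genes, collection,
                                min_genes = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- list(); models <- list()
  for (nm in names(collection)) {
    g <- intersect(collection[[nm]]$members,
                   intersect(signature_genes, rownames(cohort$expression)))
    if (length(g) < min_genes) next
    scr <- suppressWarnings(univariate_cox_screen(cohort, g))
    betas <- stats::setNames(scr$beta, scr$gene)
    score <- risk_index(betas, cohort$expression)
    spl <- median_split_logrank(score, cohort)
    rows[[nm]] <- data.frame(pathway = nm, n_genes = length(betas),
                             logrank_p = spl$logrank_p, chisq = spl$chisq,
                             cutoff = spl$cutoff, stringsAsFactors = FALSE)
    models[[nm]] <- list(betas = betas, scores = score, group = spl$group)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway has enough signature genes", call. = FALSE)
  out <- out[order(out$logrank_p), ]
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Hierarchical clustering of patients on signature genes
#'
#' Agglomerative clustering of patients with 1 - Pearson correlation
#' distance and average linkage by default. Returns the `hclust` tree, a
#' Newick serialisation, flat cluster labels at `k` clusters, and — when a
#' patient label is supplied — a per-cluster Fisher exact enrichment of
#' that label.
#'
#' @param expression gene x patient matrix (>= 2 genes, >= 3 patients).
#' @param k number of flat clusters (default 2).
#' @param distance `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param linkage linkage method for `hclust` (default `"average"`).
#' @param labels optional logical vector (named by patient) marking e.g.
#'   brain-metastasis patients for cluster enrichment.
#' @return A list of class `patient_clustering`: `hclust`, `newick`,
#'   `cluster` (named integer vector), `label_enrichment` (data.frame or
#'   NULL).
#' @export
hierarchical_cluster <- function(expression, k = 2,
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average", labels = NULL) {
  distance <- match.arg(distance)
  if (ncol(expression) < 3 || nrow(expression) < 2) {
    stop("need >= 3 patients and >= 2 genes", call. = FALSE)
  }
  if (distance == "correlation") {
    sds <- apply(expression, 2, stats::sd)
    if (any(sds == 0)) {
      stop("distance degeneracy: constant patient profile(s)", call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(expression))
  } else {
    d <- stats::dist(t(expression))
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  enr <- NULL
  if (!is.null(labels)) {
    labels <- labels[colnames(expression)]
    enr <- do.call(rbind, lapply(sort(unique(cl)), function(ci) {
      inside <- cl == ci
      tab <- matrix(c(sum(labels & inside), sum(labels & !inside),
                      sum(!labels & inside), sum(!labels & !inside)), 2)
      data.frame(cluster = ci, n = sum(inside),
                 n_labeled = sum(labels & inside),
                 fisher_p = stats::fisher.test(tab,
                                               alternative = "greater")$p.value)
    }))
  }
  structure(list(hclust = hc, newick = newick, cluster = cl,
                 label_enrichment = enr),
            class = "patient_clustering")
}

#' Pearson chi-square covariate balance check
#'
#' Tests whether a clinical category (rows/columns of the contingency
#' table) is distributed evenly across groups, without continuity
#' correction. Warns when any expected cell count is below 5.
#'
#' @param table matrix of non-negative counts with positive row and column
#'   margins (2 x c or r x 2).
#' @return A list with `statistic`, `df`, `p`, and `expected_warning`.
#' @export
covariate_balance_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  warn <- any(expected < 5)
  if (warn) warning("expected cell count(s) below 5; chi-square may be inaccurate")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected_warning = warn)
}
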