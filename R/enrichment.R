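#' Hypergeometric enrichment of one gene stratum against a collection
#'
#' For each gene set with at least one member in the universe, tests
#' whether the stratum (e.g. the up-regulated signature genes) contains
#' more set members than expected from random draws:
#' `raw_p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)` with `N` the
#' universe size, `K` the set members in the universe, `n` the stratum
#' size, and `k` the stratum genes in the set. BH adjustment across the
#' tested sets gives the FDR column.
#'
#' @param stratum_genes character vector of genes, a subset of `universe`.
#' @param universe character vector of background genes.
#' @param collection a `gene_set_collection`.
#' @return data.frame with columns `pathway`, `k`, `K`, `n`, `N`,
#'   `raw_p`, `fdr`, `pct` (= 100 k/K), `significant` (fdr < 0.05),
#'   sorted by `raw_p`.
#' @export
hypergeometric_enrichment <- function(stratum_genes, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  stratum_genes <- unique(toupper(stratum_genes))
  universe <- unique(toupper(universe))
  outside <- setdiff(stratum_genes, universe)
  if (length(outside)) {
    stop("stratum gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(stratum_genes)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, stratum_genes))
    data.frame(pathway = nm, k = k, K = K, n = n, N = N,
               raw_p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               pct = 100 * k / K, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe", call. = FALSE)
  out$raw_p <- pmin(pmax(out$raw_p, .Machine$double.xmin), 1)
  out$fdr <- bh_adjust(out$raw_p)
  out$significant <- out$fdr < 0.05
  out <- out[order(out$raw_p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Up/down-stratified enrichment of an organ signature
#'
#' Runs [hypergeometric_enrichment()] separately on the up- and
#' down-regulated shared signature genes and merges the tables
#' (column `stratum`), sorted by stratum then FDR — the layout of the
#' published per-organ pathway tables. The `fdr_display` column renders
#' small FDRs as `"< 0.001"`; full precision stays in `fdr`.
#'
#' @param sig an `organ_signature`.
#' @param collection a `gene_set_collection`.
#' @param universe background gene vector; default
#'   (`"annotated"`) restricts the integrated universe to genes in at
#'   least one set. Pass a character vector to use explicitly.
#' @param universe_genes all integrated-universe genes (required when
#'   `universe = "annotated"` or `"all"`).
#' @param fdr_threshold significance threshold (default 0.05).
#' @return data.frame of class `enrichment_table` with the columns of
#'   [hypergeometric_enrichment()] plus `stratum` and `fdr_display`.
#' @export
run_enrichment <- function(sig, collection, universe = "annotated",
                           universe_genes = NULL, fdr_threshold = 0.05) {
  stopifnot(inherits(sig, "organ_signature"),
            inherits(collection, "gene_set_collection"))
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  if (length(sig$shared_up) + length(sig$shared_down) == 0) {
    stop("signature is empty in both strata", call. = FALSE)
  }
  if (is.character(universe) && length(universe) == 1 &&
      universe %in% c("annotated", "all")) {
    if (is.null(universe_genes)) {
      stop("universe_genes required for universe = '", universe, "'",
           call. = FALSE)
    }
    universe_genes <- toupper(universe_genes)
    bg <- if (universe == "annotated") {
      annotated <- unique(toupper(unlist(lapply(collection, `[[`, "members"))))
      intersect(universe_genes, annotated)
    } else universe_genes
  } else {
    bg <- toupper(universe)
  }
  one <- function(stratum_genes, label) {
    stratum_genes <- intersect(toupper(stratum_genes), bg)
    if (!length(stratum_genes)) return(NULL)
    res <- hypergeometric_enrichment(stratum_genes, bg, collection)
    res$significant <- res$fdr < fdr_threshold
    cbind(stratum = label, res, stringsAsFactors = FALSE)
  }
  out <- rbind(one(sig$shared_up, "up"), one(sig$shared_down, "down"))
  if (is.null(out)) {
    stop("no signature gene falls in the enrichment universe", call. = FALSE)
  }
  out <- out[order(match(out$stratum, c("up", "down")), out$fdr, out$raw_p), ]
  out$fdr_display <- ifelse(out$fdr < 0.001, "< 0.001",
                            formatC(out$fdr, digits = 3, format = "f"))
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
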