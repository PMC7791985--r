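#' Per-origin DEG list for one metastasis site
#'
#' @param degs a `deg_table` of retained DEGs for one origin (typically
#'   after [filter_by_effect_size()]).
#' @param metastasis_site target organ.
#' @param primary_site origin of the metastases.
#' @param universe_size number of genes in the integrated universe.
#' @return A list of class `origin_deg_list`: `metastasis_site`,
#'   `primary_site`, `genes_up`, `genes_down`, `universe_size`.
#' @export
origin_deg_list <- function(degs, metastasis_site, primary_site,
                            universe_size) {
  stopifnot(inherits(degs, "deg_table"))
  up <- sort(degs$gene[degs$is_deg & degs$direction %in% "up"])
  down <- sort(degs$gene[degs$is_deg & degs$direction %in% "down"])
  if (length(intersect(up, down))) {
    stop("a gene cannot be both up and down in one origin", call. = FALSE)
  }
  structure(list(metastasis_site = metastasis_site,
                 primary_site = primary_site,
                 genes_up = up, genes_down = down,
                 universe_size = as.integer(universe_size)),
            class = "origin_deg_list")
}

#' Intersect per-origin DEG lists into an organ signature
#'
#' The organ-specific metastasis signature is the direction-consistent
#' intersection of the per-origin DEG lists against the shared organ
#' controls: `shared_up` is the intersection of every origin's up list,
#' `shared_down` of the down lists. A gene differential in every origin
#' but with conflicting directions is excluded and counted as discordant.
#' Pairwise overlap statistics (on total up+down lists) carry the
#' upper-tail hypergeometric p and the overlap as a percentage of each
#' list and of the shorter list.
#'
#' @param lists list of >= 2 `origin_deg_list` objects sharing
#'   `metastasis_site` and `universe_size`.
#' @return A list of class `organ_signature`: `metastasis_site`,
#'   `origin_lists`, `shared_up`, `shared_down`, `discordant`,
#'   `pairwise_overlap` (data.frame).
#' @export
intersect_deg_lists <- function(lists) {
  if (length(lists) < 2) stop("need at least two origin DEG lists", call. = FALSE)
  stopifnot(all(vapply(lists, inherits, logical(1), "origin_deg_list")))
  sites <- unique(vapply(lists, `[[`, character(1), "metastasis_site"))
  if (length(sites) != 1) {
    stop("origin lists target different metastasis sites: ",
         paste(sites, collapse = ", "), call. = FALSE)
  }
  sizes <- unique(vapply(lists, `[[`, integer(1), "universe_size"))
  if (length(sizes) != 1) {
    stop("origin lists use different gene universes", call. = FALSE)
  }
  shared_up <- sort(Reduce(intersect, lapply(lists, `[[`, "genes_up")))
  shared_down <- sort(Reduce(intersect, lapply(lists, `[[`, "genes_down")))
  totals <- lapply(lists, function(l) union(l$genes_up, l$genes_down))
  shared_total <- Reduce(intersect, totals)
  discordant <- sort(setdiff(shared_total, c(shared_up, shared_down)))

  prim <- vapply(lists, `[[`, character(1), "primary_site")
  combos <- utils::combn(seq_along(lists), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(combos)), function(c_i) {
    i <- combos[1, c_i]; j <- combos[2, c_i]
    m <- length(totals[[i]]); n <- length(totals[[j]])
    k <- length(intersect(totals[[i]], totals[[j]]))
    data.frame(origin_a = prim[i], origin_b = prim[j],
               k = k, m = m, n = n, N = sizes,
               p = overlap_significance(k, m, n, sizes),
               pct_a = 100 * k / m, pct_b = 100 * k / n,
               pct_shorter = 100 * k / min(m, n),
               stringsAsFactors = FALSE)
  }))
  structure(list(metastasis_site = sites, origin_lists = lists,
                 shared_up = shared_up, shared_down = shared_down,
                 discordant = discordant, pairwise_overlap = pw),
            class = "organ_signature")
}

#' @export
print.organ_signature <- function(x, ...) {
  cat("organ_signature for ", x$metastasis_site, ": ",
      length(x$shared_up), " up + ", length(x$shared_down),
      " down shared genes across ", length(x$origin_lists),
      " origin(s); ", length(x$discordant), " discordant\n", sep = "")
  invisible(x)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability that two gene lists of sizes `m` and `n`, drawn from a
#' universe of `N` genes, share at least `k` genes:
#' `P(X >= k)` with `X ~ Hypergeometric(N, m, n)`.
#'
#' @param k observed overlap.
#' @param m,n list sizes.
#' @param N universe size.
#' @param log10_p if TRUE also return the base-10 log of the tail (exact
#'   even when the probability underflows); the return value is then a
#'   list with `p` and `log10_p`.
#' @return The tail probability (or a list, see `log10_p`).
#' @export
overlap_significance <- function(k, m, n, N, log10_p = FALSE) {
  if (any(c(k, m, n, N) < 0) || k > min(m, n) || m > N || n > N) {
    stop("need 0 <= k <= min(m, n) <= N and m, n <= N", call. = FALSE)
  }
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  if (!log10_p) return(p)
  lp <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE, log.p = TRUE)
  list(p = p, log10_p = lp / log(10))
}

#' Overlap percentages the pipeline reports
#'
#' @param k overlap count.
#' @param m,n the two list sizes.
#' @return A list with `pct_a` (= 100k/m), `pct_b` (= 100k/n), and
#'   `pct_shorter` (= 100k/min(m,n)), each also rounded to integer percent
#'   in `*_int`.
#' @export
overlap_percent <- function(k, m, n) {
  if (k > min(m, n)) stop("overlap cannot exceed either list", call. = FALSE)
  pa <- 100 * k / m; pb <- 100 * k / n
  ps <- 100 * k / min(m, n)
  list(pct_a = pa, pct_b = pb, pct_shorter = ps,
       pct_a_int = round(pa), pct_b_int = round(pb),
       pct_shorter_int = round(ps))
}

#' Up/down composition of an organ signature
#'
#' @param sig an `organ_signature`.
#' @return A list with `n_up`, `n_down`, `frac_up`, `frac_down`
#'   (fractions of the shared signature), or `undefined = TRUE` when the
#'   signature is empty.
#' @export
summarize_directions <- function(sig) {
  stopifnot(inherits(sig, "organ_signature"))
  n_up <- length(sig$shared_up); n_down <- length(sig$shared_down)
  tot <- n_up + n_down
  if (tot == 0) {
    return(list(n_up = 0L, n_down = 0L, frac_up = NA_real_,
                frac_down = NA_real_, undefined = TRUE))
  }
  list(n_up = n_up, n_down = n_down,
       frac_up = n_up / tot, frac_down = n_down / tot, undefined = FALSE)
}
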