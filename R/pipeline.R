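#' Run the organ-specific metastasis discovery pipeline
#'
#' Orchestrates the stages end to end for one metastasis site: integrate
#' the input datasets on their common gene universe, detect DEGs per
#' primary origin against the shared controls (stable pairs + per-sample
#' reversal tests + subpopulation binomial test), screen by standardized
#' effect size, intersect the per-origin lists into the organ signature
#' with overlap statistics, run up/down-stratified pathway enrichment,
#' and — when a survival cohort is supplied — validate the signature with
#' pathway risk models.
#'
#' @param matrices list of `expr_matrix` datasets (cases for >= 2 origins
#'   plus controls for the site).
#' @param collection optional `gene_set_collection` for enrichment.
#' @param cohort optional survival cohort for validation.
#' @param params list of stage parameters; see [pipeline_params()].
#' @param out_dir optional directory; when given, every stage table is
#'   written as TSV (plus the report as JSON) so any downstream stage can
#'   be resumed from disk.
#' @return A list of class `pipeline_report`: `params`, `universe_size`,
#'   `origins` (per-origin DEG counts before/after the screen), `signature`
#'   (shared counts, overlap stats, direction fractions), `enrichment`
#'   (table or NULL), `validation` (pathway risk table or NULL), and the
#'   stage objects themselves under `objects`.
#' @export
run_organ_pipeline <- function(matrices, collection = NULL, cohort = NULL,
                               params = pipeline_params(), out_dir = NULL) {
  params <- utils::modifyList(pipeline_params(), params)
  integ <- integrate_datasets(matrices)
  mat <- integ$matrix
  ann <- mat$annotations
  origins <- sort(unique(stats::na.omit(ann$primary_site[ann$tissue_role == "metastasis"])))
  if (length(origins) < 2) {
    stop("pipeline stage 'integrate': need metastasis samples from >= 2 primary origins",
         call. = FALSE)
  }
  site <- unique(stats::na.omit(ann$metastasis_site))
  if (length(site) != 1) {
    stop("pipeline stage 'integrate': expected exactly one metastasis site, got: ",
         paste(site, collapse = ", "), call. = FALSE)
  }
  controls <- samples_by_role(mat, "control")
  pairs <- find_stable_pairs(controls, params$min_consistency)

  origin_summaries <- list()
  deg_lists <- list()
  for (o in origins) {
    cases <- samples_by_role(mat, "metastasis", o)
    calls <- reversal_calls(cases, pairs, sample_fdr = params$sample_fdr)
    degs <- population_deg_test(calls, null_rate = params$null_rate,
                                fdr_threshold = params$fdr)
    group <- subset_samples(mat, c(colnames(cases$values),
                                   colnames(controls$values)))
    screened <- filter_by_effect_size(degs, group,
                                      threshold = params$effect_threshold,
                                      center = params$effect_center)
    deg_lists[[o]] <- origin_deg_list(screened, site, o, integ$universe_size)
    origin_summaries[[o]] <- list(
      n_cases = ncol(cases$values),
      n_deg = sum(degs$is_deg),
      n_after_screen = nrow(screened),
      n_direction_conflict = attr(screened, "n_direction_conflict"),
      n_below_threshold = attr(screened, "n_below_threshold"))
    if (!is.null(out_dir)) {
      write_stage_tsv(degs, file.path(out_dir, paste0("degs_", o, ".tsv")),
                      params)
      write_stage_tsv(screened,
                      file.path(out_dir, paste0("degs_screened_", o, ".tsv")),
                      params)
    }
  }

  sig <- intersect_deg_lists(deg_lists)
  dirs <- summarize_directions(sig)
  pw <- sig$pairwise_overlap
  signature_summary <- list(
    n_shared_up = dirs$n_up, n_shared_down = dirs$n_down,
    n_discordant = length(sig$discordant),
    frac_up = dirs$frac_up, frac_down = dirs$frac_down,
    pairwise_overlap = pw)

  enrich <- NULL
  if (!is.null(collection) && (dirs$n_up + dirs$n_down) > 0) {
    enrich <- tryCatch(
      run_enrichment(sig, collection, universe = params$enrichment_universe,
                     universe_genes = genes(mat),
                     fdr_threshold = params$enrichment_fdr),
      error = function(e) NULL)
    if (!is.null(enrich) && !is.null(out_dir)) {
      write_stage_tsv(enrich, file.path(out_dir, "enrichment.tsv"), params)
    }
  }

  validation <- NULL
  if (!is.null(cohort) && (dirs$n_up + dirs$n_down) > 0 && !is.null(collection)) {
    validation <- tryCatch(
      pathway_risk_models(cohort, c(sig$shared_up, sig$shared_down), collection),
      error = function(e) NULL)
    if (!is.null(validation) && !is.null(out_dir)) {
      write_stage_tsv(validation, file.path(out_dir, "pathway_risk.tsv"), params)
    }
  }

  report <- structure(list(
    params = params,
    metastasis_site = site,
    universe_size = integ$universe_size,
    n_stable_pairs = length(pairs$low),
    origins = origin_summaries,
    signature = signature_summary,
    enrichment = enrich,
    validation = validation,
    objects = list(integrated = integ, pairs = pairs, deg_lists = deg_lists,
                   signature = sig)),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_counts(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Default pipeline parameters
#'
#' @param min_consistency stable-pair consistency threshold (default 0.99).
#' @param sample_fdr within-sample BH level for reversal calls (0.05).
#' @param null_rate binomial null per-sample call rate (0.05).
#' @param fdr BH threshold for subpopulation DEGs (0.05).
#' @param effect_threshold minimum |delta| in the screen (0.5, medium).
#' @param effect_center per-sample centering for effect sizes
#'   (`"median"` or `"none"`).
#' @param enrichment_universe `"annotated"` or `"all"`.
#' @param enrichment_fdr BH threshold for pathways (0.05).
#' @return Named list of parameters.
#' @export
pipeline_params <- function(min_consistency = 0.99, sample_fdr = 0.05,
                            null_rate = 0.05, fdr = 0.05,
                            effect_threshold = 0.5,
                            effect_center = "median",
                            enrichment_universe = "annotated",
                            enrichment_fdr = 0.05) {
  as.list(environment())
}

#' Plain-count view of a pipeline report (JSON-serialisable)
#' @param report a `pipeline_report`.
#' @return Nested list of counts and parameters only.
#' @export
report_counts <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  sig <- report$signature
  list(params = report$params,
       metastasis_site = report$metastasis_site,
       universe_size = report$universe_size,
       n_stable_pairs = report$n_stable_pairs,
       origins = report$origins,
       signature = list(
         n_shared_up = sig$n_shared_up, n_shared_down = sig$n_shared_down,
         n_discordant = sig$n_discordant,
         frac_up = sig$frac_up, frac_down = sig$frac_down,
         pairwise_overlap = sig$pairwise_overlap),
       n_significant_pathways =
         if (!is.null(report$enrichment)) sum(report$enrichment$significant) else NA,
       n_validated_pathways =
         if (!is.null(report$validation))
           sum(report$validation$logrank_p < 0.05, na.rm = TRUE) else NA)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$metastasis_site, "metastasis;",
      x$universe_size, "genes;", x$n_stable_pairs, "stable pairs\n")
  for (o in names(x$origins)) {
    s <- x$origins[[o]]
    cat(sprintf("  origin %-10s %d cases: %d DEGs, %d after effect screen\n",
                o, s$n_cases, s$n_deg, s$n_after_screen))
  }
  cat(sprintf("  signature: %d up + %d down (%d discordant)\n",
              x$signature$n_shared_up, x$signature$n_shared_down,
              x$signature$n_discordant))
  invisible(x)
}

write_stage_tsv <- function(df, path, params) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# metorgan ", utils::packageVersion("metorgan"),
                    "; params: ",
                    paste(names(params), unlist(params), sep = "=",
                          collapse = ", ")), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
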