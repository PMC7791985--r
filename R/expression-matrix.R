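#' Expression matrix with per-sample annotations
#'
#' Light-weight container for a gene-by-sample matrix of log2 expression
#' values together with the per-sample annotation table the pipeline needs
#' (dataset, platform, tissue role, primary and metastasis site).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols,
#'   upper-cased), samples in columns (colnames = sample ids).
#' @param annotations data.frame with one row per sample and columns
#'   `sample_id`, `dataset_id`, `platform_id`, `tissue_role` (one of
#'   `"metastasis"`, `"control"`), `primary_site`, `metastasis_site`.
#'   `primary_site`/`metastasis_site` may be `NA` where not applicable;
#'   control samples must carry a `metastasis_site` (the control organ) and
#'   no `primary_site`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `annotations` (annotations reordered to match the columns).
#' @export
expression_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  annotations <- validate_annotations(annotations, colnames(values))
  structure(list(values = values, annotations = annotations),
            class = "expr_matrix")
}

required_annotation_cols <- c("sample_id", "dataset_id", "platform_id",
                              "tissue_role", "primary_site", "metastasis_site")

validate_annotations <- function(annotations, sample_ids) {
  if (!is.data.frame(annotations)) {
    stop("`annotations` must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(required_annotation_cols, names(annotations))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(annotations$sample_id)) {
    stop("duplicate sample_id in annotations", call. = FALSE)
  }
  missing_samples <- setdiff(sample_ids, annotations$sample_id)
  if (length(missing_samples)) {
    stop("no annotation for sample(s): ",
         paste(utils::head(missing_samples, 5), collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[match(sample_ids, annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  bad_role <- !annotations$tissue_role %in% c("metastasis", "control")
  if (any(bad_role)) {
    stop("tissue_role must be 'metastasis' or 'control' (sample ",
         annotations$sample_id[which(bad_role)[1]], ")", call. = FALSE)
  }
  ctrl <- annotations$tissue_role == "control"
  if (any(ctrl & is.na(annotations$metastasis_site))) {
    stop("control samples must carry metastasis_site (the control organ)",
         call. = FALSE)
  }
  if (any(ctrl & !is.na(annotations$primary_site))) {
    stop("control samples must not carry a primary_site", call. = FALSE)
  }
  annotations
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  datasets: ", paste(unique(x$annotations$dataset_id), collapse = ", "),
      "\n", sep = "")
  tab <- table(x$annotations$tissue_role)
  cat("  roles:    ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Genes of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
genes <- function(x) rownames(x$values)

#' Subset an expression matrix by samples
#'
#' @param x an `expr_matrix`.
#' @param samples character vector of sample ids, or a logical/integer index
#'   into the columns.
#' @return An `expr_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  if (is.character(samples)) {
    missing <- setdiff(samples, colnames(x$values))
    if (length(missing)) {
      stop("unknown sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  v <- x$values[, samples, drop = FALSE]
  expression_matrix(v, x$annotations[x$annotations$sample_id %in% colnames(v), ,
                                     drop = FALSE])
}

#' Subset an expression matrix by genes
#' @param x an `expr_matrix`.
#' @param keep character vector of gene symbols to retain.
#' @return An `expr_matrix` restricted (and row-ordered) to `keep`.
#' @export
subset_genes <- function(x, keep) {
  keep <- toupper(keep)
  missing <- setdiff(keep, rownames(x$values))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(x$values[keep, , drop = FALSE], x$annotations)
}

#' Split an expression matrix into role groups
#'
#' @param x an `expr_matrix`.
#' @param role `"control"` or `"metastasis"`.
#' @param primary_site optional primary site to additionally filter
#'   metastasis samples on.
#' @return An `expr_matrix` with the matching samples.
#' @export
samples_by_role <- function(x, role, primary_site = NULL) {
  ann <- x$annotations
  sel <- ann$tissue_role == role
  if (!is.null(primary_site)) {
    sel <- sel & !is.na(ann$primary_site) & ann$primary_site == primary_site
  }
  if (!any(sel)) {
    stop("no samples with tissue_role '", role, "'",
         if (!is.null(primary_site)) paste0(" and primary_site '", primary_site, "'"),
         call. = FALSE)
  }
  subset_samples(x, ann$sample_id[sel])
}
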