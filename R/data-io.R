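#' Read a gene-by-sample expression TSV with its annotation table
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene symbols in the first column; cells are numeric log2 intensities.
#' Duplicate gene-symbol rows (e.g. multiple probes mapped to one symbol)
#' are collapsed per sample, by the mean by default. The companion
#' annotation TSV must carry one row per sample with columns `sample_id`,
#' `dataset_id`, `platform_id`, `tissue_role`, `primary_site`,
#' `metastasis_site` (empty/NA allowed for the two site columns where not
#' applicable).
#'
#' Lines starting with `#` in either file are treated as comments.
#'
#' @param path path to the expression TSV.
#' @param annotations_path path to the annotation TSV; defaults to
#'   `<path without extension>.annotations.tsv`.
#' @param collapse how to collapse duplicate gene symbols: `"mean"`,
#'   `"median"`, or `"max"`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, annotations_path = NULL,
                                collapse = c("mean", "median", "max")) {
  collapse <- match.arg(collapse)
  if (is.null(annotations_path)) {
    annotations_path <- sub("\\.tsv$", "", path)
    annotations_path <- paste0(annotations_path, ".annotations.tsv")
  }
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (!file.exists(annotations_path)) {
    stop("annotation file not found: ", annotations_path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2) {
    stop("malformed expression TSV header: expected gene column plus >=1 sample",
         call. = FALSE)
  }
  syms <- toupper(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s' (value '%s')",
                 syms[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- syms
  if (anyDuplicated(syms)) {
    fun <- switch(collapse, mean = mean, median = stats::median, max = max)
    num <- do.call(rbind, lapply(split(seq_along(syms), syms), function(idx) {
      apply(num[idx, , drop = FALSE], 2, fun)
    }))
  }
  num <- num[order(rownames(num)), , drop = FALSE]
  ann <- read_annotations_tsv(annotations_path)
  expression_matrix(num, ann)
}

read_annotations_tsv <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  missing_cols <- setdiff(required_annotation_cols, names(ann))
  if (length(missing_cols)) {
    stop("annotation TSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("primary_site", "metastasis_site")) {
    ann[[col]][!nzchar(trimws(ann[[col]])) | ann[[col]] == "NA"] <- NA_character_
  }
  ann
}

#' Write an expression matrix (and its annotations) to TSV
#'
#' Writes `<path>` with a `#` provenance comment line, and the annotation
#' table next to it as `<path without .tsv>.annotations.tsv`. The pair
#' round-trips through [read_expression_tsv()] bit-exactly (values are
#' written with full precision).
#'
#' @param x an `expr_matrix`.
#' @param path output TSV path.
#' @param comment optional extra text for the header comment.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path, comment = NULL) {
  header <- paste0("# metorgan expression matrix",
                   if (!is.null(comment)) paste0("; ", comment))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("gene", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  ann_path <- paste0(sub("\\.tsv$", "", path), ".annotations.tsv")
  ann <- x$annotations
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then one or more member gene symbols (upper-cased on
#' read). Empty member fields are dropped.
#'
#' @param path path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `members` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": expected name, description, >=1 member",
           call. = FALSE)
    }
    nms[i] <- fields[1]
    sets[[i]] <- list(description = fields[2],
                      members = unique(toupper(fields[-(1:2)])))
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in GMT: ", nms[anyDuplicated(nms)],
         call. = FALSE)
  }
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Integrate expression datasets on their common gene universe
#'
#' Restricts every input matrix to the genes detected on all platforms
#' (set intersection of gene lists), orders genes lexicographically, and
#' concatenates the samples. No cross-dataset intensity normalisation is
#' applied: the downstream differential-expression method uses only
#' within-sample orderings, which additive or monotone per-sample
#' distortions cannot change.
#'
#' @param matrices a list of `expr_matrix` objects (>= 1), all on log2 scale.
#' @return A list of class `integrated_dataset` with elements `matrix`
#'   (the combined `expr_matrix`), `source_datasets`, and `universe_size`.
#' @export
integrate_datasets <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix", call. = FALSE)
  stopifnot(all(vapply(matrices, inherits, logical(1), "expr_matrix")))
  common <- Reduce(intersect, lapply(matrices, genes))
  if (!length(common)) {
    stop("integration error: no gene is shared by all datasets", call. = FALSE)
  }
  common <- sort(common)
  all_ids <- unlist(lapply(matrices, function(m) colnames(m$values)))
  if (anyDuplicated(all_ids)) {
    stop("sample ids collide across datasets: ",
         all_ids[anyDuplicated(all_ids)], call. = FALSE)
  }
  values <- do.call(cbind, lapply(matrices, function(m)
    m$values[common, , drop = FALSE]))
  ann <- do.call(rbind, lapply(matrices, function(m) m$annotations))
  mat <- expression_matrix(values, ann)
  structure(list(matrix = mat,
                 source_datasets = unique(ann$dataset_id),
                 universe_size = length(common)),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat("integrated_dataset: ", x$universe_size, " shared genes, ",
      ncol(x$matrix$values), " samples from ",
      length(x$source_datasets), " dataset(s)\n", sep = "")
  invisible(x)
}
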