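#' Simulation configuration for multi-dataset metastasis expression data
#'
#' Describes the generated study: a set of metastasis case groups from
#' several primary origins plus a shared control group for one metastasis
#' site, spread over several "datasets" that emulate distinct microarray
#' platforms (each missing a random fraction of genes) with additive
#' per-dataset batch shifts.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param origins named integer vector: case count per primary origin
#'   (>= 2 origins for signature work).
#' @param n_controls number of control (normal organ tissue) samples.
#' @param n_datasets total number of datasets; each origin occupies its own
#'   dataset and the controls fill the remaining `n_datasets -
#'   length(origins)` dataset(s) (must leave at least one).
#' @param frac_common_deg fraction of genes planted as differential in
#'   every origin (half up, half down).
#' @param frac_private_deg fraction planted as differential in exactly one
#'   origin (per origin; half up, half down).
#' @param effect_size standardized log2 shift of planted genes in case
#'   samples (per-sample noise has unit SD, so this is in noise-SD units).
#' @param batch_shift_sd SD (log2 units) of the additive scalar shift each
#'   dataset applies to all of its values.
#' @param platform_dropout fraction of genes absent from each simulated
#'   platform (drawn independently per dataset).
#' @param baseline_mean,baseline_sd mean and SD (log2 units) of the
#'   per-gene baseline expression levels.
#' @param metastasis_site label of the simulated target organ.
#' @param seed integer seed; every output is a pure function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       origins = c(breast = 30, lung = 30),
                       n_controls = 40,
                       n_datasets = length(origins) + 1,
                       frac_common_deg = 0.10,
                       frac_private_deg = 0.05,
                       effect_size = 1.0,
                       batch_shift_sd = 1.0,
                       platform_dropout = 0.10,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       metastasis_site = "brain",
                       seed = 1L) {
  if (is.null(names(origins)) || any(!nzchar(names(origins)))) {
    stop("`origins` must be a named vector of case counts", call. = FALSE)
  }
  if (any(origins < 1) || n_controls < 2 || n_genes < 10) {
    stop("all sample and gene counts must be positive (>= 2 controls)",
         call. = FALSE)
  }
  if (n_datasets < length(origins) + 1) {
    stop("n_datasets must leave at least one dataset for the controls",
         call. = FALSE)
  }
  fracs <- c(frac_common_deg, frac_private_deg, platform_dropout)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (frac_common_deg + length(origins) * frac_private_deg > 1) {
    stop("config plants more DEGs than there are genes", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-dataset, multi-origin metastasis expression study
#'
#' Per-gene baselines are drawn from a broad normal on the log2 scale;
#' per-sample values add unit-SD Gaussian noise and a dataset-level
#' additive batch shift (a scalar per dataset, so within-sample orderings
#' are untouched). Planted common DEGs are shifted by `+/- effect_size` in
#' the case samples of every origin; private DEGs in the cases of exactly
#' one origin. Each dataset is emitted as its own `expr_matrix` missing a
#' random `platform_dropout` fraction of genes.
#'
#' @param config a [sim_config()].
#' @return A list with `matrices` (list of `expr_matrix`, one per dataset)
#'   and `truth` (class `ground_truth`: `common_up`, `common_down`,
#'   `private` — per-origin list with `up`/`down` —, `batch_shifts`,
#'   and the config).
#' @export
simulate_multibatch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  baseline <- stats::rnorm(g, config$baseline_mean, config$baseline_sd)
  names(baseline) <- gene_ids

  n_common <- round(config$frac_common_deg * g)
  n_private <- round(config$frac_private_deg * g)
  origins <- names(config$origins)
  planted <- sample(gene_ids, n_common + n_private * length(origins))
  common <- planted[seq_len(n_common)]
  common_up <- common[seq_len(floor(n_common / 2))]
  common_down <- setdiff(common, common_up)
  private <- list()
  offset <- n_common
  for (o in origins) {
    idx <- planted[offset + seq_len(n_private)]
    private[[o]] <- list(up = idx[seq_len(floor(n_private / 2))],
                         down = idx[-seq_len(floor(n_private / 2))])
    offset <- offset + n_private
  }

  dataset_names <- c(paste0("ds_", origins),
                     paste0("ds_control_", seq_len(config$n_datasets - length(origins))))
  # scale unit draws so the RNG stream (and hence everything else) is
  # identical across batch_shift_sd settings with the same seed
  batch_shifts <- stats::rnorm(length(dataset_names)) * config$batch_shift_sd
  names(batch_shifts) <- dataset_names
  keep_genes <- lapply(dataset_names, function(d) {
    n_drop <- round(config$platform_dropout * g)
    sort(sample(gene_ids, g - n_drop))
  })
  names(keep_genes) <- dataset_names

  # per-gene case shift for one origin
  shift_for <- function(origin) {
    s <- stats::setNames(numeric(g), gene_ids)
    s[common_up] <- config$effect_size
    s[common_down] <- -config$effect_size
    s[private[[origin]]$up] <- config$effect_size
    s[private[[origin]]$down] <- -config$effect_size
    s
  }

  make_dataset <- function(ds, ids, role, origin = NA_character_) {
    n <- length(ids)
    vals <- matrix(baseline, g, n) +
      matrix(stats::rnorm(g * n), g, n) + batch_shifts[[ds]]
    if (role == "metastasis") vals <- vals + shift_for(origin)
    dimnames(vals) <- list(gene_ids, ids)
    vals <- vals[keep_genes[[ds]], , drop = FALSE]
    ann <- data.frame(sample_id = ids, dataset_id = ds,
                      platform_id = paste0("platform_", ds),
                      tissue_role = role,
                      primary_site = if (role == "metastasis") origin else NA_character_,
                      metastasis_site = config$metastasis_site,
                      stringsAsFactors = FALSE)
    expression_matrix(vals, ann)
  }

  matrices <- list()
  for (o in origins) {
    ds <- paste0("ds_", o)
    ids <- sprintf("%s_case_%02d", o, seq_len(config$origins[[o]]))
    matrices[[ds]] <- make_dataset(ds, ids, "metastasis", o)
  }
  ctrl_ds <- grep("^ds_control_", dataset_names, value = TRUE)
  split_ctrl <- split(seq_len(config$n_controls),
                      rep_len(seq_along(ctrl_ds), config$n_controls))
  for (i in seq_along(ctrl_ds)) {
    ids <- sprintf("control_%02d", split_ctrl[[i]])
    matrices[[ctrl_ds[i]]] <- make_dataset(ctrl_ds[i], ids, "control")
  }

  truth <- structure(list(common_up = sort(common_up),
                          common_down = sort(common_down),
                          private = lapply(private, lapply, sort),
                          batch_shifts = batch_shifts,
                          config = config),
                     class = "ground_truth")
  list(matrices = matrices, truth = truth)
}

#' Build a pathway collection around a simulated ground truth
#'
#' Emits one "planted" pathway drawn from the common DEG set (so a correct
#' pipeline should rank it first in enrichment) plus decoy pathways drawn
#' uniformly from the universe.
#'
#' @param truth a `ground_truth` from [simulate_multibatch()].
#' @param universe character vector of gene symbols to draw decoys from.
#' @param n_decoys number of decoy sets.
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return A `gene_set_collection`; the planted set is named
#'   `"PLANTED_COMMON"`.
#' @export
simulate_gene_sets <- function(truth, universe, n_decoys = 50, set_size = 40,
                               seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  common <- intersect(c(truth$common_up, truth$common_down), universe)
  if (!length(common)) stop("no planted common DEG is in the universe",
                            call. = FALSE)
  planted <- sort(sample(common, min(set_size, length(common))))
  sets <- list(PLANTED_COMMON = list(description = "planted common DEG pathway",
                                     members = planted))
  for (i in seq_len(n_decoys)) {
    sets[[sprintf("DECOY_%03d", i)]] <-
      list(description = "random decoy pathway",
           members = sort(sample(universe, min(set_size, length(universe)))))
  }
  structure(sets, class = "gene_set_collection")
}

#' Simulate a survival validation cohort
#'
#' Patients carry standard-normal expression for `n_genes` genes; a planted
#' signature drives the hazard through a linear predictor
#' `lp = sum(beta_g * expr_g)` with `||beta|| = effect` (so `effect` is the
#' SD of the true log-hazard across patients). Event times are exponential
#' with rate `exp(lp)`; censoring times are uniform on `(0, c_max)` with
#' `c_max` calibrated so the expected censored fraction matches
#' `censoring`. A `subgroup_frac` fraction of patients concordantly
#' over-expresses the signature (mirroring a metastasis-prone subgroup) and
#' is labelled with the target `metastasis_site` when an event occurs.
#'
#' @param n_patients cohort size.
#' @param n_genes genes measured (signature genes included).
#' @param signature_size number of planted signature genes.
#' @param effect SD of the true log-hazard (0 gives a null cohort).
#' @param censoring target censored fraction in (0, 1).
#' @param subgroup_frac fraction of patients in the signature-high subgroup.
#' @param subgroup_shift expression shift of signature genes in that subgroup.
#' @param metastasis_site site label recorded for events in the subgroup.
#' @param seed integer seed.
#' @return A list of class `survival_cohort`: `patients` (data.frame with
#'   `id`, `time`, `event`, `metastasis_site`), `expression` (gene x
#'   patient matrix), and `truth` (signature genes with true betas, and the
#'   subgroup member ids).
#' @export
simulate_survival_cohort <- function(n_patients = 300, n_genes = 200,
                                     signature_size = 20, effect = 1.0,
                                     censoring = 0.5, subgroup_frac = 0.2,
                                     subgroup_shift = 1.0,
                                     metastasis_site = "brain", seed = 1L) {
  if (censoring <= 0 || censoring >= 1) {
    stop("censoring fraction must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  gene_ids <- sprintf("SG%04d", seq_len(n_genes))
  sig <- gene_ids[seq_len(signature_size)]
  betas <- stats::rnorm(signature_size)
  betas <- if (effect > 0) effect * betas / sqrt(sum(betas^2)) else betas * 0
  names(betas) <- sig

  ids <- sprintf("pt_%03d", seq_len(n_patients))
  expr <- matrix(stats::rnorm(n_genes * n_patients), n_genes, n_patients,
                 dimnames = list(gene_ids, ids))
  n_sub <- round(subgroup_frac * n_patients)
  subgroup <- sample(ids, n_sub)
  expr[sig, subgroup] <- expr[sig, subgroup] + subgroup_shift * sign(betas)

  lp <- drop(crossprod(expr[sig, , drop = FALSE], betas))
  t_event <- stats::rexp(n_patients, rate = exp(lp))
  # calibrate uniform censoring bound to the target censored fraction:
  # P(censored) = mean_i P(C < t_i), C ~ U(0, cmax)
  cens_frac <- function(cmax) mean(pmin(t_event / cmax, 1)) - censoring
  c_max <- tryCatch(
    stats::uniroot(cens_frac, c(1e-9, 1e9 * max(t_event)))$root,
    error = function(e) 2 * stats::median(t_event))
  t_cens <- stats::runif(n_patients, 0, c_max)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  if (sum(event) == 0 && stats::var(lp) == 0) {
    warning("degenerate cohort: no events and no hazard variation")
  }
  patients <- data.frame(
    id = ids, time = time, event = event,
    metastasis_site = ifelse(event & ids %in% subgroup, metastasis_site,
                             NA_character_),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, expression = expr,
                 truth = list(signature = sig, betas = betas,
                              subgroup = sort(subgroup))),
            class = "survival_cohort")
}

#' Apply a random strictly increasing distortion to every sample
#'
#' Each sample gets an independent transform `f(x) = c + a*x + b*x^3` with
#' `a, b > 0` (strictly increasing), emulating arbitrary per-array
#' normalisation/scanner response. Within-sample rank order is preserved
#' exactly, so rank-based results must be unchanged.
#'
#' @param x an `expr_matrix`.
#' @param seed integer seed for the per-sample coefficients.
#' @return The distorted `expr_matrix`.
#' @export
monotone_distort <- function(x, seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  set.seed(seed)
  v <- x$values
  for (j in seq_len(ncol(v))) {
    a <- stats::runif(1, 0.5, 2)
    b <- stats::runif(1, 0.01, 0.2)
    cc <- stats::runif(1, -5, 5)
    v[, j] <- cc + a * v[, j] + b * (v[, j] / 10)^3
  }
  expression_matrix(v, x$annotations)
}
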