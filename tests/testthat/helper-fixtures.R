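# Shared fixture builders: everything is generated in code at test time.

make_annotations <- function(ids, role = "control", dataset = "ds1",
                             primary = NA_character_, site = "brain") {
  data.frame(sample_id = ids, dataset_id = dataset,
             platform_id = paste0("pl_", dataset),
             tissue_role = role,
             primary_site = if (role == "control") NA_character_ else primary,
             metastasis_site = site,
             stringsAsFactors = FALSE)
}

make_matrix <- function(values, role = "control", dataset = "ds1",
                        primary = NA_character_, site = "brain") {
  expression_matrix(values, make_annotations(colnames(values), role, dataset,
                                             primary, site))
}

random_expr <- function(n_genes, n_samples, role = "control",
                        dataset = "ds1", primary = NA_character_,
                        prefix = "s") {
  v <- matrix(rnorm(n_genes * n_samples, 7, 2), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              paste0(prefix, seq_len(n_samples))))
  make_matrix(v, role, dataset, primary)
}

# small, fast simulation settings used by unit tests
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, origins = c(alpha = 8, beta = 8),
               n_controls = 12, frac_common_deg = 0.1,
               frac_private_deg = 0.05, effect_size = 1.0,
               batch_shift_sd = 1.0, platform_dropout = 0.1, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Independent oracles -------------------------------------------------------

# two-sided Fisher p from first principles: sum, over all 2x2 tables with
# the observed margins, of the table probabilities (products of binomial
# coefficients) not exceeding the observed one
fisher_oracle <- function(u, U, d, D) {
  k <- u + d
  xs <- max(0, k - D):min(k, U)
  probs <- choose(U, xs) * choose(D, k - xs) / choose(U + D, k)
  obs <- choose(U, u) * choose(D, k - u) / choose(U + D, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# upper binomial tail by direct summation
binom_tail_oracle <- function(k, m, p) {
  if (k <= 0) return(1)
  js <- k:m
  sum(choose(m, js) * p^js * (1 - p)^(m - js))
}

# upper hypergeometric tail by direct summation of choose() products
hyper_tail_oracle <- function(k, m, n, N) {
  js <- max(0, m + n - N):min(m, n)
  js <- js[js >= k]
  if (!length(js)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# exhaustive-enumeration hypergeometric tail (all C(N, n) draws)
hyper_enum_oracle <- function(k, m, n, N) {
  A <- seq_len(m)  # the "list" genes
  draws <- utils::combn(N, n)
  mean(colSums(matrix(draws %in% A, nrow = n)) >= k)
}

# naive O(m^2) BH: q_i = min over thresholds t >= p_i of m * t / rank(t)
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
  }, numeric(1))
}
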