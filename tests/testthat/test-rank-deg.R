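test_that("stable pairs follow the consistency threshold exactly", {
  # A < B in all 10 controls -> pair present
  set.seed(1)
  v <- rbind(A = rnorm(10, 0), B = rnorm(10, 10), C = rnorm(10, 5))
  colnames(v) <- paste0("c", 1:10)
  sp <- find_stable_pairs(make_matrix(v), 0.99)
  key <- paste(sp$genes[sp$low], sp$genes[sp$high])
  expect_true("A B" %in% key)

  # A < B in only 5 of 10 -> absent at 0.99
  v2 <- rbind(A = c(rep(0, 5), rep(2, 5)), B = rep(1, 10))
  colnames(v2) <- paste0("c", 1:10)
  sp2 <- find_stable_pairs(make_matrix(v2), 0.99)
  expect_length(sp2$low, 0)

  # 99 of 100 controls -> fraction 0.99 >= threshold, pair present
  v3 <- rbind(A = c(rep(0, 99), 2), B = rep(1, 100))
  colnames(v3) <- paste0("c", 1:100)
  sp3 <- find_stable_pairs(make_matrix(v3), 0.99)
  expect_equal(sp3$genes[sp3$low], "A")
  expect_equal(sp3$genes[sp3$high], "B")

  expect_error(find_stable_pairs(make_matrix(v3[, 1, drop = FALSE])),
               "at least 2")
  expect_error(find_stable_pairs(make_matrix(v3), 0.4), "0.5")
})

test_that("ties count against pair consistency", {
  v <- rbind(A = rep(1, 10), B = rep(1, 10))
  colnames(v) <- paste0("c", 1:10)
  sp <- find_stable_pairs(make_matrix(v), 0.5)
  expect_length(sp$low, 0)
})

test_that("vectorised Fisher reversal p matches fisher.test and enumeration", {
  # null table: no reversals
  expect_equal(fisher_reversal_p(0, 10, 0, 10), 1)
  # hand-enumerated spec table [[8,2],[1,9]]
  expect_equal(fisher_reversal_p(8, 10, 1, 10), 920 / 167960, tolerance = 1e-12)
  # swapping the rows gives the same p
  expect_equal(fisher_reversal_p(1, 10, 8, 10), fisher_reversal_p(8, 10, 1, 10))

  set.seed(11)
  for (i in 1:200) {
    U <- sample(0:12, 1); D <- sample(0:12, 1)
    if (U + D == 0) next
    u <- if (U > 0) sample(0:U, 1) else 0L
    d <- if (D > 0) sample(0:D, 1) else 0L
    p <- fisher_reversal_p(u, U, d, D)
    expect_equal(p, fisher_oracle(u, U, d, D), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(c(u, d, U - u, D - d), 2))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("per-sample reversal test assigns direction and flags untestable genes", {
  # controls: A < B < C < D strongly separated; E oscillates around all of
  # them, so no pair containing E is stable
  set.seed(3)
  v <- rbind(A = rnorm(20, 0, .1), B = rnorm(20, 5, .1),
             C = rnorm(20, 10, .1), D = rnorm(20, 15, .1),
             E = rep(c(-20, 20), 10))
  colnames(v) <- paste0("c", 1:20)
  sp <- find_stable_pairs(make_matrix(v), 0.99)
  expect_false(any(sp$genes[c(sp$low, sp$high)] == "E"))
  # disease sample: A jumps above C -> A up; others in place
  s <- c(A = 12, B = 5, C = 10, D = 15, E = 7.5)
  res <- sample_reversal_test(s, sp)
  expect_equal(res$direction[res$gene == "A"], "up")
  expect_gt(res$u[res$gene == "A"], 0)
  # E has no stable partners (ties in all controls)
  expect_false(res$testable[res$gene == "E"])
  expect_equal(res$fisher_p[res$gene == "E"], 1)
  expect_equal(res$direction[res$gene == "E"], "none")
})

test_that("subpopulation binomial test matches direct tail summation", {
  # build a call table by hand: gene g1 significant-up in 10 of 20 samples
  genes <- c("g1", "g2")
  samples <- paste0("s", 1:20)
  dir_mat <- matrix("none", 2, 20, dimnames = list(genes, samples))
  sig_mat <- matrix(FALSE, 2, 20, dimnames = list(genes, samples))
  dir_mat[1, 1:10] <- "up"; sig_mat[1, 1:10] <- TRUE
  calls <- structure(list(genes = genes, samples = samples,
                          direction = dir_mat, significant = sig_mat,
                          fisher_p = matrix(1, 2, 20)),
                     class = "sample_call_table")
  deg <- population_deg_test(calls, null_rate = 0.05)
  expect_equal(deg$binom_p[deg$gene == "g1"], 1.134072e-08,
               tolerance = 1e-6)
  expect_equal(deg$binom_p[deg$gene == "g1"],
               binom_tail_oracle(10, 20, 0.05), tolerance = 1e-12)
  # k = 0 -> p = 1
  expect_equal(deg$binom_p[deg$gene == "g2"], 1)
  expect_equal(deg$direction[deg$gene == "g1"], "up")
  expect_true(is.na(deg$direction[deg$gene == "g2"]))
  expect_error(population_deg_test(calls, null_rate = 0), "null_rate")
})

test_that("direction ties are excluded from DEG calls", {
  genes <- "g1"; samples <- paste0("s", 1:10)
  dir_mat <- matrix(c(rep("up", 5), rep("down", 5)), 1, 10,
                    dimnames = list(genes, samples))
  sig_mat <- matrix(TRUE, 1, 10, dimnames = list(genes, samples))
  calls <- structure(list(genes = genes, samples = samples,
                          direction = dir_mat, significant = sig_mat,
                          fisher_p = matrix(1, 1, 10)),
                     class = "sample_call_table")
  deg <- population_deg_test(calls)
  expect_true(is.na(deg$direction))
  expect_false(deg$is_deg)
})

test_that("BH adjustment is exact on hand-computed and random cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(5)
  for (i in 1:30) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # adjusted values monotone in the sorted order of raw p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # constant vector: all adjusted values equal the raw p
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
})

test_that("rank DEG calls are invariant under monotone per-sample distortion", {
  cfg <- small_config(seed = 4)
  sim <- simulate_multibatch(cfg)
  integ <- integrate_datasets(sim$matrices)
  ctrl <- samples_by_role(integ$matrix, "control")
  cases <- samples_by_role(integ$matrix, "metastasis", "alpha")
  deg1 <- rankcomp_deg(cases, ctrl)
  deg2 <- rankcomp_deg(monotone_distort(cases, seed = 99),
                       monotone_distort(ctrl, seed = 77))
  expect_identical(deg1$is_deg, deg2$is_deg)
  expect_identical(deg1$direction, deg2$direction)
  expect_identical(deg1$binom_p, deg2$binom_p)
  p1 <- attr(deg1, "pairs"); p2 <- attr(deg2, "pairs")
  expect_identical(p1$low, p2$low)
  expect_identical(p1$high, p2$high)
})

test_that("pure-null simulation keeps the DEG fraction within FDR bounds", {
  fracs <- vapply(1:5, function(s) {
    cfg <- small_config(seed = 100 + s, effect_size = 0)
    sim <- simulate_multibatch(cfg)
    integ <- integrate_datasets(sim$matrices)
    deg <- rankcomp_deg(samples_by_role(integ$matrix, "metastasis", "alpha"),
                        samples_by_role(integ$matrix, "control"))
    mean(deg$is_deg)
  }, numeric(1))
  expect_lte(mean(fracs), 2 * 0.05)
})
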