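gs <- function(mean, var, n) {
  structure(list(mean = mean, variance = var, n = n), class = "group_summary")
}

test_that("Kulinskaya delta matches the closed form and the Welch link", {
  # equal means -> delta 0 regardless of variances
  expect_equal(kulinskaya_delta(gs(3, 2, 10), gs(3, 9, 15))$delta, 0)

  # unit shift, unit variances, equal n: sigma = 2, delta = 0.5
  r <- kulinskaya_delta(gs(1, 1, 10), gs(0, 1, 10))
  expect_equal(r$pooled_sigma, 2)
  expect_equal(r$delta, 0.5)

  # same at n = 50 + 50: t_welch = sqrt(100) * 0.5 = 5 = textbook Welch t
  r2 <- kulinskaya_delta(gs(1, 1, 50), gs(0, 1, 50))
  expect_equal(r2$t_welch, 5)
  expect_equal(r2$t_welch, (1 - 0) / sqrt(1 / 50 + 1 / 50))

  expect_error(kulinskaya_delta(gs(1, 1, 1), gs(0, 1, 10)), "n >= 2")
  inf <- kulinskaya_delta(gs(1, 0, 5), gs(0, 0, 5))
  expect_true(inf$infinite)
  expect_equal(inf$delta, Inf)
})

test_that("the variance identity sigma^2/n = s_i^2/n_i + s_j^2/n_j holds", {
  set.seed(8)
  for (i in 1:50) {
    gi <- gs(rnorm(1), rexp(1), sample(2:50, 1))
    gj <- gs(rnorm(1), rexp(1), sample(2:50, 1))
    r <- kulinskaya_delta(gi, gj)
    expect_equal(r$pooled_sigma^2 / r$n,
                 gi$variance / gi$n + gj$variance / gj$n,
                 tolerance = 1e-12)
  }
})

test_that("delta is scale- and shift-invariant and antisymmetric", {
  set.seed(9)
  xi <- rnorm(20, 5, 2); xj <- rnorm(30, 4, 1)
  d0 <- kulinskaya_delta(group_summary(xi), group_summary(xj))
  d_scaled <- kulinskaya_delta(group_summary(3 * xi), group_summary(3 * xj))
  d_shift <- kulinskaya_delta(group_summary(xi + 7), group_summary(xj + 7))
  expect_equal(d_scaled$delta, d0$delta, tolerance = 1e-12)
  expect_equal(d_shift$delta, d0$delta, tolerance = 1e-12)
  swapped <- kulinskaya_delta(group_summary(xj), group_summary(xi))
  expect_equal(swapped$delta, -d0$delta, tolerance = 1e-12)
  expect_equal(swapped$t_welch, -d0$t_welch, tolerance = 1e-12)
  # sigma preserved under swap only for equal n
  yi <- rnorm(25); yj <- rnorm(25)
  a <- kulinskaya_delta(group_summary(yi), group_summary(yj))
  b <- kulinskaya_delta(group_summary(yj), group_summary(yi))
  expect_equal(a$pooled_sigma, b$pooled_sigma, tolerance = 1e-12)
})

test_that("delta estimates are consistent for a known standardized shift", {
  # true delta for unit shift, unit variances, equal n is 0.5
  set.seed(10)
  est <- replicate(200, {
    kulinskaya_delta(group_summary(rnorm(30, 1)), group_summary(rnorm(30, 0)))$delta
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 2 * mc_se + 1e-9)
})

test_that("the effect-size screen drops weak and direction-conflicting genes", {
  set.seed(12)
  n_case <- 15; n_ctrl <- 15
  mk <- function(shift) c(rnorm(n_case, 7 + shift), rnorm(n_ctrl, 7))
  v <- rbind(STRONG_UP = mk(3), NULLG = mk(0), STRONG_DOWN = mk(-3))
  colnames(v) <- c(paste0("case", 1:n_case), paste0("ctrl", 1:n_ctrl))
  ann <- rbind(make_annotations(colnames(v)[1:n_case], "metastasis",
                                "dsA", "breast"),
               make_annotations(colnames(v)[-(1:n_case)], "control", "dsB"))
  mat <- expression_matrix(v, ann)
  degs <- data.frame(gene = c("STRONG_UP", "NULLG", "STRONG_DOWN"),
                     direction = c("up", "up", "up"),  # DOWN mislabelled up
                     k_support = 9L, m_samples = 10L,
                     binom_p = 1e-6, bh_q = 1e-6, is_deg = TRUE,
                     stringsAsFactors = FALSE)
  class(degs) <- c("deg_table", "data.frame")
  out <- filter_by_effect_size(degs, mat, threshold = 0.5)
  expect_equal(out$gene, "STRONG_UP")
  expect_equal(attr(out, "n_direction_conflict"), 1L)  # STRONG_DOWN
  expect_equal(attr(out, "n_below_threshold"), 1L)     # NULLG
})

test_that("screen boundary is inclusive and zero effects are removed", {
  # construct exact group stats via a degenerate two-value design
  v <- rbind(EDGE = c(1, 3, 0, 2), FLAT = c(5, 5, 5, 5) + c(0, 1e-9, 0, 1e-9))
  colnames(v) <- c("a1", "a2", "b1", "b2")
  ann <- rbind(make_annotations(c("a1", "a2"), "metastasis", "dsA", "x"),
               make_annotations(c("b1", "b2"), "control", "dsB"))
  mat <- expression_matrix(v, ann)
  es <- effect_sizes(mat, c("EDGE", "FLAT"), center = "none")
  # EDGE: means 2 vs 1, variances 2, 2, q = .5 -> sigma^2 = 8, delta = 1/sqrt(8)
  expect_equal(es$delta[1], 1 / sqrt(8), tolerance = 1e-12)
  degs <- data.frame(gene = c("EDGE", "FLAT"), direction = "up",
                     k_support = 2L, m_samples = 2L, binom_p = 0.01,
                     bh_q = 0.01, is_deg = TRUE, stringsAsFactors = FALSE)
  class(degs) <- c("deg_table", "data.frame")
  kept <- filter_by_effect_size(degs, mat, threshold = 1 / sqrt(8),
                                center = "none")
  expect_true("EDGE" %in% kept$gene)      # boundary inclusive
  expect_false("FLAT" %in% kept$gene)     # ~zero delta removed
  expect_error(effect_sizes(mat, "MISSING"), "absent")
})

test_that("median centering removes dataset-level additive offsets", {
  set.seed(13)
  base <- rnorm(50, 7, 2)
  v_case <- matrix(base, 50, 10) + matrix(rnorm(500, 0, .5), 50) + 3  # +3 batch
  v_ctrl <- matrix(base, 50, 10) + matrix(rnorm(500, 0, .5), 50)
  colnames(v_case) <- paste0("c", 1:10); colnames(v_ctrl) <- paste0("n", 1:10)
  rownames(v_case) <- rownames(v_ctrl) <- sprintf("G%02d", 1:50)
  ann <- rbind(make_annotations(colnames(v_case), "metastasis", "dsA", "x"),
               make_annotations(colnames(v_ctrl), "control", "dsB"))
  mat <- expression_matrix(cbind(v_case, v_ctrl), ann)
  raw <- effect_sizes(mat, genes(mat), center = "none")
  cen <- effect_sizes(mat, genes(mat), center = "median")
  expect_gt(mean(raw$delta), 1)          # batch offset aliases into delta
  expect_lt(mean(abs(cen$delta)), 0.3)   # centering removes it
})
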