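mk_cohort <- function(time, event, expr, ids = sprintf("pt_%02d", seq_along(time))) {
  colnames(expr) <- ids
  list(patients = data.frame(id = ids, time = time, event = event,
                             stringsAsFactors = FALSE),
       expression = expr)
}

test_that("risk index is an exact weighted sum", {
  expr <- matrix(c(2, 1), 2, 1, dimnames = list(c("A", "B"), "p1"))
  expect_equal(unname(risk_index(c(A = 0.5, B = -1), expr)), 0)
  expect_equal(unname(risk_index(c(A = 0, B = 0), expr)), 0)
  # linearity: shifting one gene shifts every score by beta * c
  set.seed(41)
  e2 <- matrix(rnorm(30), 3, 10,
               dimnames = list(c("A", "B", "C"), paste0("p", 1:10)))
  b <- c(A = 0.3, B = -0.7, C = 1.1)
  s1 <- risk_index(b, e2)
  e3 <- e2; e3["B", ] <- e3["B", ] + 4
  expect_equal(risk_index(b, e3), s1 + b[["B"]] * 4, tolerance = 1e-12)
  # dot-product oracle
  expect_equal(unname(s1), as.numeric(t(e2) %*% b), tolerance = 1e-12)
  expect_error(risk_index(c(Z = 1), e2), "missing")
})

test_that("median split puts ties low and degenerates cleanly", {
  set.seed(42)
  expr <- matrix(rnorm(20), 1, 20, dimnames = list("A", NULL))
  co <- mk_cohort(rexp(20) + .1, rep(c(TRUE, FALSE), 10), expr)
  scores <- stats::setNames(c(rep(1, 10), rep(2, 10)), co$patients$id)
  r <- median_split_logrank(scores, co)
  expect_equal(unname(table(r$group)["low"]), 10L)  # ties at median -> low
  allsame <- stats::setNames(rep(3, 20), co$patients$id)
  rd <- median_split_logrank(allsame, co)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$logrank_p))
})

test_that("log-rank is null on identical groups and label-invariant", {
  # two groups with identical survival curves: duplicate every patient
  time <- rep(c(1, 2, 3, 4, 5), 4)
  event <- rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 4)
  expr <- matrix(0, 1, 20, dimnames = list("A", NULL))
  co <- mk_cohort(time, event, expr)
  scores <- stats::setNames(rep(c(0, 1), each = 10), co$patients$id)
  r <- median_split_logrank(scores, co)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$logrank_p, 1, tolerance = 1e-9)
  # relabelling the groups leaves p unchanged
  r2 <- median_split_logrank(stats::setNames(1 - scores, names(scores)), co)
  expect_equal(r2$logrank_p, r$logrank_p, tolerance = 1e-12)
})

test_that("univariate Cox screen recovers a planted log-hazard ratio", {
  set.seed(43)
  hits <- replicate(60, {
    n <- 300
    x <- rnorm(n)
    t_ev <- rexp(n, rate = exp(0.7 * x))
    cens <- runif(n, 0, quantile(t_ev, 0.8))
    co <- mk_cohort(pmin(t_ev, cens), t_ev <= cens,
                    matrix(x, 1, n, dimnames = list("A", NULL)))
    scr <- univariate_cox_screen(co, "A")
    abs(scr$beta - 0.7) <= 2 * scr$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Cox screen handles constant genes and reports fractions", {
  set.seed(44)
  n <- 100
  expr <- rbind(A = rnorm(n), FLAT = rep(1, n), B = rnorm(n))
  t_ev <- rexp(n, rate = exp(0.8 * expr["A", ]))
  co <- mk_cohort(t_ev, rep(TRUE, n), expr)
  expect_warning(scr <- univariate_cox_screen(co, c("A", "FLAT", "B")),
                 "FLAT")
  expect_setequal(scr$gene, c("A", "B"))
  expect_true(attr(scr, "frac_significant_raw") >= 0.5)  # A is strong
  expect_error(univariate_cox_screen(
    mk_cohort(c(1, 2), c(FALSE, TRUE), matrix(1:2, 1, 2, dimnames = list("A", NULL))),
    "A"), "events")
})

test_that("pathway risk models separate risk groups driven by a signature", {
  set.seed(45)
  co <- simulate_survival_cohort(n_patients = 200, n_genes = 60,
                                 signature_size = 10, effect = 1.2, seed = 9)
  coll <- structure(list(
    SIGPATH = list(description = "d", members = co$truth$signature),
    RANDPATH = list(description = "d", members = sprintf("SG%04d", 31:40))),
    class = "gene_set_collection")
  res <- pathway_risk_models(co, rownames(co$expression), coll)
  expect_equal(res$pathway[1], "SIGPATH")
  expect_lt(res$logrank_p[1], 0.01)
  models <- attr(res, "models")
  expect_equal(length(models$SIGPATH$betas), 10)
})

test_that("hierarchical clustering separates anti-correlated patient blocks", {
  set.seed(46)
  # block 1 follows +profile, block 2 follows -profile
  profile <- rnorm(20)
  mk_block <- function(sgn, n, prefix) {
    sapply(seq_len(n), function(i) sgn * profile + rnorm(20, 0, .1))
  }
  expr <- cbind(mk_block(1, 6, "a"), mk_block(-1, 6, "b"))
  dimnames(expr) <- list(sprintf("G%02d", 1:20),
                         c(sprintf("a%d", 1:6), sprintf("b%d", 1:6)))
  cl <- hierarchical_cluster(expr, k = 2)
  expect_length(unique(cl$cluster[1:6]), 1)
  expect_length(unique(cl$cluster[7:12]), 1)
  expect_false(cl$cluster[["a1"]] == cl$cluster[["b1"]])
  expect_match(cl$newick, "^\\(")
  # determinism and consistent relabelling under permutation
  perm <- sample(12)
  cl2 <- hierarchical_cluster(expr[, perm], k = 2)
  agree <- outer(cl$cluster[colnames(expr)[perm]],
                 cl$cluster[colnames(expr)[perm]], "==")
  agree2 <- outer(cl2$cluster, cl2$cluster, "==")
  expect_identical(unname(agree), unname(agree2))
  # duplicated profiles merge at zero height (euclidean distance)
  dup <- matrix(rep(rnorm(5), 4), 5, 4,
                dimnames = list(sprintf("G%d", 1:5), sprintf("p%d", 1:4)))
  cl_dup <- hierarchical_cluster(dup, k = 2, distance = "euclidean")
  expect_true(all(cl_dup$hclust$height < 1e-12))
  # constant profiles degenerate the correlation distance
  expect_error(hierarchical_cluster(matrix(1, 5, 4,
                 dimnames = list(sprintf("G%d", 1:5), sprintf("p%d", 1:4)))),
               "degenerac")
})

test_that("cluster label enrichment matches a Fisher enumeration oracle", {
  set.seed(47)
  profile <- rnorm(15)
  expr <- cbind(sapply(1:5, function(i) profile + rnorm(15, 0, .05)),
                sapply(1:5, function(i) -profile + rnorm(15, 0, .05)))
  dimnames(expr) <- list(sprintf("G%02d", 1:15), sprintf("p%02d", 1:10))
  labels <- stats::setNames(c(rep(TRUE, 5), rep(FALSE, 5)), colnames(expr))
  cl <- hierarchical_cluster(expr, k = 2, labels = labels)
  enr <- cl$label_enrichment
  lab_cl <- enr[enr$n_labeled == 5, ]
  # all 5 labelled patients in one 5-patient cluster of 10:
  # one-sided Fisher p = 1 / C(10,5)
  expect_equal(lab_cl$fisher_p, 1 / choose(10, 5), tolerance = 1e-10)
})

test_that("covariate balance chi-square matches hand-computed Pearson values", {
  r <- suppressWarnings(covariate_balance_chisq(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(r$statistic, 20)
  expect_equal(r$p, 7.744216e-06, tolerance = 1e-6)
  # perfectly proportional table: statistic 0, p = 1
  r2 <- covariate_balance_chisq(matrix(c(20, 10, 40, 20), 2))
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1)
  expect_error(covariate_balance_chisq(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_warning(covariate_balance_chisq(matrix(c(2, 3, 4, 5), 2)), "below 5")
})
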