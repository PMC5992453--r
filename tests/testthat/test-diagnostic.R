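test_that("confusion tables partition the sample at each cutoff", {
  ct <- build_confusion(c(10, 10, 5, 5), c(TRUE, FALSE, TRUE, FALSE), 8)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  ct27 <- build_confusion(c(10, 10, 5, 5), c(TRUE, FALSE, TRUE, FALSE), 27)
  expect_equal(ct27$tp + ct27$fp, 0L)
  expect_error(build_confusion(integer(0), logical(0), 5),
               class = "drs_validation")
  # counts always partition: property over random data
  set.seed(11)
  for (i in 1:20) {
    sc <- sample(0:26, 60, TRUE)
    st <- runif(60) < 0.4
    co <- sample(0:26, 1)
    ct <- build_confusion(sc, st, co)
    expect_equal(ct$tp + ct$fn, sum(st))
    expect_equal(ct$fp + ct$tn, sum(!st))
  }
})

test_that("diagnostic summary reproduces hand-computed proportions", {
  s <- diagnostic_summary(confusion_table(55, 47, 24, 62))
  expect_equal(s$sensitivity$est, 55 / 79)
  expect_equal(s$specificity$est, 62 / 109)
  expect_equal(s$ppv$est, 55 / 102)
  expect_equal(s$npv$est, 62 / 86)
  expect_equal(s$youden_plus, s$youden_j + 1)
  perfect <- diagnostic_summary(confusion_table(10, 0, 0, 10))
  expect_equal(perfect$sensitivity$est, 1)
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$kappa, 1)
})

test_that("Clopper-Pearson intervals agree with binom.test and behave at edges", {
  for (case in list(c(55, 79), c(62, 109), c(0, 20), c(20, 20), c(7, 30))) {
    x <- case[1]; n <- case[2]
    ci <- clopper_pearson(x, n)
    ref <- binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
    expect_true(ci[1] <= x / n && x / n <= ci[2])
  }
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
})

test_that("Clopper-Pearson coverage is at least nominal (exact enumeration)", {
  for (n in c(10, 30)) {
    cis <- t(vapply(0:n, function(x) clopper_pearson(x, n), c(0, 0)))
    for (p in seq(0.05, 0.95, by = 0.1)) {
      covered <- cis[, 1] <= p & p <= cis[, 2]
      expect_gte(sum(dbinom(0:n, n, p)[covered]), 0.95)
    }
  }
})

test_that("kappa matches its definition and an independent implementation", {
  expect_equal(cohen_kappa(confusion_table(50, 50, 50, 50)), 0)
  k <- cohen_kappa(confusion_table(55, 47, 24, 62))
  expect_equal(k, 0.255, tolerance = 1e-3)
  expect_equal(kappa_band(k), "fair")
  # independent oracle: e1071's classAgreement on the same table
  skip_if_not_installed("e1071")
  m <- matrix(c(55, 47, 24, 62), 2, byrow = TRUE)
  expect_equal(k, e1071::classAgreement(m)$kappa, tolerance = 1e-12)
  # kappa <= observed agreement; degenerate marginals flagged
  expect_lte(k, 117 / 188)
  expect_warning(k0 <- cohen_kappa(confusion_table(10, 0, 0, 0)),
                 "degenerate")
  expect_true(is.na(k0))
})

test_that("AUC equals pairwise enumeration, with ties handled", {
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(4, 7, 4, 7), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  set.seed(42)
  for (i in 1:25) {
    sc <- sample(0:26, 50, TRUE)
    st <- runif(50) < 0.4
    if (!any(st) || all(st)) next
    r <- roc_auc(sc, st)
    expect_equal(r$auc, auc_pairwise(sc, st), tolerance = 1e-12)
    # trapezoid integration over the swept ROC equals the rank formula
    expect_equal(auc_trapezoid(r$points), r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "drs_validation")
})

test_that("AUC matches pROC on a fixed sample", {
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- sample(0:26, 120, TRUE)
  st <- runif(120) < plogis(-2 + 0.15 * sc)
  r <- roc_auc(sc, st)
  p <- pROC::roc(st, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
})

test_that("cutoff selection maximises the criterion with low-cutoff ties", {
  sep <- cutoff_grid(c(rep(10, 5), rep(0, 5)),
                     rep(c(TRUE, FALSE), each = 5), 1:9)
  expect_equal(sep$selected, 1)  # every cutoff perfect; tie -> lowest
  set.seed(99)
  for (i in 1:10) {
    sc <- sample(0:26, 80, TRUE)
    st <- runif(80) < 0.4
    if (!any(st) || all(st)) next
    g <- cutoff_grid(sc, st, 3:15)
    # brute-force argmax recomputed independently
    js <- vapply(3:15, function(co) {
      sens <- mean(sc[st] > co); spec <- mean(sc[!st] <= co)
      sens + spec - 1
    }, 0)
    best <- (3:15)[which.max(js)]
    expect_equal(g$selected, best)
  }
  expect_error(cutoff_grid(1:4, c(TRUE, TRUE, FALSE, FALSE), integer(0)),
               class = "drs_validation")
})

test_that("swapping class labels swaps (sens, spec) and (ppv, npv)", {
  ct <- confusion_table(55, 47, 24, 62)
  sw <- confusion_table(62, 24, 47, 55)  # labels and calls both inverted
  s <- diagnostic_summary(ct); s2 <- diagnostic_summary(sw)
  expect_equal(s2$sensitivity$est, s$specificity$est)
  expect_equal(s2$specificity$est, s$sensitivity$est)
  expect_equal(s2$ppv$est, s$npv$est)
  expect_equal(s2$npv$est, s$ppv$est)
})
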