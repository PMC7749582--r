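# Confusion matrices, metrics, Fisher's exact test, stratification,
# and the conditional risk table.

test_that("confusion matrices count unsigned outlier agreement", {
  truth <- c("HIGH", "LOW", "NONE", "NONE", "HIGH")
  pred <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  cm <- confusion_matrix(pred, truth)
  expect_equal(cm$tp, 2)   # HIGH and LOW both count as true outliers
  expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 1)
  expect_equal(cm$n_total, 5)

  perfect <- confusion_matrix(truth != "NONE", truth)
  expect_equal(perfect$fp + perfect$fn, 0)

  none <- confusion_matrix(rep(FALSE, 5), truth)
  expect_equal(none$tp + none$fp, 0)

  # printed-count reconstruction: tn is forced by the margin
  cm2 <- confusion_from_counts(tp = 8, fp = 6, fn = 11, tn = 175 - 8 - 6 - 11)
  expect_equal(cm2$tn, 150)
  expect_error(confusion_matrix(pred, truth[1:3]), "same length")
  expect_error(confusion_matrix(pred, c(truth[1:4], "HGIH")), "unknown")
})

test_that("metrics follow the percentage definitions with absent degenerate cells", {
  m <- prediction_metrics(confusion_from_counts(8, 6, 11, 150))
  expect_equal(m$sensitivity, 100 * 8 / 19)
  expect_equal(m$sensitivity_rounded, 42.1)
  expect_equal(m$specificity_rounded, 96.2)
  expect_equal(m$accuracy_rounded, 90.3)

  m2 <- prediction_metrics(confusion_from_counts(2, 0, 5, 49))
  expect_equal(m2$sensitivity_rounded, 28.6)
  expect_equal(m2$specificity_rounded, 100)
  expect_equal(m2$accuracy_rounded, 91.1)

  # no positives at all: sensitivity absent, not zero
  m3 <- prediction_metrics(confusion_from_counts(0, 0, 0, 10))
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 100)
  expect_equal(m3$accuracy, 100)
})

test_that("Fisher's exact test matches enumeration conventions and stats::fisher.test", {
  # proportional table carries no association
  expect_equal(fisher_exact_test(confusion_from_counts(10, 10, 10, 10)), 1)

  # zero margin -> p = 1 by convention, with a warning
  expect_warning(p0 <- fisher_exact_test(confusion_from_counts(0, 0, 5, 5)),
                 "margin")
  expect_equal(p0, 1)

  # exhaustive cross-check against the standard implementation
  for (n in c(8, 12, 16)) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[combos$a + combos$b + combos$c <= n, ]
    for (i in seq_len(nrow(combos))) {
      a <- combos$a[i]; b <- combos$b[i]; c_ <- combos$c[i]
      d <- n - a - b - c_
      cm <- confusion_from_counts(a, b, c_, d)
      r1 <- a + b; c1 <- a + c_
      p_ref <- stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                         byrow = TRUE))$p.value
      p_got <- suppressWarnings(fisher_exact_test(cm))
      if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
        expect_equal(p_got, 1)
      } else {
        expect_equal(p_got, p_ref, tolerance = 1e-9)
      }
    }
  }

  # random larger tables up to n = 30
  set.seed(33)
  for (i in 1:200) {
    n <- sample(17:30, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    cells <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
    cm <- confusion_from_counts(cells[1], cells[2], cells[3], cells[4])
    p_got <- suppressWarnings(fisher_exact_test(cm))
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    r1 <- cells[1] + cells[2]; c1 <- cells[1] + cells[3]
    if (r1 %in% c(0, n) || c1 %in% c(0, n)) {
      expect_equal(p_got, 1)
    } else {
      expect_equal(p_got, p_ref, tolerance = 1e-9)
    }
  }
})

test_that("stratified metrics pool back to the whole-cohort confusion", {
  set.seed(44)
  n <- 120
  pred <- runif(n) < 0.2
  truth <- ifelse(runif(n) < 0.1, "HIGH", ifelse(runif(n) < 0.05, "LOW",
                                                 "NONE"))
  groups <- ifelse(runif(n) < 0.4, "CONTROL", "RISK")
  sm <- stratified_metrics(pred, truth, groups)
  pooled <- sm$pooled$confusion
  for (cell in c("tp", "fp", "fn", "tn")) {
    expect_equal(sm$CONTROL$confusion[[cell]] + sm$RISK$confusion[[cell]],
                 pooled[[cell]])
  }

  # order invariance
  perm <- sample(n)
  sm2 <- stratified_metrics(pred[perm], truth[perm], groups[perm])
  expect_equal(sm2$pooled$accuracy, sm$pooled$accuracy)
  expect_equal(sm2$RISK$sensitivity, sm$RISK$sensitivity)

  # NA groups drop from strata but stay pooled
  groups_na <- groups; groups_na[1:5] <- NA
  sm3 <- stratified_metrics(pred, truth, groups_na)
  expect_equal(sm3$pooled$confusion$n_total, n)
  expect_equal(sm3$CONTROL$confusion$n_total +
                 sm3$RISK$confusion$n_total, n - 5)
})

test_that("group classification requires known components only when they matter", {
  expect_equal(
    classify_group(c("FULL_TERM", "PRETERM", "FULL_TERM"),
                   c("SINGLETON", "SINGLETON", "TWIN"),
                   c("NO", "NO", "NO")),
    c("CONTROL", "RISK", "RISK")
  )
  # one known risk factor decides RISK even with UNKNOWNs elsewhere
  expect_equal(
    suppressWarnings(classify_group("PRETERM", "UNKNOWN", "UNKNOWN")), "RISK"
  )
  expect_warning(
    got <- classify_group("FULL_TERM", "UNKNOWN", "NO"), "unclassifiable"
  )
  expect_true(is.na(got))
})

test_that("the conditional risk table reproduces stratified base and cell rates", {
  d <- build_strata_dataset()
  rt <- conditional_risk_table(d$call, d$truth, d$group)
  cell <- function(g, c_) rt[rt$group == g & rt$cell == c_, ]

  expect_equal(cell("CONTROL", "ALL")$n, 56)
  expect_equal(cell("CONTROL", "ALL")$p_high_rounded, 12.50)
  expect_equal(cell("CONTROL", "ALL")$p_low_rounded, 0)
  expect_equal(cell("CONTROL", "NONE")$p_high_rounded, 9.26)   # 5 / 54
  expect_equal(cell("CONTROL", "HIGH_OUTLIER")$p_high, 100)
  expect_equal(cell("RISK", "ALL")$p_high_rounded, 5.04)       # 6 / 119
  expect_equal(cell("RISK", "ALL")$p_low_rounded, 5.04)
  expect_equal(cell("RISK", "NONE")$p_high_rounded, 2.80)      # 3 / 107
  expect_equal(cell("RISK", "NONE")$p_low_rounded, 2.80)
  expect_equal(cell("RISK", "HIGH_OUTLIER")$p_high, 50)
  expect_equal(cell("RISK", "HIGH_OUTLIER")$p_low, 0)
  expect_equal(cell("RISK", "LOW_OUTLIER")$p_low, 50)

  # weighted cell probabilities reproduce the group base rates exactly
  for (g in c("CONTROL", "RISK")) {
    cells <- rt[rt$group == g & rt$cell != "ALL", ]
    base <- cell(g, "ALL")
    expect_equal(sum(cells$n * ifelse(is.na(cells$p_high), 0,
                                      cells$p_high)) / base$n,
                 base$p_high, tolerance = 1e-12)
    expect_equal(sum(cells$n), base$n)
  }

  # empty cells report zero counts and absent probabilities
  rt2 <- conditional_risk_table(rep("NONE", 4),
                                c("HIGH", "NONE", "NONE", "NONE"),
                                rep("CONTROL", 4))
  lo <- rt2[rt2$cell == "LOW_OUTLIER", ]
  expect_equal(lo$n, 0)
  expect_true(is.na(lo$p_high))
})
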