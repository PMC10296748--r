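test_that("confusion tallies match hand cases and reduce one-vs-rest", {
  cc <- confusion(c("+", "+", "-", "-"), c("+", "+", "-", "-"), "+")
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  cc <- confusion(c("+", "-"), c("-", "+"), "+")
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 0L, fp = 1L, tn = 0L, fn = 1L))
  expect_error(confusion(c("a", "b"), c("a"), "a"), "length")
  expect_error(confusion(c("a", "b"), c("a", "b"), "z"), "absent")
})

test_that("confusion agrees with a one-pass tally oracle on random labels", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    true <- sample(c("x", "y", "z"), n, replace = TRUE)
    pred <- sample(c("x", "y", "z"), n, replace = TRUE)
    cc <- confusion(true, pred, "y")
    expect_identical(lapply(unclass(cc)[c("tp", "fp", "tn", "fn")],
                            as.integer),
                     lapply(confusion_oracle(true, pred, "y"), as.integer))
  }
})

test_that("scalar metrics match hand-computed confusion tables", {
  expect_equal(accuracy(confusion_counts(50, 0, 50, 0)), 1)
  expect_equal(accuracy(confusion_counts(0, 5, 0, 5)), 0)
  expect_equal(accuracy(confusion_counts(3, 2, 4, 1)), 0.7)
  cc <- confusion_counts(tp = 3, fp = 1, tn = 5, fn = 1)
  expect_equal(precision(cc), 0.75)
  expect_equal(recall(cc), 0.75)
  expect_equal(f1_score(cc), 0.75)
  expect_equal(csi(cc), 0.5)
  perfect <- confusion_counts(10, 0, 10, 0)
  expect_equal(c(precision(perfect), recall(perfect), specificity(perfect),
                 f1_score(perfect), csi(perfect), gmean(perfect),
                 mcc(perfect), cohen_kappa(perfect)),
               c(1, 1, 1, 1, 1, 1, 1, 1))
  inverted <- confusion_counts(0, 50, 0, 50)
  expect_equal(csi(inverted), -1)
  expect_equal(mcc(inverted), -1)
  expect_equal(mcc(confusion_counts(3, 2, 4, 1)),
               (3 * 4 - 2 * 1) / sqrt(5 * 4 * 6 * 5))
  expect_equal(cohen_kappa(confusion_counts(3, 2, 4, 1)), 0.4)
  expect_equal(cohen_kappa(confusion_counts(25, 25, 25, 25)), 0)
  expect_equal(gmean(confusion_counts(1, 1, 1, 1)), 0.5)
  expect_equal(gmean(confusion_counts(5, 5, 0, 0)), 0)
})

test_that("zero denominators warn and return 0 by default, error in strict mode", {
  cc <- confusion_counts(tp = 0, fp = 0, tn = 8, fn = 2)
  expect_warning(p <- precision(cc), "zero denominator")
  expect_equal(p, 0)
  expect_error(precision(cc, strict = TRUE), "zero denominator")
})

test_that("metrics from counts equal a brute-force label scan on 500 random problems", {
  set.seed(22)
  for (i in 1:500) {
    n <- sample(5:120, 1)
    true <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.5, 0.5))
    pred <- sample(c("pos", "neg"), n, replace = TRUE)
    o <- confusion_oracle(true, pred, "pos")
    cc <- confusion(true, pred, "pos")
    expect_equal(accuracy(cc), (o$tp + o$tn) / n)
    den_p <- o$tp + o$fp; den_r <- o$tp + o$fn; den_s <- o$tn + o$fp
    p <- if (den_p == 0) 0 else o$tp / den_p
    r <- if (den_r == 0) 0 else o$tp / den_r
    s <- if (den_s == 0) 0 else o$tn / den_s
    suppressWarnings({
      expect_equal(precision(cc), p, tolerance = 1e-10)
      expect_equal(recall(cc), r, tolerance = 1e-10)
      expect_equal(specificity(cc), s, tolerance = 1e-10)
      expect_equal(f1_score(cc), if (p + r == 0) 0 else 2 * p * r / (p + r),
                   tolerance = 1e-10)
      expect_equal(csi(cc), p + r - 1, tolerance = 1e-10)
      expect_equal(gmean(cc), sqrt(r * s), tolerance = 1e-10)
    })
    mcc_den <- sqrt(o$tp + o$fp) * sqrt(o$tp + o$fn) *
               sqrt(o$tn + o$fp) * sqrt(o$tn + o$fn)
    expect_equal(mcc(cc), if (mcc_den == 0) 0
                          else (o$tp * o$tn - o$fp * o$fn) / mcc_den,
                 tolerance = 1e-10)
    k_den <- (o$tp + o$fp) * (o$fp + o$tn) + (o$tp + o$fn) * (o$fn + o$tn)
    if (k_den > 0)
      expect_equal(cohen_kappa(cc),
                   2 * (o$tp * o$tn - o$fp * o$fn) / k_den,
                   tolerance = 1e-10)
  }
})

test_that("CSI is identically precision + recall - 1", {
  set.seed(23)
  for (i in 1:50) {
    cc <- confusion_counts(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    expect_identical(csi(cc), precision(cc) + recall(cc) - 1)
  }
})

test_that("MCC and kappa are symmetric under (tp,tn) and (fp,fn) swaps", {
  set.seed(24)
  for (i in 1:50) {
    v <- sample(0:40, 4, replace = TRUE)
    if (sum(v) == 0) next
    a <- confusion_counts(v[1], v[2], v[3], v[4])
    b <- confusion_counts(v[3], v[4], v[1], v[2])  # tp<->tn, fp<->fn
    expect_equal(mcc(a), mcc(b))
    den_a <- (v[1] + v[2]) * (v[2] + v[3]) + (v[1] + v[4]) * (v[4] + v[3])
    if (den_a > 0) expect_equal(cohen_kappa(a), cohen_kappa(b))
  }
})

test_that("AUC interpretation bins reproduce the standard table", {
  expect_equal(interpret_auc(0.00), "No distinction")
  expect_equal(interpret_auc(0.49), "No distinction")
  expect_equal(interpret_auc(0.50), "Poor classification")
  expect_equal(interpret_auc(0.69), "Poor classification")
  expect_equal(interpret_auc(0.70), "Acceptable classification")
  expect_equal(interpret_auc(0.79), "Acceptable classification")
  expect_equal(interpret_auc(0.80), "Great classification")
  expect_equal(interpret_auc(0.85), "Great classification")
  expect_equal(interpret_auc(0.89), "Great classification")
  expect_equal(interpret_auc(0.90), "Outstanding classification")
  expect_equal(interpret_auc(0.92), "Outstanding classification")
  expect_equal(interpret_auc(1.00), "Outstanding classification")
  expect_error(interpret_auc(1.2), "0, 1")
})

test_that("kappa interpretation bins reproduce the standard table", {
  expect_equal(interpret_kappa(0.00), "No agreement")
  expect_equal(interpret_kappa(0.10), "Slight agreement")
  expect_equal(interpret_kappa(0.20), "Slight agreement")
  expect_equal(interpret_kappa(0.21), "Fair agreement")
  expect_equal(interpret_kappa(0.40), "Fair agreement")
  expect_equal(interpret_kappa(0.41), "Moderate agreement")
  expect_equal(interpret_kappa(0.5393), "Moderate agreement")
  expect_equal(interpret_kappa(0.61), "Substantial agreement")
  expect_equal(interpret_kappa(0.80), "Substantial agreement")
  expect_equal(interpret_kappa(0.81), "Almost perfect agreement")
  expect_equal(interpret_kappa(0.8431), "Almost perfect agreement")
  expect_equal(interpret_kappa(0.99), "Almost perfect agreement")
  expect_equal(interpret_kappa(1.00), "Perfect agreement")
  expect_equal(interpret_kappa(-0.3), "No agreement")
})

test_that("binary metric report equals the individually computed metrics", {
  set.seed(25)
  true <- sample(c("case", "ctrl"), 80, replace = TRUE)
  pred <- sample(c("case", "ctrl"), 80, replace = TRUE)
  rep <- metric_report(true, pred, positive = "case")
  cc <- confusion(true, pred, "case")
  expect_equal(rep$metrics[["accuracy"]], accuracy(cc))
  expect_equal(rep$metrics[["precision"]], precision(cc))
  expect_equal(rep$metrics[["recall"]], recall(cc))
  expect_equal(rep$metrics[["f1"]], f1_score(cc))
  expect_equal(rep$metrics[["csi"]], csi(cc))
  expect_equal(rep$metrics[["gmean"]], gmean(cc))
  expect_equal(rep$metrics[["mcc"]], mcc(cc))
  expect_equal(rep$metrics[["kappa"]], cohen_kappa(cc))
})

test_that("a perfect 3-class prediction scores 1 on every macro metric", {
  true <- rep(c("a", "b", "c"), each = 5)
  rep <- metric_report(true, true)
  expect_true(all(abs(rep$metrics - 1) < 1e-12))
  expect_equal(dim(rep$per_class), c(3L, 9L))
  # confusion marginals equal class counts
  expect_equal(unname(rowSums(rep$confusion)), rep(5L, 3))
})

test_that("shuffled-label null sits at chance: accuracy near prior, kappa near 0", {
  set.seed(26)
  n <- 10000
  true <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
  pred <- sample(true)                       # label shuffle preserves priors
  rep <- metric_report(true, pred, positive = "a")
  expected_acc <- 0.6^2 + 0.4^2              # P(agree) under independence
  expect_lt(abs(rep$metrics[["accuracy"]] - expected_acc), 0.05)
  expect_lt(abs(rep$metrics[["kappa"]]), 0.05)
})

test_that("metric report refuses degenerate inputs", {
  expect_error(metric_report(c("a", "a"), c("a", "b")), "two classes")
  expect_error(metric_report(c("a", "b"), c("a")), "length")
})
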