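# Confusion metrics, ROC/AUC, DeLong, rCBV comparator, ARI.

test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(10, 10, 0, 0)
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(confusion_metrics(0, 0, 5, 5)$accuracy, 0)
  m2 <- confusion_metrics(3, 2, 1, 2)
  expect_equal(m2$accuracy, 0.625)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$specificity, 2 / 3)
})

test_that("zero denominators give NA, negative counts error", {
  m <- confusion_metrics(0, 5, 2, 0)  # no positives: sensitivity undefined
  expect_true(is.na(m$sensitivity))
  expect_false(is.na(m$specificity))
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("AUC equals the O(n^2) pairwise concordance oracle", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq_len(15), n, replace = TRUE)  # ties likely
    pairwise <- function(s, l) {
      sp <- s[l == 1]; sn <- s[l == 0]
      tot <- 0
      for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
      tot / (length(sp) * length(sn))
    }
    r <- roc_auc(scores, labels, n_boot = 0)
    expect_equal(r$auc, pairwise(scores, labels))
  }
})

test_that("AUC edge conventions: perfect separation 1.0, all-tied 0.5", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1),
                       n_boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(5, 8), c(0, 1, 0, 1, 0, 1, 0, 1),
                       n_boot = 0)$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1), n_boot = 0), "both classes")
})

test_that("AUC complement identity holds for tie-free scores", {
  set.seed(4)
  scores <- rnorm(40)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  a1 <- roc_auc(scores, labels, n_boot = 0)$auc
  a2 <- roc_auc(-scores, labels, n_boot = 0)$auc
  expect_equal(a1 + a2, 1)
})

test_that("AUC agrees with pROC and Youden threshold reproduces confusion metrics", {
  set.seed(21)
  scores <- round(rnorm(60), 1)
  labels <- sample(0:1, 60, replace = TRUE)
  r <- roc_auc(scores, labels, n_boot = 200, seed = 3)
  ref <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
  # thresholded predictions reproduce sensitivity/specificity exactly
  pred <- as.integer(scores >= r$threshold)
  cm <- confusion_metrics(sum(pred & labels), sum(!pred & !labels),
                          sum(pred & !labels), sum(!pred & labels))
  expect_equal(r$sensitivity, cm$sensitivity)
  expect_equal(r$specificity, cm$specificity)
  # Youden maximality against a brute-force scan
  js <- vapply(sort(unique(scores)), function(cut) {
    p <- as.integer(scores >= cut)
    mean(p[labels == 1] == 1) + mean(p[labels == 0] == 0)
  }, numeric(1))
  expect_equal(r$sensitivity + r$specificity, max(js))
})

test_that("bootstrap CI brackets the point AUC across seeds", {
  set.seed(10)
  scores <- rnorm(80)
  labels <- rep(0:1, 40)
  scores[labels == 1] <- scores[labels == 1] + 1
  for (sd_ in 1:20) {
    r <- roc_auc(scores, labels, n_boot = 200, seed = sd_)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
})

test_that("DeLong: identical scores give z = 0, p = 1; swapping negates z", {
  set.seed(6)
  s <- rnorm(40)
  l <- rep(0:1, 20)
  d0 <- delong_test(s, s, l)
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)
  s2 <- rnorm(40)
  d1 <- delong_test(s, s2, l)
  d2 <- delong_test(s2, s, l)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("DeLong agrees with pROC's implementation", {
  set.seed(14)
  l <- rep(0:1, 30)
  sa <- rnorm(60) + l * 1.2
  sb <- rnorm(60) + l * 0.4
  got <- delong_test(sa, sb, l)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(l, sa, direction = "<"), pROC::roc(l, sb, direction = "<"),
    method = "delong", paired = TRUE
  ))
  expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(abs(got$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
})

test_that("DeLong p is close to a paired-bootstrap oracle", {
  set.seed(33)
  l <- rep(0:1, 30)
  sa <- rnorm(60) + l * 1.0
  sb <- 0.8 * sa + rnorm(60, sd = 0.6)  # correlated, weaker
  got <- delong_test(sa, sb, l)
  # oracle: bootstrap SE of the AUC difference, normal-approximation p
  B <- 5000
  d <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample(60, replace = TRUE)
    if (length(unique(l[i])) < 2) { d[b] <- NA; next }
    d[b] <- roc_auc(sa[i], l[i], n_boot = 0)$auc -
      roc_auc(sb[i], l[i], n_boot = 0)$auc
  }
  d <- d[!is.na(d)]
  z_boot <- got$auc_diff / sd(d)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(got$p_value - p_boot), 0.02)
})

test_that("rCBV comparator: flat curve gives 0; deeper bolus gives more", {
  expect_equal(rcbv_baseline(rep(100, 60)), 0)
  a1 <- archetype("s", baseline = 100, depth_fraction = 0.15, time_to_peak = 10,
                  recovery_fraction = 0.9)
  a2 <- archetype("d", baseline = 100, depth_fraction = 0.30, time_to_peak = 10,
                  recovery_fraction = 0.9)
  v1 <- rcbv_baseline(generate_curve(a1))
  v2 <- rcbv_baseline(generate_curve(a2))
  expect_gt(v2, v1)
  expect_error(rcbv_baseline(c(rep(100, 59), -1)), "positive")
})

test_that("rCBV integral matches a fine-grid quadrature oracle", {
  a <- archetype("q", baseline = 100, depth_fraction = 0.4, time_to_peak = 10,
                 recovery_fraction = 0.5)
  coarse <- rcbv_baseline(generate_curve(a, 60, 1.7), baseline_window = 1:10)
  fine_curve <- generate_curve(a, 60 * 100, 1.7 / 100)
  fine <- rcbv_baseline(fine_curve, baseline_window = 1:1000, dt = 1.7 / 100)
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("adjusted Rand index matches mclust on random partitions", {
  set.seed(2)
  for (i in 1:10) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:5, 200, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})
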