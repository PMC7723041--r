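# Diagnostic statistics: confusion metrics, ROC/AUC with Youden threshold,
# bootstrap confidence intervals, DeLong's paired AUC test, and a simple
# (uncorrected) rCBV-like comparator.

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN); Sensitivity = TP / (TP + FN);
#' Specificity = TN / (TN + FP). A metric with a zero denominator is
#' reported as `NA` (not 0).
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return Tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    rlang::abort("confusion counts must be non-negative finite numbers")
  }
  if (sum(counts) == 0) rlang::abort("all confusion counts are zero")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp)
  )
}

# Mann-Whitney AUC with 0.5 credit for ties, computed from average ranks.
auc_mw <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Sensitivity/specificity over every candidate cut (predict positive when
# score >= cut). Candidate cuts are the observed scores.
roc_points <- function(scores, labels) {
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(c) mean(scores[labels == 1] >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(scores[labels == 0] < c), numeric(1))
  tibble::tibble(threshold = cuts, sensitivity = sens, specificity = spec)
}

#' ROC analysis with Youden-optimal threshold and bootstrap CI
#'
#' AUC by the Mann-Whitney statistic (ties credited 0.5, equivalent to
#' trapezoidal ROC integration). The operating threshold maximizes
#' sensitivity + specificity over observed score cuts (predict positive when
#' score >= threshold), ties broken toward the lower threshold. The 95% CI
#' is a stratified percentile bootstrap (cases resampled within each class).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor where the
#'   second level is positive).
#' @param n_boot Bootstrap replicates, default 2000.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `dsc_roc`: a one-row tibble with `auc`, `ci_low`,
#'   `ci_high`, `threshold`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- normalize_labels(labels)
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels must have equal length")
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    rlang::abort("both classes must be present for ROC analysis")
  }
  auc <- auc_mw(scores, labels)
  pts <- roc_points(scores, labels)
  j <- pts$sensitivity + pts$specificity
  best <- which(j == max(j))[1]  # lowest threshold among ties
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ipos <- which(labels == 1); ineg <- which(labels == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      ib <- c(sample(ipos, length(ipos), replace = TRUE),
              sample(ineg, length(ineg), replace = TRUE))
      auc_mw(scores[ib], labels[ib])
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  }
  out <- tibble::tibble(
    auc = auc, ci_low = ci[1], ci_high = ci[2],
    threshold = pts$threshold[best],
    sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best],
    n_pos = sum(labels == 1), n_neg = sum(labels == 0)
  )
  class(out) <- c("dsc_roc", class(out))
  out
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) != 2) rlang::abort("character labels must have two levels")
    return(as.integer(labels == lv[2]))
  }
  if (!all(labels %in% c(0, 1))) rlang::abort("numeric labels must be 0/1")
  as.integer(labels)
}

#' @exportS3Method generics::glance
glance.dsc_roc <- function(x, ...) {
  tibble::as_tibble(x)
}

# DeLong structural components: for each positive case, the mean tie-credited
# indicator against all negatives (and vice versa).
delong_components <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two paired AUCs
#'
#' Compares the AUCs of two score vectors computed on the same cases, using
#' DeLong's covariance estimate for correlated ROC curves.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels shared by both.
#' @return Tibble with `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- normalize_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    rlang::abort("scores_a, scores_b and labels must be paired (equal length)")
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    rlang::abort("both classes must be present")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    z <- if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  tibble::tibble(
    auc_a = ca$auc, auc_b = cb$auc, auc_diff = d, z = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Uncorrected rCBV-like scalar from one DSC curve
#'
#' A deliberately simple comparator for the temporal-pattern pipeline:
#' converts the signal to the relaxation-rate change
#' \eqn{\Delta R_2^*(t) = -\ln(S(t)/S_0)/TE} with \eqn{S_0} the mean over a
#' pre-bolus baseline window, and integrates its positive part over time by
#' the trapezoidal rule. No leakage correction is applied, so the value
#' conflates blood volume with leakage effects -- the regime the
#' temporal-pattern analysis is designed to resolve.
#'
#' @param curve Numeric signal vector.
#' @param baseline_window Indices of the pre-bolus baseline, default `1:10`.
#' @param te Echo time in seconds, default 0.040.
#' @param dt Sampling interval in seconds, default 1.7.
#' @return Non-negative scalar.
#' @export
rcbv_baseline <- function(curve, baseline_window = 1:10, te = 0.040, dt = 1.7) {
  if (any(curve <= 0)) {
    rlang::abort("rcbv_baseline requires strictly positive signal values")
  }
  s0 <- mean(curve[baseline_window])
  if (s0 <= 0) rlang::abort("baseline signal must be positive")
  dr2 <- pmax(-log(curve / s0) / te, 0)
  sum((dr2[-1] + dr2[-length(dr2)]) / 2) * dt
}

#' Mean lesion rCBV per patient
#'
#' Applies [rcbv_baseline()] to every lesion voxel curve and averages per
#' patient -- the scalar-perfusion comparator for patient-level ROC analysis.
#'
#' @param curves Curve tibble with `patient_id` and `tissue`.
#' @param cel_tissues Tissues counted as lesion.
#' @param ... Passed to [rcbv_baseline()].
#' @return Tibble with `patient_id` and `mean_rcbv`.
#' @export
patient_rcbv <- function(curves,
                         cel_tissues = c("glioblastoma_cel", "pcnsl_cel",
                                         "metastasis_cel"), ...) {
  sel <- curves[curves$tissue %in% cel_tissues, , drop = FALSE]
  mat <- curve_matrix(sel)
  vals <- apply(mat, 1, rcbv_baseline, ...)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(patient_id = sel$patient_id, v = vals),
                    .data$patient_id),
    mean_rcbv = mean(.data$v), .groups = "drop"
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; used
#' to score recovery of the generating archetypes by the clustering.
#'
#' @param a,b Vectors of equal length (any label type).
#' @return Scalar; 1 = identical partitions, ~0 = chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
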