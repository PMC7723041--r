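# Curve extraction, white-matter normalization, outlier removal.

test_that("extract_curves pulls exactly the labeled voxels", {
  sig <- array(0, c(2, 1, 1, 60))
  sig[1, 1, 1, ] <- 100
  lab <- array(c(match("white_matter", tissue_types()), 0L), c(2, 1, 1))
  cs <- extract_curves(sig, lab, "p1")
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$tissue, "white_matter")
  expect_equal(unname(curve_matrix(cs)[1, ]), rep(100, 60))

  ph <- small_phantom()
  cs2 <- small_curves()
  expect_identical(nrow(cs2), sum(ph$labels != 0))
  # coordinates land back on the right labels
  got <- tissue_types()[ph$labels[cbind(cs2$x, cs2$y, cs2$z)]]
  expect_identical(got, cs2$tissue)
})

test_that("extract_curves validates shapes and warns on empty labels", {
  sig <- array(0, c(2, 2, 1, 10))
  expect_error(extract_curves(sig, array(0L, c(3, 2, 1))), "shape")
  expect_warning(cs <- extract_curves(sig, array(0L, c(2, 2, 1))), "no labeled")
  expect_identical(nrow(cs), 0L)
})

test_that("normalization divides by the pooled white-matter median", {
  mat <- rbind(matrix(200, 4, 60), matrix(400, 2, 60))
  cs <- curves_from_matrix(mat, tissue = c(rep("white_matter", 4),
                                           rep("glioblastoma_cel", 2)))
  out <- normalize_to_white_matter(cs)
  m <- curve_matrix(out)
  expect_equal(unname(m[5, ]), rep(2, 60))
  expect_equal(unname(attr(out, "normalization_factor")), 200)
  # idempotent at factor 1
  out2 <- normalize_to_white_matter(out)
  expect_equal(curve_matrix(out2), curve_matrix(out))
  # pooled WM median is exactly 1
  wm <- curve_matrix(out)[out$tissue == "white_matter", ]
  expect_equal(median(wm), 1, tolerance = 1e-15)
})

test_that("normalization factor is the brute-force median of WM samples", {
  cs <- small_curves()
  out <- normalize_to_white_matter(cs)
  wm_samples <- as.vector(curve_matrix(cs)[cs$tissue == "white_matter", ])
  oracle <- sort(wm_samples)[ceiling(length(wm_samples) / 2)]  # odd count
  if (length(wm_samples) %% 2 == 0) {
    s <- sort(wm_samples)
    oracle <- (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  expect_equal(unname(attr(out, "normalization_factor")), oracle)
  wm_arch <- archetype_library()[archetype_library()$name == "white_matter", ]
  expect_gt(oracle, wm_arch$baseline * (1 - wm_arch$depth_fraction) - 3)
  expect_lt(oracle, wm_arch$baseline + 3)
})

test_that("normalization is scale-equivariant", {
  cs <- small_curves()[1:200, ]
  scaled <- set_curve_values(cs, curve_matrix(cs) * 7)
  expect_equal(curve_matrix(normalize_to_white_matter(cs)),
               curve_matrix(normalize_to_white_matter(scaled)))
})

test_that("normalization errors without white matter or on bad median", {
  cs <- curves_from_matrix(matrix(1, 3, 60), tissue = "csf")
  expect_error(normalize_to_white_matter(cs), "white-matter")
  cs0 <- curves_from_matrix(matrix(0, 3, 60), tissue = "white_matter")
  expect_error(normalize_to_white_matter(cs0), "not positive")
})

test_that("outlier rule removes exactly the curves beyond one SD of the mean signal", {
  # 8 ordinary curves + 2 extreme ones; brute-force oracle applies the rule
  mat <- rbind(matrix(rnorm(8 * 60, 1, 0.01), 8, 60),
               matrix(10, 2, 60))
  cs <- curves_from_matrix(mat)
  s <- rowMeans(mat)
  keep_oracle <- abs(s - mean(s)) <= sd(s)
  out <- remove_outliers(cs)
  expect_identical(nrow(out), sum(keep_oracle))
  expect_identical(attr(out, "n_removed"), as.integer(sum(!keep_oracle)))
  expect_identical(out$x, cs$x[keep_oracle])
})

test_that("identical curves are never removed (zero-SD path)", {
  cs <- curves_from_matrix(matrix(5, 10, 60))
  out <- remove_outliers(cs)
  expect_identical(nrow(out), 10L)
  expect_identical(attr(out, "n_removed"), 0L)
})

test_that("one-SD retention matches the normal-distribution rate", {
  # per-curve means ~ N(0,1): P(|x - mu| <= sd) ~ 0.683
  set.seed(77)
  n <- 10000
  means <- rnorm(n)
  mat <- matrix(rep(means, 60), n, 60)
  out <- remove_outliers(curves_from_matrix(mat))
  expect_lt(abs(nrow(out) / n - (pnorm(1) - pnorm(-1))), 0.02)
})

test_that("outlier removal output is a subset of its input", {
  cs <- small_curves()[1:500, ]
  out <- remove_outliers(cs)
  expect_true(all(paste(out$x, out$y, out$z) %in% paste(cs$x, cs$y, cs$z)))
  expect_lte(nrow(out), nrow(cs))
})

test_that("per-timepoint mode is available and stricter on spiky curves", {
  mat <- matrix(rnorm(20 * 60, 1, 0.01), 20, 60)
  mat[3, 30] <- 5  # one spike, mean barely moves
  cs <- curves_from_matrix(mat)
  out_pt <- remove_outliers(cs, mode = "per-timepoint")
  expect_false(3 %in% out_pt$x)
  expect_identical(attr(out_pt, "outlier_mode"), "per-timepoint")
})

test_that("curve tables round-trip through CSV with metadata sidecar", {
  dir <- withr::local_tempdir()
  cs <- normalize_to_white_matter(small_curves()[1:100, ])
  path <- file.path(dir, "curves.csv")
  write_curves(cs, path)
  back <- read_curves(path)
  expect_equal(curve_matrix(back), curve_matrix(cs), tolerance = 1e-12)
  got <- attr(back, "normalization_factor")
  want <- attr(cs, "normalization_factor")
  expect_equal(unname(got), unname(want))
  expect_identical(names(got), names(want))
})
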