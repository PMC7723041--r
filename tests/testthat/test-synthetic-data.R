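# Curve model, archetype library, and phantom generation.

test_that("zero-depth curves are flat at baseline", {
  a <- archetype("flat", baseline = 100, depth_fraction = 0, time_to_peak = 10)
  s <- generate_curve(a, n_timepoints = 60, dt = 1.7)
  expect_length(s, 60)
  expect_true(all(abs(s - 100) < 1e-9))
})

test_that("curve nadir matches baseline * (1 - depth) against a fine-grid oracle", {
  # oracle: evaluate the same closed-form signal on a 100x finer grid; its
  # minimum is the true nadir, and must equal baseline * (1 - depth)
  for (depth in c(0.2, 0.4, 0.68)) {
    a <- archetype("x", baseline = 100, depth_fraction = depth,
                   time_to_peak = 9, recovery_fraction = 0.3)
    s <- generate_curve(a, n_timepoints = 60, dt = 1.7)
    expect_lt(abs(min(s) - 100 * (1 - depth)), 100 * (1 - depth) * 0.01)
    fine <- generate_curve(a, n_timepoints = 60 * 100, dt = 1.7 / 100)
    expect_lt(abs(min(fine) - 100 * (1 - depth)), 0.2)
  }
})

test_that("final timepoint settles at the recovery target", {
  for (rec in c(0.1, 0.5, 0.9)) {
    a <- archetype("x", baseline = 120, depth_fraction = 0.5,
                   time_to_peak = 10, recovery_fraction = rec)
    s <- generate_curve(a)
    target <- 120 - (1 - rec) * 120 * 0.5
    expect_lt(abs(s[60] - target) / target, 0.02)
  }
})

test_that("noise-free curves are monotone into and out of the nadir", {
  lib <- archetype_library()
  for (i in seq_len(nrow(lib))) {
    a <- lib[i, ]
    a$noise_sd <- 0
    s <- generate_curve(a)
    nadir <- which.min(s)
    tol <- a$baseline * 1e-6
    start <- max(1, floor(a$bolus_arrival / 1.7) + 1)
    expect_true(all(diff(s[start:nadir]) <= tol),
                label = paste(a$name, "monotone decrease"))
    expect_true(all(diff(s[nadir:60]) >= -tol),
                label = paste(a$name, "monotone recovery"))
  }
})

test_that("seeded noisy curves are reproducible and seedless draws differ", {
  a <- archetype("n", baseline = 100, depth_fraction = 0.3, time_to_peak = 10,
                 noise_sd = 2)
  expect_identical(generate_curve(a, seed = 9), generate_curve(a, seed = 9))
  expect_false(identical(generate_curve(a, seed = 9), generate_curve(a, seed = 10)))
})

test_that("archetype validation names the offending field", {
  expect_error(archetype("bad", baseline = -1, depth_fraction = 0.5,
                         time_to_peak = 10), "baseline")
  expect_error(archetype("bad", baseline = 10, depth_fraction = 1.5,
                         time_to_peak = 10), "depth_fraction")
  expect_error(archetype("bad", baseline = 10, depth_fraction = 0.5,
                         time_to_peak = 10, recovery_fraction = NaN),
               "recovery_fraction")
})

test_that("archetype library has 9 distinct, well-separated, valid members", {
  lib <- archetype_library()
  expect_identical(nrow(lib), 9L)
  expect_identical(sort(lib$name), sort(tissue_types()))
  # qualitative ordering: metastasis recovers less than PCNSL
  expect_lt(lib$recovery_fraction[lib$name == "metastasis_cel"],
            lib$recovery_fraction[lib$name == "pcnsl_cel"])
  # pairwise-distinct parameter tuples
  key <- paste(lib$depth_fraction, lib$recovery_fraction, lib$time_to_peak,
               lib$baseline)
  expect_identical(anyDuplicated(key), 0L)
  # noise-free curves separated by > 10 * noise_sd * sqrt(60)
  M <- archetype_curve_matrix_pkg(lib)
  D <- as.matrix(dist(M))
  diag(D) <- Inf
  expect_gt(min(D), 10 * max(lib$noise_sd) * sqrt(60))
})

test_that("phantom honors layout, mixtures and seed", {
  # degenerate mixture: all voxels share the archetype
  spec <- phantom_spec(
    grid_shape = c(5, 5, 2), seed = 3,
    tissue_layout = list(white_matter = list(x = c(1, 5), y = c(1, 5), z = c(1, 2)))
  )
  ph <- generate_phantom(spec)
  expect_identical(nrow(ph$truth), 50L)
  expect_true(all(ph$truth$archetype == "white_matter"))

  # mixture proportions at n = 10,000: binomial oracle gives 3*sqrt(p(1-p)/n)
  spec2 <- phantom_spec(
    grid_shape = c(50, 20, 10), seed = 5,
    tissue_layout = list(glioblastoma_cel = list(x = c(1, 50), y = c(1, 20),
                                                 z = c(1, 10))),
    tissue_mixtures = list(glioblastoma_cel = c(glioblastoma_cel = 0.6,
                                                pcnsl_cel = 0.4))
  )
  ph2 <- generate_phantom(spec2)
  p_hat <- mean(ph2$truth$archetype == "glioblastoma_cel")
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))

  # seeded determinism
  ph2b <- generate_phantom(spec2)
  expect_identical(ph2$signal, ph2b$signal)

  # curve count conservation
  expect_identical(nrow(ph2$truth), sum(ph2$labels != 0))
})

test_that("overlapping layout regions are rejected", {
  expect_error(generate_phantom(phantom_spec(
    grid_shape = c(4, 4, 2),
    tissue_layout = list(
      white_matter = list(x = c(1, 3), y = c(1, 4), z = c(1, 2)),
      gray_matter = list(x = c(3, 4), y = c(1, 4), z = c(1, 2))
    )
  )), "overlap")
})

test_that("phantom spec round-trips through YAML and volumes through NIfTI", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(grid_shape = c(6, 6, 2), seed = 21)
  ph <- generate_phantom(spec)
  paths <- write_phantom(ph, dir)
  spec2 <- read_phantom_spec(paths[["spec"]])
  expect_equal(spec2$grid_shape, spec$grid_shape)
  expect_equal(spec2$tissue_mixtures, spec$tissue_mixtures, tolerance = 1e-12)
  expect_equal(spec2$archetypes$baseline, spec$archetypes$baseline)
  ph2 <- generate_phantom(spec2)
  expect_equal(ph2$signal, ph$signal)
  sig <- RNifti::readNifti(paths[["signal"]])
  expect_equal(dim(sig), dim(ph$signal))
  lab <- RNifti::readNifti(paths[["labels"]])
  expect_identical(array(as.integer(lab), dim(lab)), ph$labels)
})
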