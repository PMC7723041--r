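# Dominant-cluster rule, CNN dataset construction, CNN training/prediction.

test_that("dominant clusters reproduce the published lesion profiles", {
  # glioblastoma CEL row: cluster 5 and 3 carry the two highest proportions
  gbm <- c(13.5, 0.3, 14.3, 26.7, 4.6, 32.6, 1.4, 2.3, 4.3)
  names(gbm) <- paste0("cluster_", 0:8)
  dom <- select_dominant_clusters(gbm)
  expect_identical(dom$cluster, c(5L, 3L))
  expect_equal(dom$percentage, c(32.6, 26.7))
  # metastasis CEL row: clusters 8 and 5
  met <- c(13.7, 0, 6.3, 6.5, 9.3, 16.9, 4.4, 2.3, 40.6)
  names(met) <- paste0("cluster_", 0:8)
  dom2 <- select_dominant_clusters(met)
  expect_identical(dom2$cluster, c(8L, 5L))
  expect_equal(dom2$percentage, c(40.6, 16.9))
})

test_that("ties break toward the lower cluster id and scaling is irrelevant", {
  row <- c(50, 50, rep(0, 7))
  expect_identical(select_dominant_clusters(row)$cluster, c(0L, 1L))
  r2 <- c(10, 30, 20, rep(0, 6))
  expect_identical(select_dominant_clusters(r2)$cluster,
                   select_dominant_clusters(r2 * 3.7)$cluster)
})

test_that("fewer than two nonzero clusters returns what exists, with warning", {
  expect_warning(dom <- select_dominant_clusters(c(0, 100, 0, 0)), "fewer")
  expect_identical(dom$cluster, 1L)
})

test_that("select_dominant_clusters accepts frequency-table rows", {
  df <- tibble::tibble(tissue = "cel", cluster = c(rep(2L, 60), rep(7L, 30),
                                                   rep(1L, 10)))
  ft <- cluster_frequency_table(df, k = 9)
  dom <- select_dominant_clusters(ft[1, ])
  expect_identical(dom$cluster, c(2L, 7L))
})

test_that("CNN dataset keeps exactly the dominant-cluster lesion voxels", {
  set.seed(10)
  # patient with 100 CEL voxels: 40 in cluster 5, 25 in cluster 3, 35 spread
  cl <- c(rep(5L, 40), rep(3L, 25), rep(c(0L, 1L, 2L), length.out = 35))
  assigned <- tibble::tibble(
    patient_id = "p1",
    tissue = "glioblastoma_cel",
    cluster = cl
  )
  decoded <- matrix(seq_len(100 * 60), 100, 60)
  ds <- build_cnn_dataset(assigned, decoded, c(p1 = "gbm"))
  expect_identical(nrow(ds), 65L)
  expect_true(all(ds$cluster %in% c(5L, 3L)))
  expect_identical(unique(ds$label), "gbm")
  # rows are exactly the decoded curves of the selected voxels
  expect_equal(curve_matrix(ds), decoded[cl %in% c(5L, 3L), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("two lesions with different diagnoses produce two labels", {
  assigned <- tibble::tibble(
    patient_id = rep(c("a", "b"), each = 20),
    tissue = "metastasis_cel",
    cluster = rep(c(1L, 2L), 20)
  )
  decoded <- matrix(rnorm(40 * 60), 40, 60)
  ds <- build_cnn_dataset(assigned, decoded, c(a = "met", b = "gbm"))
  expect_setequal(unique(ds$label), c("met", "gbm"))
})

test_that("CNN backprop matches finite-difference gradients", {
  set.seed(5)
  cfg <- cnn_config(n_timepoints = 12, conv_filters = 3, dropout_p = 0,
                    fc_hidden = 4, batch_size = 6, epochs = 1, seed = 2)
  params <- dscpattern:::cnn_init_params(cfg, 2)
  running <- replicate(3, list(mean = rep(0, 3), var = rep(1, 3)),
                       simplify = FALSE)
  X <- matrix(rnorm(6 * 12), 6, 12)
  y <- c(1L, 2L, 1L, 2L, 1L, 2L)
  fw <- dscpattern:::cnn_forward(params, X, cfg, running, TRUE)
  ce <- dscpattern:::nn_softmax_ce(fw$logits, y)
  g <- dscpattern:::cnn_backward(params, fw, ce$dlogits, cfg, 6)
  loss_at <- function(p) {
    f <- dscpattern:::cnn_forward(p, X, cfg, running, TRUE)
    dscpattern:::nn_softmax_ce(f$logits, y)$loss
  }
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      eps <- 1e-6
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      expect_lt(abs((loss_at(p1) - loss_at(p2)) / (2 * eps) - g[[nm]][i]), 1e-6)
    }
  }
})

test_that("softmax outputs are probabilities and output width tracks classes", {
  set.seed(9)
  for (K in 2:4) {
    cfg <- cnn_config(n_timepoints = 20, conv_filters = 4, fc_hidden = 6,
                      learning_rate = 1e-3, batch_size = 30, epochs = 2,
                      seed = K)
    X <- matrix(rnorm(60 * 20), 60, 20)
    lab <- sample(letters[1:K], 60, replace = TRUE)
    m <- train_cnn(list(X = X, label = lab), cfg)
    P <- predict_cnn(m, X)
    expect_identical(dim(P), c(60L, as.integer(K)))
    expect_equal(unname(rowSums(P)), rep(1, 60), tolerance = 1e-9)
    expect_true(all(P >= 0))
  }
})

test_that("single-class training data is rejected", {
  X <- matrix(rnorm(20 * 60), 20, 60)
  expect_error(train_cnn(list(X = X, label = rep("a", 20))), "two classes")
})

test_that("CNN training is seed-reproducible and loss decreases on separable data", {
  set.seed(12)
  n <- 150
  X <- rbind(matrix(rnorm(n * 30, 0), n, 30), matrix(rnorm(n * 30, 1.5), n, 30))
  lab <- rep(c("a", "b"), each = n)
  cfg <- cnn_config(n_timepoints = 30, conv_filters = 8, fc_hidden = 8,
                    learning_rate = 2e-3, batch_size = 100, epochs = 150, seed = 4)
  m1 <- train_cnn(list(X = X, label = lab), cfg)
  m2 <- train_cnn(list(X = X, label = lab), cfg)
  expect_equal(tail(m1$training_history, 1), tail(m2$training_history, 1),
               tolerance = 1e-6)
  expect_lt(tail(m1$training_history, 1), m1$training_history[1])
  acc <- mean(m1$classes[max.col(predict_cnn(m1, X))] == lab)
  expect_gt(acc, 0.9)
})

test_that("patient aggregation: mean equals brute-force average, majority counts votes", {
  set.seed(13)
  X <- rbind(matrix(rnorm(25 * 30, 0), 25, 30), matrix(rnorm(25 * 30, 1.5), 25, 30))
  lab <- rep(c("a", "b"), each = 25)
  cfg <- cnn_config(n_timepoints = 30, conv_filters = 4, fc_hidden = 6,
                    learning_rate = 1e-3, batch_size = 50, epochs = 15, seed = 3)
  m <- train_cnn(list(X = X, label = lab), cfg)
  curves <- curves_from_matrix(matrix(rnorm(50 * 30, 0.6), 50, 30))
  P <- predict_cnn(m, curves)
  got <- predict_patient(m, curves, aggregation = "mean")
  expect_equal(unname(unlist(got[, m$classes])), unname(colMeans(P)))
  expect_identical(got$n_curves, 50L)
  maj <- predict_patient(m, curves, aggregation = "majority")
  votes <- table(factor(m$classes[max.col(P)], levels = m$classes))
  expect_identical(maj$predicted, names(which.max(votes)))
  expect_identical(maj$aggregation, "majority")
})
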