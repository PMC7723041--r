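# Dominant-cluster selection and the 1D CNN tumor-type classifier.

#' Select the two dominant clusters of a frequency row
#'
#' The two clusters with the highest within-lesion proportions; ties are
#' broken toward the lower cluster id. With fewer than two nonzero clusters
#' the nonzero one(s) are returned with a warning.
#'
#' @param freq_row One row of a [cluster_frequency_table()] (tibble row), or
#'   a numeric vector of percentages named `cluster_<id>` (or unnamed, in
#'   which case positions are ids 0..k-1).
#' @return Tibble with columns `cluster` (id, ordered by descending
#'   percentage) and `percentage`.
#' @export
select_dominant_clusters <- function(freq_row) {
  if (is.data.frame(freq_row)) {
    if (nrow(freq_row) != 1) rlang::abort("freq_row must be a single row")
    cols <- grep("^cluster_\\d+$", names(freq_row), value = TRUE)
    pct <- as.numeric(freq_row[1, cols])
    ids <- as.integer(sub("^cluster_", "", cols))
  } else {
    pct <- as.numeric(freq_row)
    ids <- if (!is.null(names(freq_row))) {
      as.integer(sub("^cluster_", "", names(freq_row)))
    } else {
      seq_along(pct) - 1L
    }
  }
  nz <- which(pct > 0)
  if (length(nz) < 2) {
    rlang::warn("fewer than two nonzero clusters; returning what is available")
    ord <- nz[order(-pct[nz], ids[nz])]
  } else {
    ord <- order(-pct, ids)[1:2]
  }
  tibble::tibble(cluster = ids[ord], percentage = pct[ord])
}

#' Build the CNN training table from dominant-cluster decoded curves
#'
#' For each patient, finds the contrast-enhancing-lesion voxels, computes
#' the within-lesion cluster proportions, selects the two dominant clusters,
#' and keeps the decoded curves of voxels assigned to them, labeled with the
#' patient's diagnosis.
#'
#' @param assigned Tibble with `patient_id`, `tissue` and `cluster` columns,
#'   one row per voxel (from [assign_clusters()]).
#' @param decoded Matrix of decoded curves, rows aligned with `assigned`.
#' @param diagnoses Named character vector: patient_id -> class label.
#' @param cel_tissues Tissue names treated as contrast-enhancing lesion.
#' @return Tibble with `patient_id`, `label`, `cluster` and curve columns
#'   `t1 ... tN`, one row per selected voxel.
#' @export
build_cnn_dataset <- function(assigned, decoded,
                              diagnoses,
                              cel_tissues = c("glioblastoma_cel", "pcnsl_cel",
                                              "metastasis_cel")) {
  if (nrow(assigned) != nrow(decoded)) {
    rlang::abort("decoded curves must align row-wise with the assignments")
  }
  out <- list()
  for (p in names(diagnoses)) {
    sel <- which(assigned$patient_id == p & assigned$tissue %in% cel_tissues)
    if (!length(sel)) {
      rlang::warn(paste("patient", p, "has no lesion voxels; excluded"))
      next
    }
    freq <- cluster_frequency_table(
      dplyr::mutate(assigned[sel, ], lesion = "cel"), group = "lesion",
      k = max(assigned$cluster) + 1L
    )
    dom <- select_dominant_clusters(freq)
    keep <- sel[assigned$cluster[sel] %in% dom$cluster]
    if (!length(keep)) {
      rlang::warn(paste("patient", p, "has no dominant-cluster voxels; excluded"))
      next
    }
    mat <- decoded[keep, , drop = FALSE]
    sig <- tibble::as_tibble(mat, .name_repair = ~ paste0("t", seq_len(ncol(mat))))
    out[[p]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = p, label = unname(diagnoses[[p]]),
                     cluster = assigned$cluster[keep]),
      sig
    )
  }
  dplyr::bind_rows(out)
}

#' CNN configuration
#'
#' Three convolutional blocks (kernel-2 "same" convolution with 32 feature
#' maps and ReLU, size-2 max pooling, batch normalization, dropout 0.7),
#' two fully-connected layers with ReLU, and a softmax head, trained with
#' softmax cross-entropy and Adam.
#'
#' @param n_timepoints Curve length, default 60.
#' @param conv_filters Feature maps per block, default 32.
#' @param n_blocks Convolutional blocks, default 3.
#' @param dropout_p Dropout probability, default 0.7.
#' @param fc_hidden Width of the first fully-connected layer, default 32.
#' @param learning_rate Adam learning rate, default 1e-8.
#' @param batch_size Mini-batch size, default 1000.
#' @param epochs Training epochs, default 300.
#' @param seed Integer seed.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_timepoints = 60, conv_filters = 32, n_blocks = 3,
                       dropout_p = 0.7, fc_hidden = 32,
                       learning_rate = 1e-8, batch_size = 1000, epochs = 300,
                       seed = 1L) {
  if (dropout_p < 0 || dropout_p >= 1) rlang::abort("dropout_p must be in [0, 1)")
  if (batch_size < 1) rlang::abort("batch_size must be >= 1")
  structure(
    list(n_timepoints = as.integer(n_timepoints), conv_kernel = 2L,
         conv_filters = as.integer(conv_filters),
         n_blocks = as.integer(n_blocks), dropout_p = dropout_p,
         fc_hidden = as.integer(fc_hidden), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed), optimizer = "adam", pool_size = 2L),
    class = "cnn_config"
  )
}

cnn_block_lengths <- function(config) {
  L <- config$n_timepoints
  lens <- integer(config$n_blocks + 1)
  lens[1] <- L
  for (b in seq_len(config$n_blocks)) lens[b + 1] <- lens[b] %/% 2L
  lens
}

cnn_init_params <- function(config, n_classes) {
  F_ <- config$conv_filters
  lens <- cnn_block_lengths(config)
  params <- list()
  c_in <- 1L
  for (b in seq_len(config$n_blocks)) {
    params[[paste0("Wc1_", b)]] <- nn_init(2 * c_in, F_)[seq_len(c_in), , drop = FALSE]
    params[[paste0("Wc2_", b)]] <- nn_init(2 * c_in, F_)[seq_len(c_in), , drop = FALSE]
    params[[paste0("bc_", b)]] <- rep(0, F_)
    params[[paste0("gamma_", b)]] <- rep(1, F_)
    params[[paste0("beta_", b)]] <- rep(0, F_)
    c_in <- F_
  }
  flat_dim <- lens[config$n_blocks + 1] * F_
  params$Wf1 <- nn_init(flat_dim, config$fc_hidden)
  params$bf1 <- rep(0, config$fc_hidden)
  params$Wf2 <- nn_init(config$fc_hidden, n_classes)
  params$bf2 <- rep(0, n_classes)
  params
}

cnn_forward <- function(params, X, config, running, training) {
  n <- nrow(X)
  lens <- cnn_block_lengths(config)
  A <- to_posmajor(X)
  caches <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    cv <- nn_conv_relu_fwd(A, n, params[[paste0("Wc1_", b)]],
                           params[[paste0("Wc2_", b)]],
                           params[[paste0("bc_", b)]])
    Ar <- cv$Z
    pl <- nn_pool_fwd(Ar, n, lens[b])
    bn <- nn_bn_fwd(pl$P, params[[paste0("gamma_", b)]],
                    params[[paste0("beta_", b)]], running[[b]], training)
    running[[b]] <- bn$running
    dp <- nn_dropout_fwd(bn$Y, config$dropout_p, training)
    caches[[b]] <- list(cv = cv, pl = pl, bn = bn, dp = dp)
    A <- dp$Y
  }
  Fl <- nn_flatten(A, n)
  H1pre <- nn_dense_fwd(Fl, params$Wf1, params$bf1)
  H1 <- nn_relu_fwd(H1pre)
  logits <- nn_dense_fwd(H1, params$Wf2, params$bf2)
  list(logits = logits, caches = caches, Fl = Fl, H1pre = H1pre, H1 = H1,
       running = running)
}

cnn_backward <- function(params, fw, dlogits, config, n) {
  g <- list()
  d2 <- nn_dense_bwd(fw$H1, params$Wf2, dlogits)
  g$Wf2 <- d2$dW; g$bf2 <- d2$db
  dH1pre <- nn_relu_bwd(d2$dX, fw$H1pre)
  d1 <- nn_dense_bwd(fw$Fl, params$Wf1, dH1pre)
  g$Wf1 <- d1$dW; g$bf1 <- d1$db
  dA <- nn_unflatten(d1$dX, n, config$conv_filters)
  for (b in rev(seq_len(config$n_blocks))) {
    cache <- fw$caches[[b]]
    dB <- nn_dropout_bwd(cache$dp, dA)
    bnb <- nn_bn_bwd(cache$bn, dB, params[[paste0("gamma_", b)]])
    g[[paste0("gamma_", b)]] <- bnb$dgamma
    g[[paste0("beta_", b)]] <- bnb$dbeta
    dZ <- nn_pool_relu_bwd(cache$pl, bnb$dX, cache$cv$Z)
    cb <- nn_conv_bwd(cache$cv, dZ, params[[paste0("Wc1_", b)]],
                      params[[paste0("Wc2_", b)]], n, need_dA = b > 1)
    g[[paste0("Wc1_", b)]] <- cb$dW1
    g[[paste0("Wc2_", b)]] <- cb$dW2
    g[[paste0("bc_", b)]] <- cb$db
    if (b > 1) dA <- cb$dA
  }
  g
}

#' Train the 1D CNN tumor-type classifier
#'
#' @param dataset Tibble from [build_cnn_dataset()] (needs `label` and curve
#'   columns), or a list with `X` (matrix) and `label`.
#' @param config A [cnn_config()].
#' @return Object of class `dsc_cnn`: parameters, running batch-norm stats,
#'   class vocabulary (sorted), config and per-epoch `training_history`.
#' @export
train_cnn <- function(dataset, config = cnn_config()) {
  if (is.list(dataset) && !is.data.frame(dataset)) {
    X <- dataset$X; labels <- dataset$label
  } else {
    X <- curve_matrix(dataset); labels <- dataset$label
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    rlang::abort("CNN training needs at least two classes")
  }
  y <- match(labels, classes)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  params <- cnn_init_params(config, length(classes))
  running <- replicate(config$n_blocks,
                       list(mean = rep(0, config$conv_filters),
                            var = rep(1, config$conv_filters)),
                       simplify = FALSE)
  state <- adam_init(params)
  n <- nrow(X)
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      fw <- cnn_forward(params, Xb, config, running, training = TRUE)
      running <- fw$running
      ce <- nn_softmax_ce(fw$logits, y[idx])
      if (!is.finite(ce$loss)) {
        rlang::abort(sprintf("training diverged (non-finite loss at epoch %d)",
                             epoch))
      }
      grads <- cnn_backward(params, fw, ce$dlogits, config, length(idx))
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + ce$loss * length(idx)
    }
    history <- c(history, ep_loss / n)
  }
  structure(
    list(params = params, running = running, config = config,
         classes = classes, training_history = history),
    class = "dsc_cnn"
  )
}

#' Per-curve class probabilities from the CNN
#'
#' Deterministic inference (dropout off, batch norm frozen).
#'
#' @param model Trained [train_cnn()] model.
#' @param curves Curve tibble or matrix.
#' @return Matrix n x n_classes of softmax probabilities (columns named by
#'   class).
#' @export
predict_cnn <- function(model, curves) {
  X <- if (is.matrix(curves)) curves else curve_matrix(curves)
  fw <- cnn_forward(model$params, X, model$config, model$running,
                    training = FALSE)
  P <- nn_softmax(fw$logits)
  colnames(P) <- model$classes
  P
}

#' Patient-level prediction by aggregating voxel probabilities
#'
#' @param model Trained CNN.
#' @param curves Curve tibble with a `patient_id` column, or matrix (single
#'   patient).
#' @param aggregation `"mean"` (default; average of voxel softmax
#'   probabilities) or `"majority"` (vote of voxel argmax classes).
#' @return Tibble: one row per patient with per-class probability columns,
#'   `predicted`, `n_curves` and `aggregation`.
#' @export
predict_patient <- function(model, curves, aggregation = c("mean", "majority")) {
  aggregation <- match.arg(aggregation)
  if (is.matrix(curves)) {
    curves <- dplyr::bind_cols(
      tibble::tibble(patient_id = "patient"),
      tibble::as_tibble(curves, .name_repair = ~ paste0("t", seq_len(ncol(curves))))
    )
  }
  if (!nrow(curves)) rlang::abort("no curves to predict from")
  P <- predict_cnn(model, curves)
  out <- lapply(split(seq_len(nrow(curves)), curves$patient_id), function(ix) {
    probs <- if (aggregation == "mean") {
      colMeans(P[ix, , drop = FALSE])
    } else {
      votes <- tabulate(max.col(P[ix, , drop = FALSE], ties.method = "first"),
                        nbins = ncol(P))
      votes / sum(votes)
    }
    names(probs) <- model$classes
    tibble::as_tibble(as.list(probs)) |>
      dplyr::mutate(
        patient_id = curves$patient_id[ix[1]],
        predicted = model$classes[which.max(probs)],
        n_curves = length(ix), aggregation = aggregation,
        .before = 1
      )
  })
  dplyr::bind_rows(out)
}

#' @export
print.dsc_cnn <- function(x, ...) {
  cat("1D CNN classifier:", x$config$n_blocks, "conv blocks x",
      x$config$conv_filters, "maps; classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("epochs trained:", length(x$training_history), " final loss:",
      signif(utils::tail(x$training_history, 1), 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dsc_cnn <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$training_history),
                 loss = x$training_history)
}

#' @exportS3Method generics::glance
glance.dsc_cnn <- function(x, ...) {
  tibble::tibble(
    epochs = length(x$training_history),
    final_loss = utils::tail(x$training_history, 1),
    n_classes = length(x$classes),
    learning_rate = x$config$learning_rate
  )
}
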