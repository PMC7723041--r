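# Single-layer convolutional autoencoder for DSC time-signal curves.

#' Autoencoder configuration
#'
#' Architecture: a kernel-2, 32-filter, "same"-padded 1D convolution with
#' ReLU, size-2 max pooling, batch normalization and dropout (p = 0.7) form
#' the encoder, followed by one fully-connected projection to a
#' 5-dimensional latent space; the decoder is two fully-connected layers
#' (ReLU then linear) back to the 60-point curve. Loss is mean squared
#' error, optimized with Adam. Sparsity comes from the narrow bottleneck and
#' the heavy dropout; an optional L1 activity penalty on the latent code is
#' available (`l1_penalty`, default 0).
#'
#' @param n_timepoints Curve length, default 60.
#' @param conv_filters Convolution filters, default 32.
#' @param dropout_p Dropout probability after batch norm, default 0.7.
#' @param latent_dim Latent dimensionality, default 5.
#' @param decoder_hidden Width of the first decoder layer, default 32.
#' @param learning_rate Adam learning rate, default 1e-5.
#' @param batch_size Mini-batch size, default 10000.
#' @param epochs Training epochs, default 200.
#' @param l1_penalty L1 activity-penalty coefficient on latent codes.
#' @param lr_decay Step decay of the learning rate: multiplied by 0.2 after
#'   60% and again after 85% of the epochs. Lowers the stochastic
#'   (dropout-induced) loss floor late in training. Default `TRUE`.
#' @param polish_epochs After the main (dropout-regularized) run, the whole
#'   network is fine-tuned for this many full-batch Adam epochs 
#'   on the deterministic inference path: dropout disabled, batch-norm
#'   frozen at its running statistics. This removes the reconstruction blur
#'   left by training against dropout-noised latent codes. 0 disables.
#'   Default 300.
#' @param polish_lr Adam learning rate of the fine-tune phase, default 5e-4.
#' @param early_stop Stop when the relative loss improvement over the last
#'   20 epochs falls below 1e-4. Default `FALSE`.
#' @param seed Integer seed for weight init, shuffling and dropout masks.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(n_timepoints = 60, conv_filters = 32, dropout_p = 0.7,
                      latent_dim = 5, decoder_hidden = 32,
                      learning_rate = 1e-5, batch_size = 10000, epochs = 200,
                      l1_penalty = 0, lr_decay = TRUE, polish_epochs = 300,
                      polish_lr = 5e-4, early_stop = FALSE, seed = 1L) {
  if (latent_dim < 1) rlang::abort("latent_dim must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) rlang::abort("dropout_p must be in [0, 1)")
  if (batch_size < 1) rlang::abort("batch_size must be >= 1")
  if (epochs < 1) rlang::abort("epochs must be >= 1")
  structure(
    list(n_timepoints = as.integer(n_timepoints), conv_kernel = 2L,
         conv_filters = as.integer(conv_filters), dropout_p = dropout_p,
         latent_dim = as.integer(latent_dim),
         decoder_hidden = as.integer(decoder_hidden),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), l1_penalty = l1_penalty,
         lr_decay = lr_decay, polish_epochs = as.integer(polish_epochs),
         polish_lr = polish_lr, early_stop = early_stop, seed = as.integer(seed),
         optimizer = "adam", init = "he_uniform", pool_size = 2L),
    class = "ae_config"
  )
}

ae_init_params <- function(config) {
  L <- config$n_timepoints
  F_ <- config$conv_filters
  flat_dim <- (L %/% 2L) * F_
  list(
    Wc1 = nn_init(2, F_)[1, , drop = FALSE],
    Wc2 = nn_init(2, F_)[2, , drop = FALSE],
    bc = rep(0, F_),
    gamma = rep(1, F_), beta = rep(0, F_),
    Wl = nn_init(flat_dim, config$latent_dim), bl = rep(0, config$latent_dim),
    Wd1 = nn_init(config$latent_dim, config$decoder_hidden),
    bd1 = rep(0, config$decoder_hidden),
    Wd2 = nn_init(config$decoder_hidden, L), bd2 = rep(0, L)
  )
}

# Full forward pass. X: n x L matrix. Returns activations needed by
# backprop plus the reconstruction and latent code.
ae_forward <- function(params, X, config, running, training) {
  n <- nrow(X); L <- config$n_timepoints
  A0 <- to_posmajor(X)
  cv <- nn_conv_relu_fwd(A0, n, params$Wc1, params$Wc2, params$bc)
  A1 <- cv$Z
  pl <- nn_pool_fwd(A1, n, L)
  bn <- nn_bn_fwd(pl$P, params$gamma, params$beta, running, training)
  dp <- nn_dropout_fwd(bn$Y, config$dropout_p, training)
  Fl <- nn_flatten(dp$Y, n)
  latent <- nn_dense_fwd(Fl, params$Wl, params$bl)
  H1pre <- nn_dense_fwd(latent, params$Wd1, params$bd1)
  H1 <- nn_relu_fwd(H1pre)
  recon <- nn_dense_fwd(H1, params$Wd2, params$bd2)
  list(recon = recon, latent = latent, cv = cv, A1 = A1, pl = pl, bn = bn,
       dp = dp, Fl = Fl, H1pre = H1pre, H1 = H1, running = bn$running)
}

ae_loss <- function(fw, X, config) {
  mse <- mean((fw$recon - X)^2)
  if (config$l1_penalty > 0) {
    mse + config$l1_penalty * mean(abs(fw$latent))
  } else {
    mse
  }
}

ae_backward <- function(params, fw, X, config, frozen = FALSE) {
  n <- nrow(X)
  dRecon <- 2 * (fw$recon - X) / length(X)
  g <- list()
  d2 <- nn_dense_bwd(fw$H1, params$Wd2, dRecon)
  g$Wd2 <- d2$dW; g$bd2 <- d2$db
  dH1pre <- nn_relu_bwd(d2$dX, fw$H1pre)
  d1 <- nn_dense_bwd(fw$latent, params$Wd1, dH1pre)
  g$Wd1 <- d1$dW; g$bd1 <- d1$db
  dLatent <- d1$dX
  if (config$l1_penalty > 0) {
    dLatent <- dLatent + config$l1_penalty * sign(fw$latent) / length(fw$latent)
  }
  dl <- nn_dense_bwd(fw$Fl, params$Wl, dLatent)
  g$Wl <- dl$dW; g$bl <- dl$db
  dD <- nn_unflatten(dl$dX, n, config$conv_filters)
  dB <- nn_dropout_bwd(fw$dp, dD)
  bnb <- if (frozen) {
    nn_bn_bwd_frozen(fw$bn, dB, params$gamma)
  } else {
    nn_bn_bwd(fw$bn, dB, params$gamma)
  }
  g$gamma <- bnb$dgamma; g$beta <- bnb$dbeta
  dZ1 <- nn_pool_relu_bwd(fw$pl, bnb$dX, fw$A1)
  cb <- nn_conv_bwd(fw$cv, dZ1, params$Wc1, params$Wc2, n, need_dA = FALSE)
  g$Wc1 <- cb$dW1; g$Wc2 <- cb$dW2; g$bc <- cb$db
  g
}

#' Train the convolutional autoencoder
#'
#' @param curves Curve tibble (see [extract_curves()]) or numeric matrix,
#'   one 60-point curve per row.
#' @param config An [ae_config()].
#' @return An object of class `dsc_autoencoder`: parameters, batch-norm
#'   running statistics, config, and `training_history` (per-epoch mean
#'   loss).
#' @export
train_autoencoder <- function(curves, config = ae_config()) {
  X <- if (is.matrix(curves)) curves else curve_matrix(curves)
  if (nrow(X) == 0) rlang::abort("cannot train an autoencoder on zero curves")
  if (ncol(X) != config$n_timepoints) {
    rlang::abort(sprintf("curves have %d time points but config expects %d",
                         ncol(X), config$n_timepoints))
  }
  if (nrow(X) < config$batch_size) {
    rlang::warn(sprintf(
      "only %d curves for batch size %d; training proceeds with smaller batches",
      nrow(X), config$batch_size
    ))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  params <- ae_init_params(config)
  running <- list(mean = rep(0, config$conv_filters),
                  var = rep(1, config$conv_filters))
  state <- adam_init(params)
  n <- nrow(X)
  history <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate
    if (isTRUE(config$lr_decay)) {
      if (epoch > 0.85 * config$epochs) {
        lr <- lr * 0.04
      } else if (epoch > 0.6 * config$epochs) {
        lr <- lr * 0.2
      }
    }
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      fw <- ae_forward(params, Xb, config, running, training = TRUE)
      running <- fw$running
      loss <- ae_loss(fw, Xb, config)
      if (!is.finite(loss)) {
        rlang::abort(sprintf(
          "training diverged (non-finite loss at epoch %d); lower the learning rate",
          epoch
        ))
      }
      grads <- ae_backward(params, fw, Xb, config)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
    }
    history <- c(history, ep_loss / n)
    if (config$early_stop && epoch > 20) {
      prev <- history[epoch - 20]
      if (prev > 0 && (prev - history[epoch]) / prev < 1e-4) break
    }
  }

  polish_history <- numeric(0)
  if (config$polish_epochs > 0) {
    # fine-tune the whole network on the deterministic inference path:
    # dropout disabled, batch-norm statistics frozen. This removes the
    # reconstruction blur left by dropout-noised training while staying
    # close to the regularized solution (small learning rate).
    pstate <- adam_init(params)
    for (epoch in seq_len(config$polish_epochs)) {
      lr <- config$polish_lr * if (epoch > 0.7 * config$polish_epochs) 0.2 else 1
      ord <- sample.int(n)
      ep_loss <- 0
      for (st in seq(1, n, by = config$batch_size)) {
        idx <- ord[st:min(st + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        fw <- ae_forward(params, Xb, config, running, training = FALSE)
        loss <- ae_loss(fw, Xb, config)
        if (!is.finite(loss)) break
        grads <- ae_backward(params, fw, Xb, config, frozen = TRUE)
        upd <- adam_step(params, grads, pstate, lr)
        params <- upd$params; pstate <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
      }
      polish_history <- c(polish_history, ep_loss / n)
    }
  }

  structure(
    list(params = params, running = running, config = config,
         training_history = history, polish_history = polish_history),
    class = "dsc_autoencoder"
  )
}

#' Encode curves into the latent space
#'
#' Deterministic inference pass: dropout disabled, batch-norm frozen at its
#' running statistics.
#'
#' @param model A trained [train_autoencoder()] model.
#' @param curves Curve tibble or matrix.
#' @return When given a tibble: a tibble carrying the metadata columns plus
#'   latent columns `l1 ... lK`. When given a matrix: an n x K matrix.
#' @export
encode_curves <- function(model, curves) {
  X <- if (is.matrix(curves)) curves else curve_matrix(curves)
  if (ncol(X) != model$config$n_timepoints) {
    rlang::abort(sprintf("curves have %d time points but the model expects %d",
                         ncol(X), model$config$n_timepoints))
  }
  fw <- ae_forward(model$params, X, model$config, model$running,
                   training = FALSE)
  lat <- fw$latent
  colnames(lat) <- paste0("l", seq_len(ncol(lat)))
  if (is.matrix(curves)) {
    return(lat)
  }
  meta <- curves[, setdiff(names(curves), curve_cols(curves)), drop = FALSE]
  dplyr::bind_cols(meta, tibble::as_tibble(lat))
}

#' Latent-column matrix of an encoded tibble
#'
#' @param df Tibble with latent columns `l1 ... lK`.
#' @return Numeric matrix.
#' @export
latent_matrix <- function(df) {
  cols <- grep("^l\\d+$", names(df), value = TRUE)
  as.matrix(df[, cols[order(as.integer(sub("^l", "", cols)))], drop = FALSE])
}

#' Decode latent vectors into 60-point curves
#'
#' @param model A trained autoencoder.
#' @param latents Matrix (n x latent_dim) or tibble with `l1 ... lK` columns.
#' @return Matrix of decoded curves, one row per latent vector.
#' @export
decode_latent <- function(model, latents) {
  Z <- if (is.matrix(latents)) latents else latent_matrix(latents)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != model$config$latent_dim) {
    rlang::abort(sprintf("latent vectors have length %d but the model expects %d",
                         ncol(Z), model$config$latent_dim))
  }
  H1 <- nn_relu_fwd(nn_dense_fwd(Z, model$params$Wd1, model$params$bd1))
  nn_dense_fwd(H1, model$params$Wd2, model$params$bd2)
}

#' Reconstruct curves through the autoencoder
#'
#' @param model A trained autoencoder.
#' @param curves Curve tibble or matrix.
#' @return Matrix of reconstructions, one row per curve.
#' @export
reconstruct_curves <- function(model, curves) {
  decode_latent(model, encode_curves(
    model, if (is.matrix(curves)) curves else curve_matrix(curves)
  ))
}

#' @export
print.dsc_autoencoder <- function(x, ...) {
  cat("1D convolutional autoencoder:", x$config$n_timepoints, "->",
      x$config$latent_dim, "->", x$config$n_timepoints, "\n")
  cat("filters:", x$config$conv_filters, " dropout:", x$config$dropout_p,
      " epochs trained:", length(x$training_history),
      " final loss:", signif(utils::tail(x$training_history, 1), 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dsc_autoencoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$training_history),
                 loss = x$training_history)
}

#' @exportS3Method generics::glance
glance.dsc_autoencoder <- function(x, ...) {
  tibble::tibble(
    epochs = length(x$training_history),
    final_loss = utils::tail(x$training_history, 1),
    latent_dim = x$config$latent_dim,
    conv_filters = x$config$conv_filters,
    learning_rate = x$config$learning_rate
  )
}

#' Explained variance of reconstructions
#'
#' Diagnostic: fraction of total curve variance captured by the autoencoder
#' reconstructions, \eqn{1 - SS_{res} / SS_{tot}}.
#'
#' @param model Trained autoencoder.
#' @param curves Curve tibble or matrix.
#' @return Scalar in (-Inf, 1].
#' @export
explained_variance <- function(model, curves) {
  X <- if (is.matrix(curves)) curves else curve_matrix(curves)
  R <- reconstruct_curves(model, X)
  1 - sum((X - R)^2) / sum(sweep(X, 2, colMeans(X))^2)
}

#' Serialize / restore an autoencoder model as JSON
#'
#' @param model Trained autoencoder.
#' @param path File path.
#' @return `write_autoencoder` returns `path` invisibly; `read_autoencoder`
#'   the restored model.
#' @export
write_autoencoder <- function(model, path) {
  lst <- list(
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else list(data = p)
    }),
    running = model$running,
    config = unclass(model$config),
    training_history = model$training_history
  )
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_autoencoder
#' @export
read_autoencoder <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(lst$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  cfg <- lst$config
  config <- do.call(ae_config, cfg[intersect(names(cfg), names(formals(ae_config)))])
  structure(
    list(params = params, running = lst$running, config = config,
         training_history = lst$training_history),
    class = "dsc_autoencoder"
  )
}
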