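# Shared fixtures. Heavy objects are built lazily and memoized so several
# test files can share one trained model.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# A small phantom: every tissue 100% its own archetype.
small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_phantom(phantom_spec(grid_shape = c(16, 16, 4), seed = 11))
  })
}

# Curve tibble extracted from the small phantom.
small_curves <- function() {
  fixture("small_curves", function() {
    ph <- small_phantom()
    extract_curves(ph$signal, ph$labels, patient_id = "ph1")
  })
}

# Noise-free archetype curves, normalized the way the pipeline normalizes.
clean_archetype_curves <- function(norm = 1) {
  archetype_curve_matrix_pkg(archetype_library()) / norm
}

# archetype_curve_matrix is internal; rebuild it from exported pieces.
archetype_curve_matrix_pkg <- function(archs, n_timepoints = 60, dt = 1.7) {
  out <- t(vapply(seq_len(nrow(archs)), function(i) {
    a <- archs[i, ]
    a$noise_sd <- 0
    generate_curve(a, n_timepoints, dt)
  }, numeric(n_timepoints)))
  rownames(out) <- archs$name
  out
}

# Replace the signal columns of a curve tibble.
set_curve_values <- function(df, mat) {
  df[, grep("^t\\d+$", names(df))] <- mat
  df
}

# Curve tibble wrapping a plain matrix with minimal metadata.
curves_from_matrix <- function(mat, tissue = "white_matter",
                               patient_id = "p1") {
  sig <- tibble::as_tibble(as.data.frame(mat),
                           .name_repair = ~ paste0("t", seq_len(ncol(mat))))
  dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id, x = seq_len(nrow(mat)),
                   y = 1L, z = 1L,
                   tissue = rep_len(tissue, nrow(mat))),
    sig
  )
}

# A quick-to-train autoencoder on noisy archetype curves (shared by the
# autoencoder and clustering unit tests; acceptance tests train their own at
# the sizes the criteria state).
small_trained_ae <- function() {
  fixture("small_trained_ae", function() {
    set.seed(402)
    lib <- archetype_library()
    clean <- archetype_curve_matrix_pkg(lib)
    n_per <- 120
    X <- do.call(rbind, lapply(1:9, function(i) {
      matrix(rep(clean[i, ], n_per), n_per, 60, byrow = TRUE) +
        rnorm(n_per * 60, 0, lib$noise_sd[i])
    })) / 100
    cfg <- ae_config(learning_rate = 2e-3, batch_size = 540, epochs = 150,
                     seed = 5)
    list(model = train_autoencoder(X, cfg), X = X,
         clean = clean / 100,
         truth = rep(lib$name, each = n_per))
  })
}
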