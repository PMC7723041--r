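# Study-scale fixtures for the acceptance tests: one autoencoder trained at
# the stated scale (5,000 archetype-library curves), one phantom clustering
# run, and one two-class tumor cohort with CNN + rCBV evaluation. Memoized
# so the expensive pieces are built once per test run.

# Practical training configuration: Adam at 2e-3 with step decay (the
# reference rates are documented defaults; see the methods vignette).
study_ae_config <- function(epochs = 300, seed = 2024L) {
  ae_config(learning_rate = 2e-3, batch_size = 2500, epochs = epochs,
            decoder_hidden = 64, polish_epochs = 400, seed = seed)
}

# 5,000 noisy curves drawn evenly from the 9-archetype library, with tissue
# labels so the pipeline's white-matter normalization applies as it would on
# a patient: the training set for the study autoencoder.
study_library_curves <- function(n_total = 5000, seed = 71L) {
  lib <- archetype_library()
  set.seed(seed)
  n_per <- rep(n_total %/% 9, 9)
  n_per[seq_len(n_total %% 9)] <- n_per[seq_len(n_total %% 9)] + 1
  clean <- archetype_curve_matrix_pkg(lib)
  X <- do.call(rbind, lapply(1:9, function(i) {
    matrix(rep(clean[i, ], n_per[i]), n_per[i], 60, byrow = TRUE) +
      rnorm(n_per[i] * 60, 0, lib$noise_sd[i])
  }))
  curves_from_matrix(X, tissue = rep(lib$name, n_per), patient_id = "study")
}

study_ae <- function() {
  fixture("study_ae", function() {
    # normalization only: the +/-1 SD exclusion rule is validated on its own
    # fixtures; on a low-noise multimodal phantom it would delete entire
    # bright tissue classes (see the methods vignette)
    curves <- normalize_to_white_matter(study_library_curves())
    model <- train_autoencoder(curves, study_ae_config())
    norm <- unname(attr(curves, "normalization_factor"))
    list(model = model, curves = curves, norm = norm,
         clean = archetype_curve_matrix_pkg(archetype_library()) / norm)
  })
}

# Full pipeline on a pure-mixture phantom: encode with the study
# autoencoder, k-means in latent space, prototypes, assignments, truth.
study_phantom_run <- function() {
  fixture("study_phantom_run", function() {
    ae <- study_ae()
    ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 8), seed = 301))
    curves <- extract_curves(ph$signal, ph$labels, "ph") |>
      normalize_to_white_matter()
    latents <- encode_curves(ae$model, curves)
    km <- fit_kmeans(latents, k = 9, seed = 302, ae_model = ae$model)
    assigned <- assign_clusters(km, latents)
    truth_key <- paste(ph$truth$x, ph$truth$y, ph$truth$z)
    truth_arch <- ph$truth$archetype[match(paste(curves$x, curves$y, curves$z),
                                           truth_key)]
    list(phantom = ph, curves = curves, km = km, assigned = assigned,
         truth_arch = truth_arch, ae = ae)
  })
}

# Two-class tumor cohort sharing depth_fraction but differing in
# recovery_fraction by 0.55: the scalar-rCBV failure regime.
study_cohort_archetypes <- function() {
  list(
    low_recovery = archetype("tumor_low_psr", baseline = 120,
                             depth_fraction = 0.55, time_to_peak = 9,
                             wash_sharpness = 4, recovery_fraction = 0.15,
                             noise_sd = 1),
    high_recovery = archetype("tumor_high_psr", baseline = 120,
                              depth_fraction = 0.55, time_to_peak = 9,
                              wash_sharpness = 4, recovery_fraction = 0.70,
                              noise_sd = 1)
  )
}

# Cohort pipeline: normalize per patient, train a cohort autoencoder,
# cluster, select dominant clusters per lesion, train the CNN on decoded
# dominant-cluster curves of the training patients, score held-out patients
# with both the CNN and mean lesion rCBV.
study_cohort_run <- function() {
  fixture("study_cohort_run", function() {
    sim <- simulate_tumor_cohort(study_cohort_archetypes(), n_per_class = 30,
                                 lesion_voxels = 80, wm_voxels = 40,
                                 seed = 901)
    raw <- sim$curves
    curves <- normalize_to_white_matter(raw) |> remove_outliers()
    pats <- names(sim$diagnoses)
    classes <- split(pats, sim$diagnoses)
    train_pat <- sort(unlist(lapply(classes, function(p) p[1:20])))
    test_pat <- setdiff(pats, train_pat)

    cfg <- ae_config(learning_rate = 2e-3, batch_size = 2500, epochs = 250,
                     decoder_hidden = 64, polish_epochs = 250, seed = 902)
    ae <- train_autoencoder(curves[curves$patient_id %in% train_pat, ], cfg)
    latents <- encode_curves(ae, curves)
    km <- fit_kmeans(latents[latents$patient_id %in% train_pat, ],
                     k = 9, seed = 903, ae_model = ae)
    assigned <- assign_clusters(km, latents)
    decoded <- decode_latent(ae, latents)

    ds_all <- build_cnn_dataset(assigned, decoded, sim$diagnoses)
    ds_train <- ds_all[ds_all$patient_id %in% train_pat, ]

    list(sim = sim, raw = raw, curves = curves, ae = ae, km = km,
         assigned = assigned, decoded = decoded, ds_train = ds_train,
         ds_all = ds_all, train_pat = train_pat, test_pat = test_pat)
  })
}

study_cnn_config <- function(seed) {
  cnn_config(learning_rate = 2e-3, batch_size = 1000, epochs = 200,
             seed = seed)
}

# Patient-level scores for the held-out patients under one CNN seed.
study_cohort_scores <- function(cnn_seed) {
  co <- study_cohort_run()
  cnn <- train_cnn(co$ds_train, study_cnn_config(cnn_seed))
  ds_test <- co$ds_all[co$ds_all$patient_id %in% co$test_pat, ]
  pred <- predict_patient(cnn, ds_test, aggregation = "mean")
  truth <- co$sim$diagnoses[pred$patient_id]
  # positive class: the low-recovery tumor
  tibble::tibble(
    patient_id = pred$patient_id,
    score = pred[["low_recovery"]],
    label = as.integer(truth == "low_recovery")
  )
}
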