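# End-to-end convenience wrappers: preprocessing -> autoencoder -> k-means
# -> frequency table, and a multi-patient synthetic tumor cohort.

#' Run the temporal-pattern pipeline on a curve set
#'
#' Normalizes curves to the white-matter median, removes outlier curves,
#' trains the autoencoder, encodes all retained curves, fits k-means in the
#' latent space, decodes cluster prototypes, assigns clusters and tabulates
#' per-tissue frequencies.
#'
#' @param curves Curve tibble from [extract_curves()].
#' @param config An [ae_config()].
#' @param k Number of temporal-pattern clusters, default 9.
#' @param seed Seed for the k-means restarts.
#' @param train_subsample Optional cap on the number of curves used to train
#'   the autoencoder (sampled without replacement, seeded); all curves are
#'   still encoded and clustered.
#' @param outlier_mode Passed to [remove_outliers()].
#' @return List of class `dsc_pipeline`: `curves` (retained, normalized),
#'   `ae`, `latents`, `clusters` (model), `assigned`, `frequency`.
#' @export
run_pattern_pipeline <- function(curves, config = ae_config(), k = 9,
                                 seed = 1L, train_subsample = NULL,
                                 outlier_mode = "per-curve") {
  curves <- normalize_to_white_matter(curves)
  curves <- remove_outliers(curves, mode = outlier_mode)
  train_set <- curves
  if (!is.null(train_subsample) && nrow(curves) > train_subsample) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    train_set <- curves[sample.int(nrow(curves), train_subsample), ]
  }
  ae <- train_autoencoder(train_set, config)
  latents <- encode_curves(ae, curves)
  km <- fit_kmeans(latents, k = k, seed = seed, ae_model = ae)
  assigned <- assign_clusters(km, latents)
  freq <- cluster_frequency_table(assigned, group = "tissue", k = k)
  structure(
    list(curves = curves, ae = ae, latents = latents, clusters = km,
         assigned = assigned, frequency = freq),
    class = "dsc_pipeline"
  )
}

#' @export
print.dsc_pipeline <- function(x, ...) {
  cat("DSC temporal-pattern pipeline:", nrow(x$curves), "curves,",
      x$clusters$k, "patterns\n")
  print(x$frequency)
  invisible(x)
}

#' Simulate a multi-patient tumor cohort
#'
#' Generates per-patient curve sets for a two-class tumor study: every
#' patient has a block of white-matter voxels (for normalization) and a
#' contrast-enhancing lesion drawn from the class archetype, with
#' patient-level heterogeneity expressed as jitter on baseline and depth
#' (shared between classes, so scalar perfusion summaries overlap while the
#' temporal shape stays class-specific).
#'
#' @param class_archetypes Named list of two one-row archetype tibbles; names
#'   are the diagnosis labels.
#' @param n_per_class Patients per class.
#' @param lesion_voxels Lesion curves per patient.
#' @param wm_voxels White-matter curves per patient.
#' @param depth_jitter_sd SD of the per-patient normal jitter added to the
#'   lesion archetype's depth_fraction (clipped to \[0.02, 0.95\]).
#' @param baseline_jitter_sd SD of the per-patient multiplicative
#'   (log-normal) baseline jitter.
#' @param n_timepoints,dt Temporal sampling.
#' @param seed Integer seed.
#' @return List: `curves` (tibble over all patients, lesion voxels labeled
#'   `glioblastoma_cel`, plus `white_matter` voxels) and `diagnoses` (named
#'   character vector patient_id -> class label).
#' @export
simulate_tumor_cohort <- function(class_archetypes, n_per_class = 20,
                                  lesion_voxels = 80, wm_voxels = 40,
                                  depth_jitter_sd = 0.08,
                                  baseline_jitter_sd = 0.08,
                                  n_timepoints = 60, dt = 1.7, seed = 1L) {
  stopifnot(length(class_archetypes) == 2, !is.null(names(class_archetypes)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  wm <- archetype_library()[archetype_library()$name == "white_matter", ]
  out <- list()
  diagnoses <- character(0)
  pid <- 0
  for (cls in names(class_archetypes)) {
    base_arch <- class_archetypes[[cls]]
    for (i in seq_len(n_per_class)) {
      pid <- pid + 1
      p <- sprintf("pt%03d", pid)
      diagnoses[[p]] <- cls
      arch <- base_arch
      arch$depth_fraction <- min(0.95, max(
        0.02, arch$depth_fraction + stats::rnorm(1, 0, depth_jitter_sd)
      ))
      arch$baseline <- arch$baseline * exp(stats::rnorm(1, 0, baseline_jitter_sd))
      clean_lesion <- generate_curve(dplyr::mutate(arch, noise_sd = 0),
                                     n_timepoints, dt)
      clean_wm <- generate_curve(dplyr::mutate(wm, noise_sd = 0),
                                 n_timepoints, dt)
      les <- matrix(rep(clean_lesion, lesion_voxels), lesion_voxels,
                    n_timepoints, byrow = TRUE) +
        stats::rnorm(lesion_voxels * n_timepoints, 0, base_arch$noise_sd)
      wmm <- matrix(rep(clean_wm, wm_voxels), wm_voxels, n_timepoints,
                    byrow = TRUE) +
        stats::rnorm(wm_voxels * n_timepoints, 0, wm$noise_sd)
      mat <- rbind(les, wmm)
      sig <- tibble::as_tibble(mat, .name_repair = ~ paste0("t", seq_len(n_timepoints)))
      out[[p]] <- dplyr::bind_cols(
        tibble::tibble(
          patient_id = p,
          x = seq_len(nrow(mat)), y = 1L, z = 1L,
          tissue = c(rep("glioblastoma_cel", lesion_voxels),
                     rep("white_matter", wm_voxels))
        ),
        sig
      )
    }
  }
  list(curves = dplyr::bind_rows(out), diagnoses = diagnoses)
}
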