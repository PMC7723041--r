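# Curve archetypes and the gamma-variate signal model for synthetic DSC data.

#' Canonical tissue vocabulary
#'
#' The nine tissue classes used throughout the pipeline, in their canonical
#' order. Integer label codes in label volumes are positions in this vector
#' (1-based); 0 is background.
#'
#' @return Character vector of length 9.
#' @export
tissue_types <- function() {
  c(
    "glioblastoma_cel", "pcnsl_cel", "metastasis_cel",
    "nonenhancing_tumor", "edema", "gray_matter",
    "white_matter", "csf", "necrosis"
  )
}

#' Construct a curve archetype
#'
#' An archetype is a parametric description of one temporal pattern of a DSC
#' time-signal intensity curve: a pre-bolus baseline, a bolus-induced signal
#' drop of a given fractional depth reached `time_to_peak` seconds after
#' bolus arrival, and a tail that recovers a given fraction of the drop by
#' the end of the acquisition. The first-pass kinetics follow a gamma-variate
#' concentration curve; `wash_sharpness` is its dimensionless shape
#' parameter (larger = sharper wash-in/wash-out).
#'
#' @param name Label for the archetype.
#' @param baseline Pre-bolus signal, arbitrary units (> 0).
#' @param depth_fraction Fraction of baseline lost at the nadir, in \[0, 1\].
#' @param time_to_peak Seconds from bolus arrival to the nadir (> 0).
#' @param bolus_arrival Seconds from acquisition start to bolus arrival.
#' @param wash_sharpness Gamma-variate shape parameter (> 0).
#' @param recovery_fraction Fraction of the signal drop recovered at the last
#'   time point, in \[0, 1\].
#' @param noise_sd Standard deviation of additive Gaussian noise, signal units.
#' @return A one-row tibble with the validated fields.
#' @export
archetype <- function(name, baseline, depth_fraction, time_to_peak,
                      bolus_arrival = 20, wash_sharpness = 3,
                      recovery_fraction = 0.5, noise_sd = 0) {
  check_num <- function(x, field, lo = -Inf, hi = Inf) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < lo || x > hi) {
      rlang::abort(sprintf(
        "archetype field '%s' must be a finite number in [%s, %s], got %s",
        field, format(lo), format(hi), paste(format(x), collapse = ",")
      ))
    }
    invisible(x)
  }
  check_num(baseline, "baseline", lo = .Machine$double.eps)
  check_num(depth_fraction, "depth_fraction", 0, 1)
  check_num(time_to_peak, "time_to_peak", lo = .Machine$double.eps)
  check_num(bolus_arrival, "bolus_arrival", 0)
  check_num(wash_sharpness, "wash_sharpness", lo = .Machine$double.eps)
  check_num(recovery_fraction, "recovery_fraction", 0, 1)
  check_num(noise_sd, "noise_sd", 0)
  tibble::tibble(
    name = as.character(name), baseline = baseline,
    depth_fraction = depth_fraction, time_to_peak = time_to_peak,
    bolus_arrival = bolus_arrival, wash_sharpness = wash_sharpness,
    recovery_fraction = recovery_fraction, noise_sd = noise_sd
  )
}

#' Library of nine tissue archetypes
#'
#' One archetype per tissue class, encoding the qualitative orderings seen in
#' DSC studies of brain tumors: glioblastoma-like lesions show an acute deep
#' signal drop with small relative recovery; lymphoma (PCNSL)-like lesions a
#' less acute drop with high recovery; metastasis-like lesions the deepest
#' drop with very low recovery; necrosis a high, nearly flat baseline; white
#' matter an intermediate baseline with a small drop. Baselines are spaced so
#' that noise-free curves of distinct archetypes are well separated relative
#' to the default noise level.
#'
#' @return A tibble with 9 rows, one archetype per tissue in
#'   [tissue_types()] order.
#' @export
archetype_library <- function() {
  dplyr::bind_rows(
    archetype("glioblastoma_cel", baseline = 138, depth_fraction = 0.55,
              time_to_peak = 9, wash_sharpness = 4,
              recovery_fraction = 0.30, noise_sd = 1),
    archetype("pcnsl_cel", baseline = 128, depth_fraction = 0.40,
              time_to_peak = 13, wash_sharpness = 2.5,
              recovery_fraction = 0.85, noise_sd = 1),
    archetype("metastasis_cel", baseline = 155, depth_fraction = 0.68,
              time_to_peak = 8, wash_sharpness = 5,
              recovery_fraction = 0.08, noise_sd = 1),
    archetype("nonenhancing_tumor", baseline = 76, depth_fraction = 0.30,
              time_to_peak = 12, wash_sharpness = 3,
              recovery_fraction = 0.70, noise_sd = 1),
    archetype("edema", baseline = 88, depth_fraction = 0.22,
              time_to_peak = 14, wash_sharpness = 3,
              recovery_fraction = 0.80, noise_sd = 1),
    archetype("gray_matter", baseline = 114, depth_fraction = 0.40,
              time_to_peak = 9, wash_sharpness = 3.5,
              recovery_fraction = 0.90, noise_sd = 1),
    archetype("white_matter", baseline = 100, depth_fraction = 0.15,
              time_to_peak = 11, wash_sharpness = 3,
              recovery_fraction = 0.92, noise_sd = 1),
    archetype("csf", baseline = 175, depth_fraction = 0.08,
              time_to_peak = 16, wash_sharpness = 2,
              recovery_fraction = 0.95, noise_sd = 1),
    archetype("necrosis", baseline = 195, depth_fraction = 0.03,
              time_to_peak = 18, wash_sharpness = 2,
              recovery_fraction = 0.90, noise_sd = 1)
  )
}

# Solve the concentration model for one archetype on a fine time grid.
# C(t) = a * g(t) + b * h(t), with g a unit-peak gamma variate and h the
# normalized running integral of g (leakage plateau). a and b are chosen so
# that max C equals -log(1 - depth) and C at the last sample time equals
# -log(1 - (1 - recovery) * depth).
curve_model <- function(arch, n_timepoints, dt, refine = 20) {
  t_end <- (n_timepoints - 1) * dt
  tf <- seq(0, t_end, by = dt / refine)
  a_shape <- arch$wash_sharpness
  tau <- pmax(tf - arch$bolus_arrival, 0)
  g <- (tau / arch$time_to_peak)^a_shape *
    exp(a_shape * (1 - tau / arch$time_to_peak))
  g[tau == 0] <- 0
  cumg <- cumsum(g) * (dt / refine)
  h <- if (cumg[length(cumg)] > 0) cumg / cumg[length(cumg)] else cumg

  depth <- min(arch$depth_fraction, 1 - 1e-8)
  c_max <- -log(1 - depth)
  c_end <- -log(1 - (1 - arch$recovery_fraction) * depth)
  g_end <- g[length(g)]

  if (c_max <= 0) {
    cf <- rep(0, length(tf))
  } else {
    obj <- function(a) {
      b <- max(0, c_end - a * g_end)
      max(a * g + b * h) - c_max
    }
    a <- stats::uniroot(obj, c(0, 2 * c_max + 1), tol = 1e-12)$root
    b <- max(0, c_end - a * g_end)
    cf <- a * g + b * h
  }
  list(t_fine = tf, conc_fine = cf,
       signal_fine = arch$baseline * exp(-cf))
}

#' Generate one synthetic DSC time-signal intensity curve
#'
#' Evaluates the archetype's signal model \eqn{S(t) = S_0 e^{-C(t)}} at
#' `n_timepoints` samples spaced `dt` seconds apart, where \eqn{C(t)} is a
#' gamma-variate first pass plus a leakage plateau, scaled so the nadir
#' equals `baseline * (1 - depth_fraction)` and the tail settles at
#' `baseline - (1 - recovery_fraction) * baseline * depth_fraction`.
#' Gaussian noise of standard deviation `noise_sd` is added per time point.
#'
#' @param arch A one-row archetype tibble (see [archetype()]).
#' @param n_timepoints Number of samples (>= 2); default 60.
#' @param dt Sampling interval in seconds; default 1.7.
#' @param seed Optional integer seed; with `noise_sd > 0` the same seed gives
#'   the same curve. Ignored (curve is deterministic) when `noise_sd = 0`.
#' @return Numeric vector of length `n_timepoints`.
#' @export
generate_curve <- function(arch, n_timepoints = 60, dt = 1.7, seed = NULL) {
  if (is.list(arch) && !is.data.frame(arch)) arch <- tibble::as_tibble(arch)
  arch <- do.call(archetype, as.list(arch[1, intersect(
    names(arch),
    c("name", "baseline", "depth_fraction", "time_to_peak", "bolus_arrival",
      "wash_sharpness", "recovery_fraction", "noise_sd")
  )]))
  if (n_timepoints < 2) rlang::abort("n_timepoints must be >= 2")
  if (dt <= 0) rlang::abort("dt must be > 0")
  m <- curve_model(arch, n_timepoints, dt)
  s <- m$signal_fine[seq(1, length(m$t_fine), by = 20)]
  if (arch$noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    s <- s + stats::rnorm(n_timepoints, 0, arch$noise_sd)
  }
  s
}

# Noise-free curves for a whole archetype table: rows = archetypes.
archetype_curve_matrix <- function(archs, n_timepoints = 60, dt = 1.7) {
  out <- t(vapply(seq_len(nrow(archs)), function(i) {
    a <- archs[i, ]
    a$noise_sd <- 0
    generate_curve(a, n_timepoints, dt)
  }, numeric(n_timepoints)))
  rownames(out) <- archs$name
  out
}
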