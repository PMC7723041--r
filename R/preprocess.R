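# Voxelwise curve extraction, white-matter normalization, outlier exclusion.

# Names of the signal columns of a curve tibble, in temporal order.
curve_cols <- function(df) {
  cols <- grep("^t\\d+$", names(df), value = TRUE)
  cols[order(as.integer(sub("^t", "", cols)))]
}

#' Extract the signal matrix from a curve tibble
#'
#' @param df A curve tibble with signal columns `t1 ... tN`.
#' @return Numeric matrix, one row per voxel curve.
#' @export
curve_matrix <- function(df) {
  as.matrix(df[, curve_cols(df), drop = FALSE])
}

# Build a curve tibble from a matrix plus metadata columns.
set_curve_matrix <- function(df, mat) {
  df[, curve_cols(df)] <- mat
  df
}

#' Extract per-voxel time-signal curves from a 4D volume
#'
#' Pulls one 60-point (or `dim(signal)[4]`-point) curve per voxel carrying a
#' non-background label, and attaches the voxel coordinate and tissue name.
#' Curves containing non-finite samples are dropped with a warning.
#'
#' @param signal 4D numeric array (x, y, z, t).
#' @param labels 3D integer array of tissue codes (0 = background; codes are
#'   positions in [tissue_types()]).
#' @param patient_id Identifier recorded on every record.
#' @return A tibble with columns `patient_id`, `x`, `y`, `z`, `tissue`, and
#'   signal columns `t1 ... tN`, one row per labeled voxel.
#' @export
extract_curves <- function(signal, labels, patient_id = "patient") {
  ds <- dim(signal); dl <- dim(labels)
  if (length(ds) != 4) rlang::abort("signal must be a 4D array (x, y, z, t)")
  if (length(dl) != 3 || any(ds[1:3] != dl)) {
    rlang::abort("label volume shape must match the spatial shape of the signal")
  }
  nt <- ds[4]
  idx <- which(labels != 0)
  if (!length(idx)) {
    rlang::warn("label volume has no labeled voxels; returning an empty curve set")
  }
  coords <- arrayInd(idx, dl)
  flat <- matrix(signal, prod(dl), nt)
  mat <- flat[idx, , drop = FALSE]
  ok <- rowSums(!is.finite(mat)) == 0
  if (any(!ok)) {
    rlang::warn(sprintf("dropped %d curve(s) with non-finite samples", sum(!ok)))
  }
  out <- tibble::tibble(
    patient_id = patient_id,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    tissue = tissue_types()[labels[idx]]
  )
  sig <- tibble::as_tibble(mat, .name_repair = ~ paste0("t", seq_len(nt)))
  out <- dplyr::bind_cols(out, sig)[ok, , drop = FALSE]
  out
}

#' Normalize curves to the white-matter median
#'
#' Divides every curve by one scalar per patient: the median of all
#' white-matter samples, pooled over white-matter voxels and time points.
#' A scalar (rather than per-timepoint) factor preserves curve shape, which
#' is the feature the autoencoder must learn. After normalization the pooled
#' white-matter median equals 1 up to floating point.
#'
#' @param curves Curve tibble from [extract_curves()]; must contain at least
#'   one `white_matter` voxel per patient.
#' @return The normalized tibble, with the per-patient factors stored in
#'   `attr(, "normalization_factor")` (named numeric vector).
#' @export
normalize_to_white_matter <- function(curves) {
  pats <- unique(curves$patient_id)
  factors <- stats::setNames(numeric(length(pats)), pats)
  mat <- curve_matrix(curves)
  for (p in pats) {
    sel <- curves$patient_id == p
    wm <- sel & curves$tissue == "white_matter"
    if (!any(wm)) {
      rlang::abort(paste0("patient '", p, "' has no white-matter voxels; ",
                          "white-matter normalization is undefined"))
    }
    f <- stats::median(mat[wm, , drop = FALSE])
    if (!is.finite(f) || f <= 0) {
      rlang::abort(paste0("white-matter median for patient '", p,
                          "' is not positive; cannot normalize"))
    }
    mat[sel, ] <- mat[sel, , drop = FALSE] / f
    factors[[p]] <- f
  }
  out <- set_curve_matrix(curves, mat)
  attr(out, "normalization_factor") <- factors
  out
}

#' Exclude outlier curves by the one-standard-deviation rule
#'
#' Summarizes each curve by its mean signal over time, computes the mean and
#' standard deviation of those summaries per patient, and retains curves
#' whose summary lies within one standard deviation of the mean
#' (`per-curve` mode, the default). The alternative `per-timepoint` mode
#' requires every sample of a curve to lie within one SD of that time
#' point's mean. When the SD is zero nothing is removed.
#'
#' @param curves Curve tibble (>= 2 rows).
#' @param mode `"per-curve"` (default) or `"per-timepoint"`.
#' @return Filtered tibble; `attr(, "n_removed")` records the count removed,
#'   `attr(, "outlier_mode")` the rule used. Attributes present on input
#'   (e.g. normalization factors) are carried through.
#' @export
remove_outliers <- function(curves, mode = c("per-curve", "per-timepoint")) {
  mode <- match.arg(mode)
  if (nrow(curves) < 2) rlang::abort("need at least 2 curves to define outliers")
  mat <- curve_matrix(curves)
  keep <- rep(TRUE, nrow(curves))
  for (p in unique(curves$patient_id)) {
    sel <- which(curves$patient_id == p)
    sub <- mat[sel, , drop = FALSE]
    if (mode == "per-curve") {
      s <- rowMeans(sub)
      mu <- mean(s); sd <- stats::sd(s)
      if (is.finite(sd) && sd > 0) keep[sel] <- abs(s - mu) <= sd
    } else {
      mu <- colMeans(sub); sd <- apply(sub, 2, stats::sd)
      sd[!is.finite(sd) | sd == 0] <- Inf
      dev <- abs(sweep(sub, 2, mu)) <= matrix(sd, nrow(sub), ncol(sub), byrow = TRUE)
      keep[sel] <- rowSums(!dev) == 0
    }
  }
  out <- curves[keep, , drop = FALSE]
  attr(out, "normalization_factor") <- attr(curves, "normalization_factor")
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "outlier_mode") <- mode
  out
}

#' Read and write curve tables
#'
#' Curve tables are stored as plain CSV (one row per voxel, columns
#' `patient_id, x, y, z, tissue, t1..tN`) plus an optional JSON sidecar with
#' normalization factors and outlier-removal counts.
#'
#' @param curves Curve tibble.
#' @param path CSV path; sidecar written to `<path>.json` when metadata
#'   attributes are present.
#' @return `write_curves` returns `path` invisibly; `read_curves` the tibble
#'   with attributes restored when a sidecar is found.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  meta <- list(
    # as.list keeps patient names through auto_unbox serialization
    normalization_factor = as.list(attr(curves, "normalization_factor")),
    n_removed = attr(curves, "n_removed"),
    outlier_mode = attr(curves, "outlier_mode")
  )
  if (any(!vapply(meta, is.null, logical(1)))) {
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "normalization_factor") <- unlist(meta$normalization_factor)
    attr(out, "n_removed") <- meta$n_removed
    attr(out, "outlier_mode") <- meta$outlier_mode
  }
  out
}
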