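# Labeled 3D digital phantom with per-voxel DSC curves.

#' Default box layout for the digital phantom
#'
#' Partitions the grid into nine axis-aligned boxes, one per tissue class,
#' covering the whole volume. Sizes roughly follow anatomy: white and gray
#' matter largest, lesion compartments smallest.
#'
#' @param grid_shape Integer vector of length 3 (voxels per axis). The first
#'   axis must have at least 32 voxels' worth of proportions; any shape with
#'   `grid_shape[1] >= 8` works because boundaries are computed by fractions.
#' @return Named list of regions; each region is a list with integer ranges
#'   `x`, `y`, `z` (inclusive).
#' @export
phantom_layout_default <- function(grid_shape = c(32, 32, 8)) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  # contiguous non-empty segments with sizes proportional to `shares`
  # (largest-remainder allocation)
  segments <- function(n, shares) {
    k <- length(shares)
    if (n < k) rlang::abort("grid axis too small for the default layout")
    raw <- shares / sum(shares) * (n - k)
    sizes <- floor(raw) + 1L
    rem <- n - sum(sizes)
    if (rem > 0) {
      ord <- order(raw - floor(raw), decreasing = TRUE)
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
    hi <- cumsum(sizes)
    lo <- c(1L, utils::head(hi, -1) + 1L)
    Map(function(a, b) c(as.integer(a), as.integer(b)), lo, hi)
  }
  xs <- segments(nx, c(12, 8, 4, 4, 4))       # WM | GM | CSF | edema+NET | lesions
  yd <- segments(ny, c(16, 16))               # split of the edema/NET slab
  ye <- segments(ny, c(10, 10, 7, 5))         # split of the lesion slab
  zall <- c(1L, as.integer(nz))
  yall <- c(1L, as.integer(ny))
  list(
    white_matter       = list(x = xs[[1]], y = yall, z = zall),
    gray_matter        = list(x = xs[[2]], y = yall, z = zall),
    csf                = list(x = xs[[3]], y = yall, z = zall),
    edema              = list(x = xs[[4]], y = yd[[1]], z = zall),
    nonenhancing_tumor = list(x = xs[[4]], y = yd[[2]], z = zall),
    glioblastoma_cel   = list(x = xs[[5]], y = ye[[1]], z = zall),
    pcnsl_cel          = list(x = xs[[5]], y = ye[[2]], z = zall),
    metastasis_cel     = list(x = xs[[5]], y = ye[[3]], z = zall),
    necrosis           = list(x = xs[[5]], y = ye[[4]], z = zall)
  )
}

#' Specify a digital DSC phantom
#'
#' Bundles everything needed to generate a labeled 4D phantom: grid shape,
#' temporal sampling, a tissue layout (boxes per tissue), per-tissue mixtures
#' over curve archetypes (to emulate intratumoral heterogeneity), and a seed.
#'
#' @param grid_shape Voxels per axis, default `c(32, 32, 8)`.
#' @param n_timepoints Samples per curve, default 60.
#' @param dt Sampling interval in seconds, default 1.7.
#' @param tissue_layout Named list of box regions as in
#'   [phantom_layout_default()]. Tissues absent from the layout are simply
#'   not simulated. Regions must not overlap.
#' @param tissue_mixtures Named list: for each tissue, a named probability
#'   vector over archetype names. Default: each tissue draws 100% from its
#'   own archetype.
#' @param archetypes Archetype table, default [archetype_library()].
#' @param seed Integer seed driving all sampling (archetype draws, then
#'   noise, in that fixed order).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 8), n_timepoints = 60,
                         dt = 1.7, tissue_layout = NULL,
                         tissue_mixtures = NULL,
                         archetypes = archetype_library(), seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    rlang::abort("grid_shape must be 3 positive integers")
  }
  if (n_timepoints < 2) rlang::abort("n_timepoints must be >= 2")
  if (dt <= 0) rlang::abort("dt must be > 0")
  if (is.null(tissue_layout)) tissue_layout <- phantom_layout_default(grid_shape)
  unknown <- setdiff(names(tissue_layout), tissue_types())
  if (length(unknown)) {
    rlang::abort(paste("unknown tissue(s) in layout:", paste(unknown, collapse = ", ")))
  }
  if (is.null(tissue_mixtures)) {
    tissue_mixtures <- lapply(names(tissue_layout), function(tt) {
      stats::setNames(1, tt)
    })
    names(tissue_mixtures) <- names(tissue_layout)
  }
  for (tt in names(tissue_layout)) {
    mix <- tissue_mixtures[[tt]]
    if (is.null(mix)) rlang::abort(paste("no mixture for tissue", tt))
    if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
      rlang::abort(paste("mixture for", tt, "must be a probability vector summing to 1"))
    }
    if (!all(names(mix) %in% archetypes$name)) {
      rlang::abort(paste("mixture for", tt, "references unknown archetypes"))
    }
  }
  structure(
    list(grid_shape = as.integer(grid_shape), n_timepoints = as.integer(n_timepoints),
         dt = dt, tissue_layout = tissue_layout,
         tissue_mixtures = tissue_mixtures, archetypes = archetypes,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Rasterize the box layout into a 3D integer label volume; error on overlap.
layout_to_labels <- function(spec) {
  lab <- array(0L, spec$grid_shape)
  codes <- stats::setNames(seq_along(tissue_types()), tissue_types())
  for (tt in names(spec$tissue_layout)) {
    r <- spec$tissue_layout[[tt]]
    xs <- r$x[1]:r$x[2]; ys <- r$y[1]:r$y[2]; zs <- r$z[1]:r$z[2]
    if (max(xs) > spec$grid_shape[1] || max(ys) > spec$grid_shape[2] ||
        max(zs) > spec$grid_shape[3] || min(c(xs, ys, zs)) < 1) {
      rlang::abort(paste("region for", tt, "falls outside the grid"))
    }
    if (any(lab[xs, ys, zs] != 0L)) {
      rlang::abort(paste("tissue_layout regions overlap at tissue", tt))
    }
    lab[xs, ys, zs] <- codes[[tt]]
  }
  lab
}

#' Generate a digital DSC phantom
#'
#' Builds the label volume from the layout, draws one generating archetype
#' per labeled voxel from its tissue's mixture, evaluates the noise-free
#' archetype curve once per archetype, and adds per-voxel Gaussian noise.
#' All randomness is driven by `spec$seed` in a fixed stream order
#' (archetype draws by tissue in layout order, then noise in voxel order),
#' so runs are bit-reproducible.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `signal` (4D array
#'   x,y,z,t), `labels` (3D integer array), `truth` (tibble with voxel
#'   coordinates, tissue and generating archetype), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- layout_to_labels(spec)
  nt <- spec$n_timepoints
  base_curves <- archetype_curve_matrix(spec$archetypes, nt, spec$dt)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  # archetype draws, per tissue in layout order
  truth <- list()
  for (tt in names(spec$tissue_layout)) {
    code <- match(tt, tissue_types())
    idx <- which(labels == code)  # column-major voxel order within tissue
    mix <- spec$tissue_mixtures[[tt]]
    draw <- if (length(mix) == 1) {
      rep(names(mix), length(idx))
    } else {
      sample(names(mix), length(idx), replace = TRUE, prob = mix)
    }
    truth[[tt]] <- tibble::tibble(lin_index = idx, tissue = tt, archetype = draw)
  }
  truth <- dplyr::bind_rows(truth)
  truth <- dplyr::arrange(truth, .data$lin_index)
  coords <- arrayInd(truth$lin_index, spec$grid_shape)
  truth$x <- coords[, 1]; truth$y <- coords[, 2]; truth$z <- coords[, 3]

  signal <- array(0, c(spec$grid_shape, nt))
  arch_rows <- match(truth$archetype, spec$archetypes$name)
  curves <- base_curves[arch_rows, , drop = FALSE]
  noise_sd <- spec$archetypes$noise_sd[arch_rows]
  if (any(noise_sd > 0)) {
    curves <- curves + matrix(stats::rnorm(length(curves)), nrow(curves), nt) * noise_sd
  }
  nvox <- prod(spec$grid_shape)
  flat <- matrix(signal, nvox, nt)
  flat[truth$lin_index, ] <- curves
  signal <- array(flat, c(spec$grid_shape, nt))

  structure(
    list(signal = signal, labels = labels,
         truth = dplyr::select(truth, "x", "y", "z", "tissue", "archetype"),
         spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("DSC digital phantom:", paste(x$spec$grid_shape, collapse = " x "),
      "voxels,", x$spec$n_timepoints, "time points (dt =", x$spec$dt, "s)\n")
  cat("labeled voxels:", nrow(x$truth), "across",
      length(unique(x$truth$tissue)), "tissues\n")
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the 4D signal and 3D label volumes as NIfTI-1, the ground-truth
#' archetype assignments as CSV, and the spec as YAML.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    signal = file.path(dir, "dsc.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    truth = file.path(dir, "truth.csv"),
    spec = file.path(dir, "spec.yaml")
  )
  RNifti::writeNifti(RNifti::asNifti(phantom$signal), paths[["signal"]])
  RNifti::writeNifti(RNifti::asNifti(phantom$labels, datatype = "int16"),
                     paths[["labels"]])
  utils::write.csv(phantom$truth, paths[["truth"]], row.names = FALSE)
  write_phantom_spec(phantom$spec, paths[["spec"]])
  invisible(paths)
}

#' Round-trip a phantom spec through YAML
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns the reconstructed `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  lst <- list(
    grid_shape = spec$grid_shape, n_timepoints = spec$n_timepoints,
    dt = spec$dt, seed = spec$seed,
    tissue_layout = lapply(spec$tissue_layout, function(r) {
      lapply(r, as.integer)
    }),
    tissue_mixtures = lapply(spec$tissue_mixtures, as.list),
    archetypes = lapply(seq_len(nrow(spec$archetypes)), function(i) {
      as.list(spec$archetypes[i, ])
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  archs <- dplyr::bind_rows(lapply(lst$archetypes, tibble::as_tibble))
  layout <- lapply(lst$tissue_layout, function(r) lapply(r, as.integer))
  mixtures <- lapply(lst$tissue_mixtures, unlist)
  phantom_spec(
    grid_shape = unlist(lst$grid_shape), n_timepoints = lst$n_timepoints,
    dt = lst$dt, tissue_layout = layout, tissue_mixtures = mixtures,
    archetypes = archs, seed = lst$seed
  )
}
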