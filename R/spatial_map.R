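# Mapping cluster assignments back onto anatomy.

#' Build a 3D cluster-map volume from voxel assignments
#'
#' Places each assigned voxel's cluster id, offset by +1, at its (x, y, z)
#' coordinate; 0 marks background and voxels removed by outlier filtering
#' (the NIfTI background convention).
#'
#' @param assigned Tibble with `x`, `y`, `z` and `cluster` columns.
#' @param reference_shape Integer vector of length 3 (volume shape).
#' @return 3D integer array with values in `0 .. k`.
#' @export
build_cluster_map <- function(assigned, reference_shape) {
  vol <- array(0L, reference_shape)
  if (!nrow(assigned)) {
    return(vol)
  }
  bad <- assigned$x < 1 | assigned$x > reference_shape[1] |
    assigned$y < 1 | assigned$y > reference_shape[2] |
    assigned$z < 1 | assigned$z > reference_shape[3]
  if (any(bad)) {
    offenders <- utils::head(which(bad), 5)
    rlang::abort(sprintf(
      "%d record(s) fall outside the reference shape (first rows: %s)",
      sum(bad), paste(offenders, collapse = ", ")
    ))
  }
  idx <- cbind(assigned$x, assigned$y, assigned$z)
  vol[idx] <- as.integer(assigned$cluster) + 1L
  vol
}

#' Write / read a cluster map as NIfTI-1
#'
#' Stored as unsigned 8-bit integers, so round-trips are bit-exact for
#' k <= 254.
#'
#' @param vol 3D integer array from [build_cluster_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional NIfTI image or path whose header (affine,
#'   orientation) is carried over.
#' @return `write_cluster_map` returns `path` invisibly; `read_cluster_map`
#'   the integer array.
#' @export
write_cluster_map <- function(vol, path, reference = NULL) {
  img <- if (!is.null(reference)) {
    RNifti::asNifti(vol, reference = RNifti::asNifti(reference),
                    datatype = "uint8")
  } else {
    RNifti::asNifti(vol, datatype = "uint8")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(img), dim(img))
  arr
}

#' Plot axial slices of a cluster map
#'
#' @param vol 3D cluster-map array.
#' @param slices Which z slices to show; default all.
#' @return A ggplot object (tile plot, one facet per slice).
#' @export
plot_cluster_map <- function(vol, slices = seq_len(dim(vol)[3])) {
  df <- purrr::map_dfr(slices, function(z) {
    sl <- vol[, , z]
    tibble::tibble(
      x = rep(seq_len(nrow(sl)), ncol(sl)),
      y = rep(seq_len(ncol(sl)), each = nrow(sl)),
      value = as.vector(sl), slice = z
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_viridis_d(name = "cluster + 1") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
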