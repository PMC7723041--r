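# k-means temporal-pattern clustering of latent representations.

# k-means++ seeding (Arthur & Vassilvitskii) on a data matrix.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = probs)
    centers[j, ] <- X[nxt, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# Squared Euclidean distances from every row of X to every center row.
dist2_to_centers <- function(X, centers) {
  # |x|^2 - 2 x.c + |c|^2, clipped at 0 for numeric safety
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  pmax(d2, 0)
}

# One Lloyd run from given centers; returns assignment, centers, inertia and
# the per-iteration inertia trace. Empty clusters are re-seeded at the point
# farthest from its current center.
lloyd_run <- function(X, centers, max_iter = 100, tol = 1e-10) {
  trace <- numeric(0)
  assign <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
    trace <- c(trace, inertia)
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
        new_centers[j, ] <- X[far, ]
      }
    }
    shift <- sum((new_centers - centers)^2)
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- dist2_to_centers(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(centers = centers, assign = assign, inertia = inertia,
       trace = c(trace, inertia))
}

#' Fit k-means temporal-pattern clusters in latent space
#'
#' Lloyd's algorithm with k-means++ initialization and `n_init` restarts
#' (best within-cluster sum of squares kept). When an autoencoder model is
#' supplied, centroids are decoded into 60-point prototype curves and
#' cluster ids are canonically relabeled by ascending prototype nadir depth
#' (fraction of early-curve baseline lost at the minimum), making ids stable
#' across runs; without a model, centroids are ordered by L2 norm.
#'
#' @param latents Tibble with `l1 ... lK` columns (from [encode_curves()])
#'   or a numeric matrix.
#' @param k Number of clusters, default 9.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts, default 10.
#' @param ae_model Optional trained autoencoder used to decode prototypes.
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `dsc_kmeans`: `centroids` (k x latent_dim),
#'   `prototype_curves` (k x 60, when decodable), `inertia`,
#'   `inertia_trace` of the winning run, `k`, `seed`.
#' @export
fit_kmeans <- function(latents, k = 9, seed = 1L, n_init = 10,
                       ae_model = NULL, max_iter = 100) {
  X <- if (is.matrix(latents)) latents else latent_matrix(latents)
  if (k < 2) rlang::abort("k must be >= 2")
  if (nrow(unique(as.data.frame(X))) < k) {
    rlang::abort(sprintf("need at least k = %d distinct latent vectors", k))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (i in seq_len(n_init)) {
    run <- lloyd_run(X, kmeanspp_init(X, k), max_iter = max_iter)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }

  prototypes <- NULL
  if (!is.null(ae_model)) {
    prototypes <- decode_latent(ae_model, best$centers)
    ord <- order(prototype_nadir_depth(prototypes))
  } else {
    ord <- order(sqrt(rowSums(best$centers^2)))
  }
  relabel <- match(seq_len(k), ord)
  model <- structure(
    list(k = k, centroids = best$centers[ord, , drop = FALSE],
         prototype_curves = if (!is.null(prototypes)) {
           prototypes[ord, , drop = FALSE]
         },
         inertia = best$inertia, inertia_trace = best$trace,
         seed = as.integer(seed)),
    class = "dsc_kmeans"
  )
  model
}

# Fractional nadir depth of each prototype curve: 1 - min / baseline, with
# baseline estimated from the first five samples.
prototype_nadir_depth <- function(protos) {
  apply(protos, 1, function(p) {
    b <- mean(p[seq_len(min(5, length(p)))])
    if (b <= 0) return(0)
    1 - min(p) / b
  })
}

#' Assign latent vectors to their nearest centroid
#'
#' Euclidean nearest-centroid assignment; ties broken toward the lowest
#' cluster id. Cluster ids are 0-based (`0 .. k-1`), matching the reporting
#' convention of the frequency tables.
#'
#' @param model A [fit_kmeans()] model.
#' @param latents Latent tibble or matrix.
#' @return When given a tibble: the tibble plus a `cluster` column. When
#'   given a matrix: an integer vector of cluster ids.
#' @export
assign_clusters <- function(model, latents) {
  X <- if (is.matrix(latents)) latents else latent_matrix(latents)
  if (ncol(X) != ncol(model$centroids)) {
    rlang::abort("latent dimensionality does not match the cluster model")
  }
  d2 <- dist2_to_centers(X, model$centroids)
  cl <- max.col(-d2, ties.method = "first") - 1L
  if (is.matrix(latents)) {
    return(cl)
  }
  dplyr::mutate(latents, cluster = cl)
}

#' Decode cluster centroids into prototype temporal patterns
#'
#' @param ae_model Trained autoencoder.
#' @param cluster_model A [fit_kmeans()] model.
#' @return The cluster model with `prototype_curves` filled (k x 60 matrix).
#' @export
decode_cluster_prototypes <- function(ae_model, cluster_model) {
  cluster_model$prototype_curves <- decode_latent(ae_model,
                                                  cluster_model$centroids)
  cluster_model
}

#' Tabulate cluster frequencies per tissue or lesion
#'
#' For each group (tissue type by default, or any grouping column), computes
#' the percentage of its voxels assigned to each cluster. Rows sum to 100.
#'
#' @param assigned Tibble with a `cluster` column (from [assign_clusters()])
#'   and the grouping column.
#' @param group Name of the grouping column, default `"tissue"`.
#' @param k Number of clusters (defines the column range), default
#'   `max(cluster) + 1`.
#' @return A tibble: one row per group, columns `cluster_0 ... cluster_<k-1>`
#'   holding percentages, plus `n_voxels`.
#' @export
cluster_frequency_table <- function(assigned, group = "tissue", k = NULL) {
  if (!group %in% names(assigned)) {
    rlang::abort(paste("grouping column", group, "not found"))
  }
  if (is.null(k)) k <- max(assigned$cluster) + 1L
  groups <- unique(assigned[[group]])
  rows <- lapply(groups, function(gv) {
    cl <- assigned$cluster[assigned[[group]] == gv]
    if (!length(cl)) {
      rlang::warn(paste("group", gv, "has no voxels; row omitted"))
      return(NULL)
    }
    counts <- tabulate(cl + 1L, nbins = k)
    pct <- 100 * counts / sum(counts)
    row <- tibble::as_tibble(as.list(stats::setNames(
      pct, paste0("cluster_", seq_len(k) - 1L)
    )))
    dplyr::bind_cols(tibble::tibble(!!group := gv), row,
                     tibble::tibble(n_voxels = sum(counts)))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.dsc_kmeans <- function(x, ...) {
  cat("k-means temporal-pattern model: k =", x$k,
      " inertia =", signif(x$inertia, 6), "\n")
  if (!is.null(x$prototype_curves)) {
    cat("prototype curves decoded (", nrow(x$prototype_curves), "x",
        ncol(x$prototype_curves), "), ids ordered by nadir depth\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dsc_kmeans <- function(x, ...) {
  out <- tibble::tibble(cluster = seq_len(x$k) - 1L)
  if (!is.null(x$prototype_curves)) {
    out$nadir_depth <- prototype_nadir_depth(x$prototype_curves)
  }
  out
}

#' @exportS3Method generics::glance
glance.dsc_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia,
                 iterations = length(x$inertia_trace))
}

#' Serialize / restore a cluster model as JSON
#'
#' @param model A `dsc_kmeans` model.
#' @param path File path.
#' @return `write_cluster_model` returns `path` invisibly;
#'   `read_cluster_model` the restored model.
#' @export
write_cluster_model <- function(model, path) {
  lst <- list(
    k = model$k,
    centroids = list(dim = dim(model$centroids),
                     data = as.vector(model$centroids)),
    prototype_curves = if (!is.null(model$prototype_curves)) {
      list(dim = dim(model$prototype_curves),
           data = as.vector(model$prototype_curves))
    },
    inertia = model$inertia, inertia_trace = model$inertia_trace,
    seed = model$seed
  )
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = lst$k,
         centroids = matrix(lst$centroids$data, lst$centroids$dim[1],
                            lst$centroids$dim[2]),
         prototype_curves = if (!is.null(lst$prototype_curves)) {
           matrix(lst$prototype_curves$data, lst$prototype_curves$dim[1],
                  lst$prototype_curves$dim[2])
         },
         inertia = lst$inertia, inertia_trace = lst$inertia_trace,
         seed = lst$seed),
    class = "dsc_kmeans"
  )
}
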