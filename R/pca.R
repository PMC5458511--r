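#' Eigenvolume principal component analysis of an aligned ensemble
#'
#' Decomposes the masked, mean-centred class volumes into orthonormal
#' eigenvolumes and per-class coefficients (the "linear factors" placing
#' each class in conformational space). Because the number of classes N is
#' far smaller than the voxel count, the decomposition is computed from the
#' N x N Gram matrix of the centred data: with X the N x V masked data
#' matrix, G = X X^T has eigenpairs (lambda_k, u_k), the k-th eigenvolume
#' is X^T u_k / sqrt(lambda_k) and the coefficients are sqrt(lambda_k) u_ik.
#' The PCA is unweighted: particle counts enter only the downstream energy
#' landscape. Each eigenvolume's sign is fixed so that its
#' largest-magnitude masked voxel is positive, making coefficients
#' reproducible across runs and platforms.
#'
#' @param ensemble an `aligned_ensemble` (see [align_ensemble()]) or a
#'   plain list of [voxel_grid()]s.
#' @param mask [binary_mask()] over which the analysis is performed.
#' @param K number of components to retain (`K <= N - 1`).
#' @param weighted if `TRUE`, classes are weighted by their particle counts
#'   (rows scaled by sqrt(count/mean count)) before the decomposition;
#'   default `FALSE`.
#' @return An object of class `eigen_decomposition` with fields
#'   `mean_volume`, `eigenvolumes` (list of K [voxel_grid()]s, zero outside
#'   the mask), `eigenvalues` (descending), `coefficients` (N x K matrix),
#'   `coefficients_tbl` (tibble with class_id, n_particles, c1..cK),
#'   `analysis_mask`, `total_variance`, `K`.
#' @export
fit_pca <- function(ensemble, mask, K, weighted = FALSE) {
  if (inherits(ensemble, "aligned_ensemble")) {
    vols <- ensemble$volumes
    counts <- ensemble$counts
  } else {
    vols <- ensemble
    counts <- rep(NA_integer_, length(vols))
  }
  N <- length(vols)
  if (N < 2) stop("need at least 2 class volumes for PCA", call. = FALSE)
  if (K > N - 1) stop("K must be at most N - 1 = ", N - 1, call. = FALSE)
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask",
                                           call. = FALSE)
  for (v in vols) check_same_grid(v, mask)
  msk <- mask$data
  X <- t(vapply(vols, function(v) v$data[msk], numeric(sum(msk))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (isTRUE(weighted)) {
    w <- counts / mean(counts)
    Xc <- Xc * sqrt(w)
  }
  total_var <- sum(Xc^2)
  if (total_var == 0)
    stop("degenerate ensemble: all volumes identical inside the mask",
         call. = FALSE)
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  pos <- lam > 1e-12 * total_var
  if (sum(pos) < K)
    stop("ensemble supports only ", sum(pos), " components (K = ", K, ")",
         call. = FALSE)
  lam <- lam[seq_len(K)]
  U <- eg$vectors[, seq_len(K), drop = FALSE]
  EV <- crossprod(Xc, sweep(U, 2, sqrt(lam), "/"))     # V x K, orthonormal
  coef <- sweep(U, 2, sqrt(lam), "*")                  # N x K
  # sign convention: largest-magnitude masked voxel of each eigenvolume > 0
  for (k in seq_len(K)) {
    s <- sign(EV[which.max(abs(EV[, k])), k])
    if (s < 0) { EV[, k] <- -EV[, k]; coef[, k] <- -coef[, k] }
  }
  grid_of <- function(values) {
    a <- array(0, dim = mask$shape)
    a[msk] <- values
    voxel_grid(a, mask$voxel_size, mask$origin)
  }
  eigenvolumes <- lapply(seq_len(K), function(k) grid_of(EV[, k]))
  ctbl <- tibble::as_tibble(stats::setNames(as.data.frame(coef),
                                            paste0("c", seq_len(K))))
  ctbl <- dplyr::bind_cols(tibble::tibble(class_id = seq_len(N),
                                          n_particles = counts), ctbl)
  structure(
    list(mean_volume = grid_of(mu), eigenvolumes = eigenvolumes,
         eigenvalues = lam, coefficients = coef, coefficients_tbl = ctbl,
         analysis_mask = mask, total_variance = total_var, K = K,
         weighted = isTRUE(weighted)),
    class = "eigen_decomposition"
  )
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf("<eigen_decomposition> N = %d classes, K = %d components\n",
              nrow(x$coefficients), x$K))
  fr <- explained_variance(x)
  cat("  explained variance:", paste(sprintf("%.1f%%", 100 * fr), collapse = " "),
      "\n")
  invisible(x)
}

#' Project a volume onto an eigenvolume basis
#'
#' Coefficients are the masked inner products of the mean-subtracted volume
#' with each eigenvolume; `project_volume(mean_volume)` is the zero vector
#' and projecting class i reproduces row i of the fitted coefficients.
#'
#' @param volume a [voxel_grid()] on the decomposition's grid.
#' @param decomposition an `eigen_decomposition`.
#' @return Numeric vector of K coefficients.
#' @export
project_volume <- function(volume, decomposition) {
  stopifnot(inherits(decomposition, "eigen_decomposition"))
  check_same_grid(volume, decomposition$analysis_mask)
  msk <- decomposition$analysis_mask$data
  d <- volume$data[msk] - decomposition$mean_volume$data[msk]
  vapply(decomposition$eigenvolumes,
         function(ev) sum(d * ev$data[msk]), numeric(1))
}

#' Fraction of ensemble variance captured per component
#'
#' @param decomposition an `eigen_decomposition`.
#' @return Numeric vector: eigenvalue_k / total centred variance,
#'   non-increasing, in \[0, 1\]; sums to 1 when K = N - 1.
#' @export
explained_variance <- function(decomposition) {
  stopifnot(inherits(decomposition, "eigen_decomposition"))
  decomposition$eigenvalues / decomposition$total_variance
}

#' Reconstruct a class volume from the decomposition
#'
#' @param decomposition an `eigen_decomposition`.
#' @param i class index.
#' @return mean + sum_k coefficients\[i,k\] eigenvolume_k as a [voxel_grid()];
#'   exact (masked RMS ~ machine precision) when K = N - 1.
#' @export
reconstruct_class <- function(decomposition, i) {
  out <- decomposition$mean_volume$data
  for (k in seq_len(decomposition$K))
    out <- out + decomposition$coefficients[i, k] *
      decomposition$eigenvolumes[[k]]$data
  voxel_grid(out, decomposition$mean_volume$voxel_size,
             decomposition$mean_volume$origin)
}

#' @export
tidy.eigen_decomposition <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = explained_variance(x))
}

#' @export
glance.eigen_decomposition <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$coefficients), K = x$K,
                 total_variance = x$total_variance,
                 weighted = x$weighted)
}

#' Write PCA results as TSV / MRC artifacts
#'
#' @param decomposition an `eigen_decomposition`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_pca <- function(decomposition, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (k in seq_len(decomposition$K)) {
    p <- file.path(dir, sprintf("eigenvolume_%02d.mrc", k))
    write_map(decomposition$eigenvolumes[[k]], p)
    paths <- c(paths, p)
  }
  write_map(decomposition$mean_volume, file.path(dir, "mean_volume.mrc"))
  readr::write_tsv(decomposition$coefficients_tbl,
                   file.path(dir, "coefficients.tsv"))
  readr::write_tsv(tidy(decomposition), file.path(dir, "eigenvalues.tsv"))
  invisible(c(paths, file.path(dir, c("mean_volume.mrc", "coefficients.tsv",
                                      "eigenvalues.tsv"))))
}
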