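#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard size measure of geometric morphometrics.
#' Centroid size is invariant to translation and rotation and scales linearly
#' with isotropic scaling.
#'
#' @param config a `k x 3` coordinate matrix.
#' @return a positive scalar.
#' @examples
#' centroid_size(rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0)))  # 2
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stopf("need at least 3 landmarks")
  centered <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs < .Machine$double.eps^0.5 * nrow(config)) {
    stopf("all landmarks coincident: zero centroid size")
  }
  cs
}

#' @rdname centroid_size
#' @details `center_config()` translates a configuration so its centroid is
#'   at the origin.
#' @export
center_config <- function(config) {
  sweep(config, 2, colMeans(config))
}

#' Optimal rotation of one centered configuration onto another
#'
#' Solves the orthogonal Procrustes problem with the reflection excluded:
#' the proper rotation `R` (3x3, determinant +1) minimizing
#' `||source %*% R - target||` in the Frobenius norm, via singular value
#' decomposition of the cross-covariance matrix. Reflections are disallowed
#' because left/right anatomy must not mirror.
#'
#' @param source,target centered `k x 3` matrices with equal `k`.
#' @return a 3x3 rotation matrix.
#' @export
optimal_rotation <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target))
  if (max(abs(colMeans(source))) > 1e-6 * sqrt(sum(source^2)) + 1e-12 ||
      max(abs(colMeans(target))) > 1e-6 * sqrt(sum(target^2)) + 1e-12) {
    stopf("optimal_rotation expects centered configurations")
  }
  M <- crossprod(source, target)
  sv <- svd(M)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) {
    stopf("ill-conditioned rotation: configuration rank < 2")
  }
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all configurations: each is centered, optionally
#' scaled to unit centroid size, and rotated to the running consensus; the
#' consensus is then updated to the mean of the aligned configurations. The
#' loop stops when the change in the total residual sum of squares falls to
#' `tol` or `max_iter` is reached. Centroid sizes are recorded before
#' scaling, in the original units. With `scale = TRUE` (the default) aligned
#' shapes have unit centroid size and inter-shape distances are partial
#' Procrustes distances.
#'
#' @param dataset a [landmark_dataset()] or a `k x 3 x n` array.
#' @param scale remove size by scaling each configuration to unit centroid
#'   size?
#' @param tol convergence threshold on the change in total residual sum of
#'   squares.
#' @param max_iter iteration cap; non-convergence warns and sets
#'   `converged = FALSE`.
#' @return an object of class `aligned_sample` with elements `coords`
#'   (`k x 3 x n` aligned array), `centroid_sizes`, `consensus`, `iterations`,
#'   `converged`, `scaled`, and the originating specimen table/metadata.
#' @export
gpa <- function(dataset, scale = TRUE, tol = 1e-10, max_iter = 200L) {
  if (inherits(dataset, "landmark_dataset")) {
    coords <- dataset$coords
    specimens <- dataset$specimens
    metadata <- dataset$metadata
  } else {
    coords <- dataset
    specimens <- data.frame(
      specimen_id = dimnames(coords)[[3]] %||%
        paste0("specimen_", seq_len(dim(coords)[3])),
      species = dimnames(coords)[[3]] %||%
        paste0("specimen_", seq_len(dim(coords)[3])),
      stringsAsFactors = FALSE
    )
    metadata <- NULL
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[3]; k <- dim(coords)[1]
  if (n < 2L) stopf("generalized Procrustes analysis needs at least 2 configurations")
  if (k < 3L) stopf("need at least 3 landmarks")

  cs <- numeric(n)
  aligned <- coords
  for (i in seq_len(n)) {
    m <- center_config(coords[, , i])
    cs[i] <- tryCatch(centroid_size(coords[, , i]), error = function(e)
      stopf("specimen '%s': %s", specimens$specimen_id[i], conditionMessage(e)))
    aligned[, , i] <- if (scale) m / cs[i] else m
  }

  consensus <- aligned[, , 1]
  rss_prev <- Inf
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      R <- tryCatch(optimal_rotation(aligned[, , i], consensus),
                    error = function(e)
                      stopf("specimen '%s': %s", specimens$specimen_id[i],
                            conditionMessage(e)))
      aligned[, , i] <- aligned[, , i] %*% R
    }
    consensus <- apply(aligned, c(1, 2), mean)
    consensus <- center_config(consensus)
    if (scale) consensus <- consensus / sqrt(sum(consensus^2))
    rss <- sum(sweep(aligned, c(1, 2), consensus)^2)
    if (abs(rss_prev - rss) <= tol) { converged <- TRUE; break }
    rss_prev <- rss
  }
  if (!converged) {
    warnf("generalized Procrustes analysis did not converge in %d iterations",
          max_iter)
  }
  consensus <- apply(aligned, c(1, 2), mean)
  structure(
    list(coords = aligned, centroid_sizes = cs, consensus = consensus,
         iterations = iterations, converged = converged, scaled = scale,
         specimens = specimens, metadata = metadata),
    class = "aligned_sample"
  )
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf(
    "Aligned sample: %d specimens x %d landmarks (%s, %d iterations%s)\n",
    dim(x$coords)[3], dim(x$coords)[1],
    if (x$scaled) "unit centroid size" else "unscaled",
    x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Partial Procrustes distance between two aligned shapes
#'
#' The Euclidean (root summed squared) distance between two centered,
#' unit-centroid-size configurations after optimally rotating the first onto
#' the second. Both preconditions are checked.
#'
#' @param a,b centered `k x 3` matrices of unit centroid size.
#' @param tol precondition tolerance.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b, tol = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  for (m in list(a, b)) {
    if (max(abs(colMeans(m))) > tol) {
      stopf("procrustes_distance expects centered configurations")
    }
    if (abs(sqrt(sum(m^2)) - 1) > tol) {
      stopf("procrustes_distance expects unit-centroid-size configurations")
    }
  }
  R <- optimal_rotation(a, b)
  sqrt(sum((a %*% R - b)^2))
}

# Internal fast path: distance of each member configuration from the members'
# mean shape (mean rescaled to unit centroid size when the sample is scaled),
# re-rotating each member onto the mean. Returns the vector of distances.
residual_distances <- function(coords, scaled = TRUE) {
  meanshape <- apply(coords, c(1, 2), mean)
  meanshape <- center_config(meanshape)
  if (scaled) meanshape <- meanshape / sqrt(sum(meanshape^2))
  n <- dim(coords)[3]
  d <- numeric(n)
  for (i in seq_len(n)) {
    R <- optimal_rotation(coords[, , i], meanshape)
    d[i] <- sqrt(sum((coords[, , i] %*% R - meanshape)^2))
  }
  d
}
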