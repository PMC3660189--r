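#' Principal components of aligned shape coordinates
#'
#' Decomposes the (column-centered) matrix of flattened aligned coordinates
#' (one specimen per row, `3k` columns). Superimposition removes 7 degrees of
#' freedom (3 translation, 3 rotation, 1 size), so at most
#' `min(n - 1, 3k - 7)` components carry shape variation; only that many are
#' retained. Loading signs follow a fixed convention (the largest-magnitude
#' entry of each loading is positive) so scores are reproducible across runs.
#'
#' @param aligned an `aligned_sample` from [gpa()], or a specimens-by-variables
#'   numeric matrix (rows = specimens), in which case the 7-degree-of-freedom
#'   cap is not applied.
#' @return an object of class `shape_space` with elements `scores`
#'   (`n x m`), `eigenvalues` (descending), `loadings` (`m x 3k`),
#'   `percent_variance`, `center`, `stage` (`"raw"`), and the specimen table
#'   when available.
#' @export
shape_pca <- function(aligned) {
  if (inherits(aligned, "aligned_sample")) {
    X <- flatten_coords(aligned$coords)
    dof_cap <- ncol(X) - 7L
    specimens <- aligned$specimens
    log_cs <- log(aligned$centroid_sizes)
  } else {
    X <- as.matrix(aligned)
    dof_cap <- ncol(X)
    specimens <- NULL
    log_cs <- NULL
  }
  n <- nrow(X)
  if (n < 3L) stopf("principal component analysis needs at least 3 specimens")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  eig_all <- sv$d^2 / (n - 1)
  total <- sum(eig_all)
  m <- max(1L, min(n - 1L, dof_cap))
  m <- min(m, length(eig_all))
  scores <- sv$u[, seq_len(m), drop = FALSE] %*%
    diag(sv$d[seq_len(m)], m, m)
  loadings <- t(sv$v[, seq_len(m), drop = FALSE])
  # deterministic sign convention
  for (j in seq_len(m)) {
    i_max <- which.max(abs(loadings[j, ]))
    if (loadings[j, i_max] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(m))
  rownames(loadings) <- paste0("PC", seq_len(m))
  structure(
    list(scores = scores, eigenvalues = eig_all[seq_len(m)],
         loadings = loadings,
         percent_variance = 100 * eig_all[seq_len(m)] / total,
         total_variance = total, center = center, stage = "raw",
         specimens = specimens, log_cs = log_cs),
    class = "shape_space"
  )
}

flatten_coords <- function(coords) {
  n <- dim(coords)[3]; k <- dim(coords)[1]
  X <- t(apply(coords, 3, function(m) as.vector(t(m))))
  dim(X) <- c(n, 3L * k)
  rownames(X) <- dimnames(coords)[[3]]
  colnames(X) <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                   function(i, a) paste0("lm", i, ".", a))))
  X
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("Shape space (%s): %d specimens, %d components\n", x$stage,
              nrow(x$scores), ncol(x$scores)))
  pv <- utils::head(x$percent_variance, 4)
  cat(sprintf("  %s: %s%% of variance\n",
              paste(colnames(x$scores)[seq_along(pv)], collapse = "-"),
              paste(sprintf("%.1f", pv), collapse = ", ")))
  invisible(x)
}

#' Remove allometric size variation from a shape space
#'
#' Cranial shape often covaries with size (allometry); when two clades differ
#' in size range, raw shape variance conflates shape disparity with size
#' disparity. This correction regresses every retained principal component
#' score column on log centroid size (ordinary least squares with intercept)
#' and re-decomposes the residual score matrix with a second principal
#' component analysis. The corrected scores are, by construction, linearly
#' uncorrelated with log centroid size.
#'
#' @param space a `shape_space` of stage `"raw"` from [shape_pca()].
#' @param log_cs per-specimen log centroid size, in the same specimen order;
#'   defaults to the sizes recorded by [gpa()].
#' @return a `shape_space` of stage `"size_corrected"`.
#' @export
remove_allometry <- function(space, log_cs = NULL) {
  stopifnot(inherits(space, "shape_space"))
  if (!identical(space$stage, "raw")) {
    stopf("remove_allometry expects a raw-stage shape space")
  }
  log_cs <- log_cs %||% space$log_cs
  if (is.null(log_cs)) stopf("log centroid sizes are required")
  if (length(log_cs) != nrow(space$scores)) {
    stopf("log_cs length (%d) does not match specimen count (%d)",
          length(log_cs), nrow(space$scores))
  }
  if (!all(is.finite(log_cs))) stopf("log_cs must be finite")
  if (stats::var(log_cs) < .Machine$double.eps) {
    warnf("log centroid size has zero variance; allometric correction is a no-op")
    out <- space
    out$stage <- "size_corrected"
    out$log_cs <- log_cs
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, log_cs), space$scores)
  resid <- fit$residuals
  out <- shape_pca(resid)
  # the regression removes one degree of freedom; trailing components with
  # numerically zero eigenvalues are round-off noise and are dropped
  keep <- max(1L, sum(out$eigenvalues > max(out$eigenvalues) * 1e-10))
  out$scores <- out$scores[, seq_len(keep), drop = FALSE]
  out$loadings <- out$loadings[seq_len(keep), , drop = FALSE]
  out$eigenvalues <- out$eigenvalues[seq_len(keep)]
  out$percent_variance <- out$percent_variance[seq_len(keep)]
  out$stage <- "size_corrected"
  out$specimens <- space$specimens
  out$log_cs <- log_cs
  rownames(out$scores) <- rownames(space$scores)
  out
}

#' Convex-hull area of a group in morphospace
#'
#' Area of the 2D convex hull of a set of specimens' scores on a chosen pair
#' of component axes — a simple summary of how much morphospace a group
#' occupies. Fewer than 3 members, or collinear members, give area 0 with a
#' warning.
#'
#' @param space a `shape_space`.
#' @param members specimen indices (or names matching score rownames);
#'   defaults to all.
#' @param axes pair of component indices, default `c(1, 2)`.
#' @return non-negative scalar area in squared score units.
#' @export
morphospace_hull_area <- function(space, members = NULL, axes = c(1, 2)) {
  stopifnot(length(axes) == 2L)
  pts <- space$scores[, axes, drop = FALSE]
  if (!is.null(members)) pts <- pts[members, , drop = FALSE]
  if (nrow(pts) < 3L) {
    warnf("fewer than 3 members: hull area is 0")
    return(0)
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3L) {
    warnf("collinear members: hull area is 0")
    return(0)
  }
  polygon_area(pts[hull, 1], pts[hull, 2])
}

# shoelace formula on an ordered polygon
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
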