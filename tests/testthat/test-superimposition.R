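test_that("centroid size is the root summed squared deviation and behaves under similarity", {
  cross <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(centroid_size(cross), 2)
  set.seed(10)
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(centroid_size(m * 3.7), 3.7 * centroid_size(m))
  expect_equal(centroid_size(sweep(m, 2, c(5, -2, 100), "+")),
               centroid_size(m))
  expect_error(centroid_size(matrix(1, 4, 3)), "coincident")
})

test_that("optimal_rotation recovers known rotations and refuses reflections", {
  set.seed(11)
  src <- center_config(matrix(rnorm(15), 5, 3))
  Rknown <- rot_z(0.8) %*% rot_y(1.1)
  Rhat <- optimal_rotation(src, src %*% Rknown)
  expect_equal(Rhat, Rknown, tolerance = 1e-10)
  expect_equal(det(Rhat), 1, tolerance = 1e-10)
  expect_lt(sum((src %*% Rhat - src %*% Rknown)^2), 1e-18)

  # mirror image of a chiral configuration: proper rotation, nonzero residual
  mirror <- src %*% diag(c(1, 1, -1))
  Rm <- optimal_rotation(src, mirror)
  expect_equal(det(Rm), 1, tolerance = 1e-10)
  expect_gt(sum((src %*% Rm - mirror)^2), 1e-4)

  expect_error(optimal_rotation(src + 1, src), "centered")
  degenerate <- cbind(seq_len(5), 0, 0)
  degenerate <- sweep(degenerate, 2, colMeans(degenerate))
  expect_error(optimal_rotation(degenerate, degenerate), "rank")
})

test_that("optimal_rotation and procrustes_distance match the Euler-grid oracle", {
  set.seed(12)
  for (case in 1:3) {
    a <- center_config(matrix(rnorm(15), 5, 3))
    b <- center_config(matrix(rnorm(15), 5, 3))
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    oracle <- grid_rotation_oracle(a, b)
    d_svd <- procrustes_distance(a, b)
    # optimality: the closed form can only be better than the grid
    expect_lte(d_svd, sqrt(oracle$rss) + 1e-12)
    # and the 1-degree grid gets within grid tolerance of it
    expect_lt(sqrt(oracle$rss) - d_svd, 5e-3)
  }
})

test_that("gpa aligns exact copies under random similarity transforms", {
  set.seed(13)
  base <- make_mean_shape(7, seed = 3)
  n <- 6
  coords <- array(NA_real_, c(7, 3, n))
  for (i in 1:n) {
    R <- rot_z(runif(1, 0, 2 * pi)) %*% rot_y(runif(1, 0, pi))
    coords[, , i] <- sweep(base %*% R * runif(1, 0.5, 4), 2,
                           runif(3, -5, 5), "+")
  }
  al <- gpa(coords)
  expect_true(al$converged)
  spread <- sweep(al$coords, c(1, 2), al$consensus)
  expect_lt(sum(spread^2), 1e-12)
  # centroids at origin, unit centroid size
  expect_lt(max(abs(apply(al$coords, 3, colMeans))), 1e-10)
  expect_equal(apply(al$coords, 3, function(m) sqrt(sum(m^2))),
               rep(1, n), tolerance = 1e-8)
  # centroid sizes recorded pre-scaling, in original units
  expect_equal(al$centroid_sizes,
               apply(coords, 3, centroid_size), tolerance = 1e-10)
})

test_that("gpa is equivariant under rigid motion + rescaling of any input and idempotent", {
  ds <- simulate_study(two_clade_spec(n = 8, seed = 21))
  al1 <- gpa(ds)
  # perturb one input by an arbitrary similarity transform
  coords2 <- ds$coords
  R <- rot_y(2.2) %*% rot_z(0.4)
  coords2[, , 3] <- sweep(coords2[, , 3] %*% R * 3.1, 2, c(8, -3, 2), "+")
  al2 <- gpa(coords2)
  expect_equal(al2$coords, al1$coords, tolerance = 1e-4,
               ignore_attr = TRUE)
  # idempotence: re-running on aligned output changes nothing
  al3 <- gpa(al1$coords)
  expect_equal(al3$coords, al1$coords, tolerance = 1e-4)
  expect_equal(al3$consensus, al1$consensus, tolerance = 1e-4)
})

test_that("two-configuration gpa agrees with an ordinary pairwise fit", {
  set.seed(14)
  a <- center_config(matrix(rnorm(18), 6, 3))
  b <- center_config(matrix(rnorm(18), 6, 3))
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  al <- gpa(array(c(a, b), c(6, 3, 2)))
  # inter-specimen distance after GPA equals the direct pairwise partial
  # Procrustes distance (consensus convention cannot change it)
  d_gpa <- sqrt(sum((al$coords[, , 1] - al$coords[, , 2])^2))
  expect_equal(d_gpa, procrustes_distance(a, b), tolerance = 1e-6)
})

test_that("procrustes_distance is a premetric consistent with its contract", {
  set.seed(15)
  mk <- function() {
    m <- center_config(matrix(rnorm(24), 8, 3))
    m / sqrt(sum(m^2))
  }
  a <- mk(); b <- mk(); c <- mk()
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-8)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-10)
  # approximate triangle inequality near the consensus
  expect_lte(procrustes_distance(a, c),
             procrustes_distance(a, b) + procrustes_distance(b, c) + 1e-8)
  expect_error(procrustes_distance(a * 2, b), "unit")
  expect_error(procrustes_distance(a + 0.5, b), "centered")
})

test_that("consensus is closer to the sample than any single configuration", {
  ds <- simulate_study(two_clade_spec(n = 10, seed = 31))
  al <- gpa(ds)
  ss_to_consensus <- sum(sweep(al$coords, c(1, 2), al$consensus)^2)
  for (j in c(1, 5, 11)) {
    ss_to_j <- sum(sweep(al$coords, c(1, 2), al$coords[, , j])^2)
    expect_lte(ss_to_consensus, ss_to_j + 1e-10)
  }
})
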