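# Fixtures and independent oracles, built in code at test time.

# A 4-landmark, 2-specimen dataset with hand-set coordinates.
tiny_dataset <- function() {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 0.9, 0), c(0.1, 0, 1))
  landmark_dataset(list(a, b), c("spA", "spB"), c("Alpha_sp", "Beta_sp"))
}

tiny_metadata <- function() {
  data.frame(
    species = c("Alpha_sp", "Beta_sp"),
    clade = c("marsupial", "placental"),
    sex = c("female", "male"),
    diet = c("omnivore", "folivore"),
    habitat = c("terrestrial", "arboreal"),
    activity = c("nocturnal_crepuscular", "none"),
    stringsAsFactors = FALSE
  )
}

# 16-landmark scheme with all four region tags, for reduced-landmark batteries.
scheme16 <- function() {
  landmark_scheme(
    "k16", 1:16,
    c(rep("oral", 5), rep("viscerocranium_both", 4),
      rep("viscerocranium_non_oral", 4), rep("neurocranium", 3))
  )
}

# Two-clade synthetic study in the whole-skull detection regime.
two_clade_spec <- function(n = 60, v_a = 0.018, v_b = 0.052, seed = 1,
                           scheme = scheme16(), slope_a = 0, slope_b = 0) {
  synthetic_spec(
    groups = list(
      list(label = "mars", clade = "marsupial", n = n,
           planted_variance = v_a, allometric_slope = slope_a,
           ecology = list(diet = "omnivore", habitat = "terrestrial",
                          activity = "nocturnal_crepuscular")),
      list(label = "plac", clade = "placental", n = n,
           planted_variance = v_b, allometric_slope = slope_b,
           ecology = list(diet = "omnivore", habitat = "terrestrial",
                          activity = "nocturnal_crepuscular"))
    ),
    scheme = scheme, seed = seed
  )
}

clade_members <- function(ds, clade) {
  md <- ds$metadata
  cl <- md$clade[match(ds$specimens$species, md$species)]
  which(cl == clade)
}

# --- independent oracles ---------------------------------------------------

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))

# Coarse-to-fine Euler-angle (z-y-z) grid search for the rotation minimizing
# ||source %*% R - target||, ending at 1 degree resolution. Independent of
# the SVD solution.
grid_rotation_oracle <- function(source, target) {
  resid <- function(R) sum((source %*% R - target)^2)
  best <- list(rss = Inf, ang = c(0, 0, 0))
  scan <- function(centers, half_range, step) {
    for (a in seq(centers[1] - half_range, centers[1] + half_range, by = step))
      for (b in seq(max(centers[2] - half_range, 0),
                    min(centers[2] + half_range, pi), by = step))
        for (c in seq(centers[3] - half_range, centers[3] + half_range,
                      by = step)) {
          r <- resid(rot_z(a) %*% rot_y(b) %*% rot_z(c))
          if (r < best$rss) best <<- list(rss = r, ang = c(a, b, c))
        }
  }
  deg <- pi / 180
  scan(c(pi, pi / 2, pi), pi, 15 * deg)
  scan(best$ang, 15 * deg, 3 * deg)
  scan(best$ang, 3 * deg, 1 * deg)
  list(rss = best$rss,
       R = rot_z(best$ang[1]) %*% rot_y(best$ang[2]) %*% rot_z(best$ang[3]))
}

# Brute-force convex hull area: a point is interior iff it lies inside some
# triangle of three other points; remaining points are hull vertices, ordered
# by angle about their centroid, area by the shoelace formula.
brute_hull_area <- function(x, y) {
  n <- length(x)
  in_triangle <- function(px, py, i, j, k) {
    s <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- s(x[i], y[i], x[j], y[j], px, py)
    d2 <- s(x[j], y[j], x[k], y[k], px, py)
    d3 <- s(x[k], y[k], x[i], y[i], px, py)
    (d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0)
  }
  interior <- logical(n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    for (tri in utils::combn(others, 3, simplify = FALSE)) {
      if (in_triangle(x[p], y[p], tri[1], tri[2], tri[3])) {
        interior[p] <- TRUE
        break
      }
    }
  }
  hx <- x[!interior]; hy <- y[!interior]
  ord <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[ord]; hy <- hy[ord]
  j <- c(length(hx), seq_len(length(hx) - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# Exhaustive-enumeration two-sided permutation p for two groups of residual
# distances (pools the squared distances, enumerates all assignments).
enum_perm_p <- function(d_a, d_b) {
  na <- length(d_a); nb <- length(d_b)
  d2 <- c(d_a, d_b)^2
  obs <- sum(d2[(na + 1):(na + nb)]) / (nb - 1) - sum(d2[1:na]) / (na - 1)
  assignments <- utils::combn(na + nb, na, simplify = FALSE)
  deltas <- vapply(assignments, function(ia) {
    ib <- setdiff(seq_len(na + nb), ia)
    sum(d2[ib]) / (nb - 1) - sum(d2[ia]) / (na - 1)
  }, numeric(1))
  mean(abs(deltas) >= abs(obs) - 1e-12)
}
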