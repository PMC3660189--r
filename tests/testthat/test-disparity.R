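test_that("group_variance matches hand algebra and a direct-summation oracle", {
  # identical shapes: zero variance
  base <- make_mean_shape(6, seed = 61)
  al_same <- gpa(array(rep(base, 4), c(6, 3, 4)))
  expect_lt(group_variance(al_same), 1e-20)

  # two shapes at distance d have variance d^2 / 2 with the n-1 denominator
  ds2 <- simulate_study(two_clade_spec(n = 2, seed = 62))
  al2 <- gpa(keep2 <- ds2)
  d <- procrustes_distance(al2$coords[, , 1], al2$coords[, , 2])
  # small curvature effects from rescaling the two-shape mean to unit size
  expect_equal(group_variance(al2, 1:2), d^2 / 2, tolerance = 0.01)

  # 10 random shapes vs brute-force: rotate each member onto the unit-size
  # mean shape independently and sum squared distances
  ds <- simulate_study(two_clade_spec(n = 5, seed = 63))
  al <- gpa(ds)
  idx <- 1:10
  mshape <- apply(al$coords[, , idx], c(1, 2), mean)
  mshape <- center_config(mshape); mshape <- mshape / sqrt(sum(mshape^2))
  brute <- sum(vapply(idx, function(i) {
    g <- grid_rotation_oracle(al$coords[, , i], mshape)
    g$rss
  }, numeric(1))) / (length(idx) - 1)
  expect_equal(group_variance(al, idx), brute, tolerance = 0.02)
  expect_error(group_variance(al, 1L), "at least 2")
})

test_that("delta_variance reproduces printed worked examples", {
  expect_equal(delta_variance(0.0258, 0.0681), 0.0423, tolerance = 1e-12)
  expect_equal(delta_variance(0.0314, 0.0310), -0.0004, tolerance = 1e-12)
  expect_equal(delta_variance(0.5, 0.5), 0)
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_equal(bonferroni_threshold(0.01, 36), 0.01 / 36)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_error(bonferroni_threshold(1.2, 5))
})

test_that("bootstrap_equalize resamples every stratum to the target size deterministically", {
  set.seed(64)
  groups <- list(m = 1:95, p = 96:145)
  sex <- c(rep(c("male", "female"), c(50, 45)),
           rep(c("male", "female"), c(30, 20)))
  plan <- resampling_plan(n_bootstrap = 50, n_permutations = 99, seed = 9)
  reps <- bootstrap_equalize(groups, strata = sex, plan = plan)
  expect_length(reps, 50L)
  for (r in reps[c(1, 25, 50)]) {
    expect_length(r$m, 40L)  # 2 strata x n_target = 20
    expect_length(r$p, 40L)
    expect_true(all(r$m %in% groups$m))
    expect_true(all(r$p %in% groups$p))
    # each stratum at exactly n_target
    expect_equal(sum(sex[r$m] == "male"), 20L)
    expect_equal(sum(sex[r$p] == "female"), 20L)
  }
  reps2 <- bootstrap_equalize(groups, strata = sex, plan = plan)
  expect_identical(reps, reps2)
  expect_error(
    bootstrap_equalize(groups, strata = sex,
                       plan = resampling_plan(seed = 1, n_target = 25)),
    "smallest stratum")
  expect_error(bootstrap_equalize(list(m = integer(0), p = 1:5),
                                  plan = plan), "empty stratum")
})

test_that("bootstrap group variance is consistent with the full-sample variance", {
  ds <- simulate_study(two_clade_spec(n = 40, seed = 65))
  al <- gpa(ds)
  mars <- clade_members(ds, "marsupial")
  full <- group_variance(al, mars)
  plan <- resampling_plan(n_bootstrap = 300, n_permutations = 99, seed = 3,
                          n_target = 40)
  reps <- bootstrap_equalize(list(m = mars, p = clade_members(ds, "placental")),
                             strata = NULL, plan = plan)
  boot_mean <- mean(vapply(reps, function(r) group_variance(al, r$m),
                           numeric(1)))
  # with replacement at n_target = n the bootstrap mean approaches the
  # full-sample variance (small downward bias of order 1/n)
  expect_equal(boot_mean, full, tolerance = 0.08)
})

test_that("permutation test is exchangeable, antisymmetric and deterministic", {
  ds <- simulate_study(two_clade_spec(n = 20, v_a = 0.03, v_b = 0.03,
                                      seed = 66))
  al <- gpa(ds)
  a <- clade_members(ds, "marsupial"); b <- clade_members(ds, "placental")
  plan <- resampling_plan(n_bootstrap = 0, n_permutations = 199, seed = 17)
  res <- permutation_test(al, a, b, plan)
  res_swap <- permutation_test(al, b, a, plan)
  expect_equal(res_swap$delta, -res$delta)
  expect_equal(res_swap$p_value, res$p_value)
  expect_identical(permutation_test(al, a, b, plan)$p_value, res$p_value)
  expect_gte(res$p_value, 1 / 200)
  expect_error(permutation_test(al, a, c(a[1], b)), "overlap")
})

test_that("monte-carlo p matches exhaustive enumeration at 3+3", {
  ds <- simulate_study(two_clade_spec(n = 3, seed = 67))
  al <- gpa(ds)
  a <- clade_members(ds, "marsupial"); b <- clade_members(ds, "placental")
  d_a <- group_residuals(al, a); d_b <- group_residuals(al, b)
  p_exact <- enum_perm_p(d_a, d_b)
  B <- 4000
  res <- permutation_test(al, a, b,
                          resampling_plan(n_bootstrap = 0,
                                          n_permutations = B, seed = 5))
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(res$p_value - p_exact), 4 * se + 2 / B)
})

test_that("power is monotone in the true variance ratio", {
  n_sim <- 40; B <- 99
  mean_shape <- make_mean_shape(10, seed = 72)
  power_at <- function(ratio) {
    rej <- 0L
    for (r in seq_len(n_sim)) {
      # paired seeds across ratios: same draws, scaled variance
      g1 <- simulate_group(mean_shape, 0.02, 20, seed = 500 + r)
      g2 <- simulate_group(mean_shape, 0.02 * ratio, 20, seed = 900 + r)
      al <- gpa(array(c(g1$coords, g2$coords), c(10, 3, 40)))
      res <- permutation_test(al, 1:20, 21:40,
                              resampling_plan(n_bootstrap = 0,
                                              n_permutations = B, seed = r))
      rej <- rej + (res$p_value < 0.05)
    }
    rej / n_sim
  }
  pw <- vapply(c(1, 2, 4, 8), power_at, numeric(1))
  # non-decreasing up to Monte-Carlo slack, and clearly powered at ratio 8
  expect_true(all(diff(pw) >= -0.1))
  expect_gt(pw[4], pw[1])
  expect_gte(pw[4], 0.9)
})

test_that("the battery produces one row per grouping x region with shared Bonferroni m", {
  spec <- two_clade_spec(n = 12, seed = 73, scheme = scheme16())
  ds <- simulate_study(spec)
  plan <- resampling_plan(n_bootstrap = 0, n_permutations = 99, seed = 2)
  res <- run_disparity_battery(
    ds, regions = c("whole_skull", "neurocranium", "viscerocranium",
                    "viscerocranium_non_oral", "oral"),
    groupings = clade_groupings(), plan = plan)
  expect_equal(nrow(res), 5L)
  expect_equal(attr(res, "m"), 5L)
  expect_equal(unique(res$alpha_adjusted), 0.01 / 5)
  expect_setequal(res$region, c("whole_skull", "neurocranium",
                                "viscerocranium", "viscerocranium_non_oral",
                                "oral"))
  expect_true(all(res$delta == res$variance_b - res$variance_a))
})

test_that("undersized cells are skipped with a reason, not an error", {
  ds <- simulate_study(two_clade_spec(n = 6, seed = 74))
  # a diet split with no placental members
  ds$metadata$diet[ds$metadata$clade == "marsupial"][1:3] <- "folivore"
  ds$metadata$diet[ds$metadata$diet != "folivore"] <- "omnivore"
  plan <- resampling_plan(n_bootstrap = 0, n_permutations = 99, seed = 4)
  groupings <- clade_groupings(eco_splits = TRUE)
  keep <- vapply(groupings, function(g)
    (g$label %in% c("all", "folivores", "omnivores")), logical(1))
  res <- suppressWarnings(run_disparity_battery(
    ds, regions = "whole_skull", groupings = groupings[keep], plan = plan))
  expect_equal(nrow(res), 2L)  # folivore split lacks placentals
  expect_match(attr(res, "skipped"), "folivores", all = FALSE)
})

test_that("marsupials versus marsupials-plus-fossils runs as a single overlapping-group row", {
  spec <- synthetic_spec(groups = list(
    list(label = "mars", clade = "marsupial", n = 20,
         planted_variance = 0.018),
    list(label = "foss", clade = "fossil_metatherian", n = 6,
         planted_variance = 0.018)
  ), scheme = scheme16(), seed = 75)
  ds <- simulate_study(spec)
  plan <- resampling_plan(n_bootstrap = 0, n_permutations = 199, seed = 6)
  res <- run_disparity_battery(ds, regions = "whole_skull",
                               groupings = metatherian_grouping(),
                               plan = plan)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_a, 20L)
  expect_equal(res$n_b, 26L)
  # same planted variance in fossils: no significant increase expected
  expect_gt(res$p_value, 0.01)
})
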