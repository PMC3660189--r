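#' Procrustes variance of a group of aligned shapes
#'
#' The variance-based disparity measure: the summed squared partial
#' Procrustes distances of the group members from the members' mean shape,
#' divided by `n - 1`. Variance-based disparity is more robust to sample size
#' than range-based measures, which is why it is used for clade comparisons.
#'
#' @param aligned an `aligned_sample` from [gpa()] (scaled), or a
#'   specimens-by-variables score matrix, in which case plain Euclidean
#'   distances from the column mean are used.
#' @param members specimen indices or names; defaults to all.
#' @return non-negative scalar, in squared partial-Procrustes-distance units.
#' @export
group_variance <- function(aligned, members = NULL) {
  d <- group_residuals(aligned, members)
  sum(d^2) / (length(d) - 1)
}

#' @rdname group_variance
#' @details `group_residuals()` returns the individual member distances from
#'   the group mean shape, the quantities permuted by the delta-variance
#'   null.
#' @export
group_residuals <- function(aligned, members = NULL) {
  if (inherits(aligned, "aligned_sample")) {
    idx <- resolve_members(aligned, members)
    if (length(idx) < 2L) stopf("group variance needs at least 2 members")
    residual_distances(aligned$coords[, , idx, drop = FALSE],
                       scaled = aligned$scaled)
  } else {
    X <- as.matrix(aligned)
    if (!is.null(members)) X <- X[members, , drop = FALSE]
    if (nrow(X) < 2L) stopf("group variance needs at least 2 members")
    ctr <- colMeans(X)
    sqrt(rowSums(sweep(X, 2, ctr)^2))
  }
}

resolve_members <- function(aligned, members) {
  if (is.null(members)) return(seq_len(dim(aligned$coords)[3]))
  if (is.character(members)) {
    idx <- match(members, aligned$specimens$specimen_id)
    if (anyNA(idx)) {
      stopf("unknown specimen id(s): %s",
            paste(members[is.na(idx)], collapse = ", "))
    }
    return(idx)
  }
  as.integer(members)
}

#' Difference in Procrustes variance between two groups
#'
#' The delta-variance statistic: `variance_b - variance_a`. In a
#' marsupial-versus-placental comparison with marsupials as group A, a
#' positive delta means placentals are the more disparate clade.
#'
#' @param variance_a,variance_b non-negative group variances.
#' @return `variance_b - variance_a`.
#' @examples
#' delta_variance(0.0258, 0.0681)  # 0.0423
#' @export
delta_variance <- function(variance_a, variance_b) {
  stopifnot(variance_a >= 0, variance_b >= 0)
  variance_b - variance_a
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal significance level, in (0, 1).
#' @param m number of tests performed on the same data.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.01, 5)   # 0.002
#' bonferroni_threshold(0.01, 36)  # ~2.78e-4
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Resampling settings for disparity comparisons
#'
#' Bundles the bootstrap-equalization and permutation settings. Defaults are
#' 1,000 bootstrap iterations and 1,000 permutations with significance
#' assessed at `alpha = 0.01`; strata are (clade, sex) cells so that both
#' sexes of both clades are resampled to a common size before disparity is
#' quantified.
#'
#' @param n_bootstrap bootstrap replicates used to equalize sample sizes
#'   (0 disables equalization and uses the raw groups).
#' @param n_permutations permutations for the delta-variance null.
#' @param seed integer RNG seed; all resampling is a pure function of it.
#' @param n_target common per-stratum size; default (`NULL`) is the smallest
#'   stratum.
#' @param strata_fields metadata fields defining strata within each group.
#' @param tail `"two_sided"` (on `|delta|`) or `"greater"` (`delta_b > delta_a`).
#' @param alpha nominal significance level before multiple-test adjustment.
#' @return an object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_bootstrap = 1000L, n_permutations = 1000L,
                            seed = 1L, n_target = NULL,
                            strata_fields = c("clade", "sex"),
                            tail = c("two_sided", "greater"),
                            alpha = 0.01) {
  tail <- match.arg(tail)
  stopifnot(n_bootstrap >= 0, n_permutations >= 1, alpha > 0, alpha < 1)
  if (n_permutations < 99) {
    warnf("n_permutations = %d gives coarse p-value resolution (>= 1/%d)",
          n_permutations, n_permutations + 1)
  }
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), n_target = n_target,
         strata_fields = strata_fields, tail = tail, alpha = alpha),
    class = "resampling_plan"
  )
}

#' Stratified bootstrap equalization of group sample sizes
#'
#' Corrects for unequal sampling between the groups by resampling every
#' stratum (for example each clade-by-sex cell) with replacement to a common
#' size before disparity is quantified. Each replicate pools the equalized
#' strata back into their groups. The replicate sequence is a pure function
#' of the plan's seed.
#'
#' @param groups named list of two (or more) integer membership vectors.
#' @param strata vector assigning a stratum label to every specimen indexable
#'   by the membership vectors (e.g. sex); `NULL` treats each group as one
#'   stratum.
#' @param plan a [resampling_plan()].
#' @return list of `n_bootstrap` replicates; each replicate is a named list
#'   of resampled membership vectors per group.
#' @export
bootstrap_equalize <- function(groups, strata = NULL, plan = resampling_plan()) {
  stopifnot(is.list(groups), length(groups) >= 2)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stopf("empty stratum (%s)", g)
  }
  cells <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    st <- if (is.null(strata)) rep("all", length(idx)) else
      as.character(strata[idx])
    for (s in unique(st)) {
      cell <- idx[st == s]
      if (!length(cell)) stopf("empty stratum (%s, %s)", g, s)
      cells[[paste(g, s, sep = "|")]] <- list(group = g, members = cell)
    }
  }
  sizes <- vapply(cells, function(c) length(c$members), integer(1))
  n_target <- plan$n_target %||% min(sizes)
  if (n_target < 2L) stopf("equalized stratum size %d is too small", n_target)
  if (n_target > min(sizes)) {
    stopf("n_target (%d) exceeds the smallest stratum (%d: %s)",
          n_target, min(sizes), names(cells)[which.min(sizes)])
  }
  local_seed(plan$seed, {
    lapply(seq_len(max(1L, plan$n_bootstrap)), function(b) {
      rep_groups <- stats::setNames(
        vector("list", length(groups)), names(groups))
      for (cell in cells) {
        draw <- cell$members[sample.int(length(cell$members), n_target,
                                        replace = TRUE)]
        rep_groups[[cell$group]] <- c(rep_groups[[cell$group]], draw)
      }
      rep_groups
    })
  })
}

#' Delta-variance permutation test for a disparity difference
#'
#' Tests whether two groups differ in Procrustes variance more than expected
#' if specimens were randomly assigned to groups. The observed statistic is
#' `delta = variance_b - variance_a`; when the plan requests bootstrap
#' equalization the observed group variances are the means over the equalized
#' bootstrap replicates. The null distribution pools the residual Procrustes
#' distances of individuals from their own group mean, randomly permutes
#' them, reassigns the first `n_a` to group A and the rest to group B, and
#' recomputes delta; group means are not recomputed under the null (the
#' distances themselves are the exchangeable units). The p-value is
#' `(b + 1) / (B + 1)` where `b` counts permuted deltas at least as extreme
#' as the observed one.
#'
#' @param aligned an `aligned_sample` from [gpa()], or a
#'   specimens-by-variables score matrix (e.g. size-corrected principal
#'   component scores).
#' @param members_a,members_b disjoint specimen index (or id) vectors.
#' @param plan a [resampling_plan()].
#' @param strata optional per-specimen stratum labels for the bootstrap
#'   (ignored when `plan$n_bootstrap == 0`).
#' @param labels length-2 character vector naming the groups.
#' @param alpha_adjusted significance threshold against which `p_value` is
#'   judged; defaults to the plan's unadjusted `alpha`.
#' @return an object of class `disparity_result`: group variances, delta,
#'   permutation p-value, and all resampling settings.
#' @export
permutation_test <- function(aligned, members_a, members_b,
                             plan = resampling_plan(), strata = NULL,
                             labels = c("group_a", "group_b"),
                             alpha_adjusted = plan$alpha,
                             allow_overlap = FALSE) {
  if (inherits(aligned, "aligned_sample")) {
    members_a <- resolve_members(aligned, members_a)
    members_b <- resolve_members(aligned, members_b)
  }
  if (!allow_overlap && length(intersect(members_a, members_b))) {
    stopf("groups overlap: permutation test requires disjoint groups")
  }
  use_boot <- plan$n_bootstrap > 0L
  if (use_boot) {
    reps <- bootstrap_equalize(
      stats::setNames(list(members_a, members_b), labels),
      strata = strata, plan = plan)
    va_reps <- vapply(reps, function(r) group_variance(aligned, r[[1]]),
                      numeric(1))
    vb_reps <- vapply(reps, function(r) group_variance(aligned, r[[2]]),
                      numeric(1))
    variance_a <- mean(va_reps); variance_b <- mean(vb_reps)
    ref <- reps[[1]]  # reference replicate for the null residual pool
    d_a <- group_residuals(aligned, ref[[1]])
    d_b <- group_residuals(aligned, ref[[2]])
    n_equalized <- length(ref[[1]])
  } else {
    if (length(members_a) < 2L || length(members_b) < 2L) {
      stopf("both groups need at least 2 members")
    }
    variance_a <- group_variance(aligned, members_a)
    variance_b <- group_variance(aligned, members_b)
    d_a <- group_residuals(aligned, members_a)
    d_b <- group_residuals(aligned, members_b)
    n_equalized <- NA_integer_
  }
  delta_obs <- delta_variance(variance_a, variance_b)
  # observed delta for the null comparison uses the same residual pool as the
  # permutations, so the test is exchangeable under H0
  na <- length(d_a); nb <- length(d_b)
  n <- na + nb
  delta_ref <- sum(d_b^2) / (nb - 1) - sum(d_a^2) / (na - 1)
  # canonical pool (sorted) and leading block (the smaller group), so that
  # swapping the group labels reproduces the identical null draws and the
  # two-sided p is exactly label-invariant
  d2 <- sort(c(d_a, d_b)^2, decreasing = TRUE)
  m1 <- min(na, nb)
  lead_is_a <- na <= nb
  total <- sum(d2)
  B <- plan$n_permutations
  perm_seed <- derive_seed(plan$seed, 104729)
  delta_perm <- local_seed(perm_seed, {
    vapply(seq_len(B), function(b) {
      lead <- sum(d2[sample.int(n, m1)])
      v_lead <- lead / (m1 - 1)
      v_rest <- (total - lead) / (n - m1 - 1)
      if (lead_is_a) v_rest - v_lead else v_lead - v_rest
    }, numeric(1))
  })
  eps <- 1e-12
  b_ge <- if (plan$tail == "two_sided") {
    sum(abs(delta_perm) >= abs(delta_ref) - eps)
  } else {
    sum(delta_perm >= delta_ref - eps)
  }
  p <- (b_ge + 1) / (B + 1)
  structure(
    list(dataset_label = NA_character_, region = NA_character_,
         group_a = labels[1], group_b = labels[2],
         n_a = length(members_a), n_b = length(members_b),
         variance_a = variance_a, variance_b = variance_b,
         delta = delta_obs, p_value = p,
         n_permutations = B, n_bootstrap = plan$n_bootstrap,
         n_equalized = n_equalized, seed = plan$seed, tail = plan$tail,
         alpha_adjusted = alpha_adjusted,
         significant = p < alpha_adjusted),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat(sprintf("Delta-variance test: %s vs %s\n", x$group_a, x$group_b))
  cat(sprintf("  variance %s = %.4g, variance %s = %.4g, delta = %.4g\n",
              x$group_a, x$variance_a, x$group_b, x$variance_b, x$delta))
  cat(sprintf("  p = %.4g (%s, %d permutations%s)%s\n", x$p_value, x$tail,
              x$n_permutations,
              if (x$n_bootstrap > 0)
                sprintf(", %d bootstrap reps at n = %d per stratum",
                        x$n_bootstrap, x$n_equalized) else "",
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' @export
as.data.frame.disparity_result <- function(x, ...) {
  data.frame(
    dataset = x$dataset_label, region = x$region,
    group_a = x$group_a, group_b = x$group_b,
    n_a = x$n_a, n_b = x$n_b,
    variance_a = x$variance_a, variance_b = x$variance_b,
    delta = x$delta, p_value = x$p_value,
    alpha_adjusted = x$alpha_adjusted, significant = x$significant,
    stringsAsFactors = FALSE
  )
}

#' Run a battery of region- and group-stratified disparity tests
#'
#' For each grouping and each skull-region query the battery restricts the
#' dataset to the region's landmarks, re-superimposes the subset (so region
#' disparity reflects the region's own shape, not a slice of whole-skull
#' shape), optionally removes allometry, applies the bootstrap-equalized
#' delta-variance permutation test, and emits one result row. After all rows
#' are computed, the Bonferroni threshold `alpha / m` is applied with `m` the
#' number of tests actually performed.
#'
#' @param dataset a [landmark_dataset()] with scheme and metadata.
#' @param regions character vector of region queries (see
#'   [region_subset_ids()]).
#' @param groupings list of groupings. Each grouping is a list with elements
#'   `label`, `a` and `b` (named lists `field = allowed values` selecting the
#'   two groups), and optionally `within` (a filter applied to the whole
#'   dataset first, e.g. `list(diet = "folivore")`).
#' @param plan a [resampling_plan()].
#' @param size_correction remove allometry and test in the size-corrected
#'   principal-component score space (`TRUE`, default), or test partial
#'   Procrustes distances on the aligned coordinates (`FALSE`).
#' @param species_average average aligned specimens within species before
#'   testing (one point per species)?
#' @return a `data.frame` with one row per (grouping, region) test, plus
#'   attributes `m` (tests performed), `alpha_adjusted`, and `skipped` (rows
#'   skipped with reasons). Cells with fewer than 2 specimens per group are
#'   skipped, not errors.
#' @export
run_disparity_battery <- function(dataset, regions, groupings,
                                  plan = resampling_plan(),
                                  size_correction = TRUE,
                                  species_average = FALSE) {
  if (is.null(dataset$scheme)) stopf("dataset has no landmark scheme")
  rows <- list(); skipped <- list()
  test_id <- 0L
  for (grouping in groupings) {
    d_g <- dataset
    for (f in names(grouping$within %||% list())) {
      d_g <- suppressWarnings(
        filter_by_group(d_g, f, grouping$within[[f]]))
    }
    sel_a <- select_members(d_g, grouping$a)
    sel_b <- select_members(d_g, grouping$b)
    for (region in regions) {
      label <- grouping$label %||% "all"
      if (length(sel_a) < 2L || length(sel_b) < 2L) {
        skipped[[length(skipped) + 1L]] <- sprintf(
          "%s / %s: group too small (n_a = %d, n_b = %d)", label, region,
          length(sel_a), length(sel_b))
        next
      }
      ids <- region_subset_ids(d_g$scheme, region)
      d_r <- subset_dataset(d_g, ids)
      test_id <- test_id + 1L
      row_plan <- plan
      row_plan$seed <- as.integer(derive_seed(plan$seed, test_id))
      res <- battery_single_test(d_r, sel_a, sel_b, row_plan,
                                 size_correction, species_average,
                                 labels = c(grouping$label_a %||% "group_a",
                                            grouping$label_b %||% "group_b"),
                                 allow_overlap = isTRUE(grouping$allow_overlap))
      res$dataset_label <- label
      res$region <- region
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  m <- length(rows)
  if (!m) stopf("no testable (grouping, region) combinations")
  out <- do.call(rbind, rows)
  out$alpha_adjusted <- bonferroni_threshold(plan$alpha, m)
  out$significant <- out$p_value < out$alpha_adjusted
  attr(out, "m") <- m
  attr(out, "alpha_adjusted") <- bonferroni_threshold(plan$alpha, m)
  attr(out, "skipped") <- unlist(skipped) %||% character(0)
  out
}

select_members <- function(dataset, filters) {
  keep <- rep(TRUE, n_specimens(dataset))
  for (f in names(filters)) {
    keep <- keep & dataset_field(dataset, f) %in% filters[[f]]
  }
  which(keep)
}

battery_single_test <- function(d_r, sel_a, sel_b, plan, size_correction,
                                species_average, labels,
                                allow_overlap = FALSE) {
  aligned <- gpa(d_r)
  strata <- battery_strata(d_r, plan$strata_fields)
  if (species_average) {
    avg <- average_by_species(aligned)
    aligned <- avg$aligned
    sel_a <- unique(avg$map[sel_a]); sel_b <- unique(avg$map[sel_b])
    strata <- if (!is.null(strata)) strata[avg$first] else NULL
  }
  target <- if (size_correction) {
    remove_allometry(shape_pca(aligned))$scores
  } else {
    aligned
  }
  permutation_test(target, sel_a, sel_b, plan, strata = strata,
                   labels = labels, allow_overlap = allow_overlap)
}

battery_strata <- function(dataset, strata_fields) {
  if (is.null(strata_fields) || !length(strata_fields) ||
      is.null(dataset$metadata)) {
    return(NULL)
  }
  cols <- lapply(strata_fields, function(f) dataset_field(dataset, f))
  do.call(paste, c(cols, sep = "|"))
}

# Average aligned coordinates within species; returns the reduced sample, a
# map from specimen index to species index, and the first specimen index of
# each species (for carrying per-specimen covariates).
average_by_species <- function(aligned) {
  species <- aligned$specimens$species
  uniq <- unique(species)
  map <- match(species, uniq)
  k <- dim(aligned$coords)[1]
  coords <- array(0, dim = c(k, 3, length(uniq)),
                  dimnames = list(dimnames(aligned$coords)[[1]],
                                  c("x", "y", "z"), uniq))
  cs <- numeric(length(uniq))
  for (i in seq_along(uniq)) {
    sel <- which(map == i)
    m <- apply(aligned$coords[, , sel, drop = FALSE], c(1, 2), mean)
    m <- center_config(m)
    if (aligned$scaled) m <- m / sqrt(sum(m^2))
    coords[, , i] <- m
    cs[i] <- exp(mean(log(aligned$centroid_sizes[sel])))
  }
  out <- aligned
  out$coords <- coords
  out$centroid_sizes <- cs
  out$specimens <- data.frame(specimen_id = uniq, species = uniq,
                              stringsAsFactors = FALSE)
  list(aligned = out, map = map, first = match(uniq, species))
}
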