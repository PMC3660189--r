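#' Standard clade groupings for disparity batteries
#'
#' `clade_groupings()` builds the grouping list for an extant
#' marsupial-versus-placental battery: the full dataset, plus (optionally)
#' one grouping per ecological split — the four diet classes, the
#' nocturnal/crepuscular activity class, and the three habitat classes (eight
#' splits; diurnal and cathemeral taxa are too scarce among marsupials to
#' support a comparison and are not split on). With `eco_splits = TRUE` and
#' four region queries this yields the 36-test battery; the full-dataset
#' grouping alone over five regions yields the 5-test battery.
#' `metatherian_grouping()` compares extant marsupials against extant
#' marsupials pooled with fossil metatherians.
#'
#' @param eco_splits include the eight ecological splits?
#' @return a list of groupings for [run_disparity_battery()].
#' @export
clade_groupings <- function(eco_splits = FALSE) {
  base <- list(label = "all", label_a = "marsupial", label_b = "placental",
               a = list(clade = "marsupial"), b = list(clade = "placental"))
  out <- list(base)
  if (eco_splits) {
    splits <- c(
      folivores = "diet=folivore", frugivores = "diet=frugivore",
      carnivores_insectivores = "diet=carnivore_insectivore",
      omnivores = "diet=omnivore",
      nocturnal_crepuscular = "activity=nocturnal_crepuscular",
      arboreal = "habitat=arboreal", terrestrial = "habitat=terrestrial",
      fossorial = "habitat=fossorial"
    )
    for (nm in names(splits)) {
      fv <- strsplit(splits[[nm]], "=", fixed = TRUE)[[1]]
      g <- base
      g$label <- nm
      g$within <- stats::setNames(list(fv[2]), fv[1])
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' @rdname clade_groupings
#' @export
metatherian_grouping <- function() {
  list(list(
    label = "marsupials_vs_marsupials_plus_fossils",
    label_a = "marsupials", label_b = "marsupials_and_fossils",
    a = list(clade = "marsupial"),
    b = list(clade = c("marsupial", "fossil_metatherian")),
    # the extant specimens appear in both groups by design; the permutation
    # pools the two groups' residual distances regardless
    allow_overlap = TRUE
  ))
}

#' Pipeline configuration
#'
#' Reads (or validates) the configuration driving the command-line pipeline.
#' Configurations are JSON objects; every output written by the pipeline
#' records the seed and a hash of the configuration so runs are traceable and
#' re-execution with an unchanged configuration is bit-identical.
#'
#' @param config a named list, or the path of a JSON configuration file.
#' @return a validated configuration list of class `pipeline_config`, with a
#'   `hash` field.
#' @export
pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out <- config$out %||% "morphodisp_out"
  for (f in c("landmarks", "metadata")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stopf("configured %s path '%s' does not exist", f, config[[f]])
    }
  }
  # the hash captures the analytic inputs only, not where results land or
  # whether overwriting was allowed
  analytic <- config[setdiff(sort(names(config)), c("out", "force", "hash"))]
  canonical <- jsonlite::toJSON(analytic, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(canonical), tmp)
  config$hash <- substr(unname(tools::md5sum(tmp)), 1, 12)
  unlink(tmp)
  class(config) <- c("pipeline_config", "list")
  config
}

config_plan <- function(config) {
  resampling_plan(
    n_bootstrap = config$n_bootstrap %||% 1000L,
    n_permutations = config$n_permutations %||% 1000L,
    seed = config$seed,
    n_target = config$n_target,
    strata_fields = config$strata_fields %||% c("clade", "sex"),
    tail = config$tail %||% "two_sided",
    alpha = config$alpha %||% 0.01
  )
}

pipeline_log <- function(lines, stage, ...) {
  c(lines, sprintf("[%s] %s", stage, sprintf(...)))
}

prepare_outdir <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  config$out
}

write_manifest <- function(outdir, files, config, log_lines) {
  writeLines(log_lines, file.path(outdir, "log.txt"))
  files <- c(files, file.path(outdir, "log.txt"))
  sums <- tools::md5sum(files)
  manifest <- sprintf("%s  %s", sums, basename(names(sums)))
  header <- sprintf("# config_hash=%s seed=%d", config$hash, config$seed)
  writeLines(c(header, manifest), file.path(outdir, "manifest.txt"))
  invisible(files)
}

check_overwrite <- function(outdir, files, force) {
  existing <- files[file.exists(files)]
  if (length(existing) && !isTRUE(force)) {
    stopf("output file(s) already exist (use force = TRUE / --force): %s",
          paste(basename(existing), collapse = ", "))
  }
}

#' Simulate a synthetic study and write it to disk
#'
#' Writes landmarks (`csv_long`), metadata, and the landmark scheme of a
#' synthetic study to the configured output directory, plus a manifest with
#' checksums and a log. Re-running with the same configuration produces
#' identical files; existing outputs are not overwritten unless
#' `config$force` is set.
#'
#' @param config a [pipeline_config()] (list or JSON path). Recognized
#'   fields: `seed`, `out`, `force`, `sex_ratio`, `size_distribution`,
#'   `groups` (as in [synthetic_spec()]), `scheme`.
#' @return invisibly, the paths written.
#' @export
cmd_simulate <- function(config) {
  config <- pipeline_config(config)
  outdir <- prepare_outdir(config)
  files <- file.path(outdir, c("landmarks.csv", "metadata.csv", "scheme.csv"))
  check_overwrite(outdir, files, config$force)
  log_lines <- pipeline_log(character(), "simulate",
                            "seed=%d config=%s", config$seed, config$hash)
  groups <- config$groups
  if (!is.null(groups) && is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) as.list(groups[i, ]))
  }
  spec <- synthetic_spec(
    groups = groups,
    scheme = load_scheme(config$scheme %||% "table3"),
    sex_ratio = config$sex_ratio %||% 0.5,
    size_distribution = config$size_distribution %||% c(3, 0.4),
    seed = config$seed
  )
  ds <- simulate_study(spec)
  write_landmark_table(ds, files[1], "csv_long")
  write_metadata(ds$metadata, files[2])
  write_scheme(ds$scheme, files[3])
  log_lines <- pipeline_log(log_lines, "simulate",
                            "%d specimens x %d landmarks written",
                            n_specimens(ds), n_landmarks(ds))
  write_manifest(outdir, files, config, log_lines)
  invisible(files)
}

load_configured_dataset <- function(config) {
  if (is.null(config$landmarks)) stopf("config requires a 'landmarks' path")
  ds <- read_landmark_table(config$landmarks,
                            config$landmark_format %||% "csv_long")
  if (!is.null(config$metadata)) {
    ds <- attach_metadata(ds, read_metadata(config$metadata))
  }
  scheme <- load_scheme(config$scheme %||% "table3")
  if (!is.null(config$scheme_variant)) {
    ids <- scheme$variants[[config$scheme_variant]]
    if (is.null(ids)) stopf("scheme has no variant '%s'", config$scheme_variant)
  }
  if (!identical(as.integer(scheme$landmark_ids), ds$landmark_ids)) {
    stopf("scheme '%s' landmark ids do not match the landmark file",
          scheme$name)
  }
  ds$scheme <- scheme
  if (!is.null(config$scheme_variant)) {
    ds <- subset_dataset(ds, scheme$variants[[config$scheme_variant]])
  }
  ds
}

config_groupings <- function(config) {
  if (is.null(config$groupings) || is.character(config$groupings)) {
    spec <- config$groupings %||% "clades"
    return(switch(spec,
                  clades = clade_groupings(FALSE),
                  clades_eco = clade_groupings(TRUE),
                  metatherian = metatherian_grouping(),
                  stopf("unknown grouping preset '%s'", spec)))
  }
  config$groupings
}

#' Run the full disparity pipeline
#'
#' Reads landmarks, metadata and scheme, runs generalized Procrustes
#' superimposition, optional allometric correction, and the delta-variance
#' battery over the configured regions and groupings, and writes a report CSV
#' (one row per test: dataset, skull region, group variances, delta, p-value,
#' Bonferroni-adjusted decision), a log, and a manifest.
#'
#' @param config a [pipeline_config()]. Recognized fields: `landmarks`,
#'   `landmark_format`, `metadata`, `scheme`, `scheme_variant`, `regions`,
#'   `groupings` (`"clades"`, `"clades_eco"`, `"metatherian"`, or an explicit
#'   list), `size_correction`, `species_average`, `n_permutations`,
#'   `n_bootstrap`, `n_target`, `strata_fields`, `alpha`, `seed`, `out`,
#'   `force`.
#' @return the battery result `data.frame`, invisibly.
#' @export
cmd_run <- function(config) {
  config <- pipeline_config(config)
  outdir <- prepare_outdir(config)
  report_path <- file.path(outdir, "disparity_report.csv")
  check_overwrite(outdir, report_path, config$force)
  log_lines <- pipeline_log(character(), "run", "seed=%d config=%s",
                            config$seed, config$hash)
  ds <- load_configured_dataset(config)
  log_lines <- pipeline_log(log_lines, "read", "%d specimens x %d landmarks",
                            n_specimens(ds), n_landmarks(ds))
  regions <- config$regions %||% REGION_QUERIES
  groupings <- config_groupings(config)
  plan <- config_plan(config)
  res <- run_disparity_battery(
    ds, regions = regions, groupings = groupings, plan = plan,
    size_correction = config$size_correction %||% TRUE,
    species_average = config$species_average %||% FALSE)
  m <- attr(res, "m")
  log_lines <- pipeline_log(log_lines, "battery",
                            "%d tests, Bonferroni m=%d, adjusted alpha=%g",
                            nrow(res), m, attr(res, "alpha_adjusted"))
  for (s in attr(res, "skipped")) {
    log_lines <- pipeline_log(log_lines, "battery", "skipped: %s", s)
  }
  header <- sprintf("# config_hash=%s seed=%d bonferroni_m=%d adjusted_alpha=%g",
                    config$hash, config$seed, m, attr(res, "alpha_adjusted"))
  writeLines(header, report_path)
  suppressWarnings(utils::write.table(
    res, report_path, sep = ",", row.names = FALSE, append = TRUE,
    quote = FALSE))
  write_manifest(outdir, report_path, config, log_lines)
  invisible(res)
}

#' Export morphospace scores, variance percentages, and hull areas
#'
#' Runs superimposition and principal component analysis (raw and
#' size-corrected), writes both score tables with percent variance per
#' component, per-clade convex-hull areas on the configured axis pairs, and
#' optional scatter plots with hull outlines.
#'
#' @param config a [pipeline_config()]. Additional fields: `axes` (list of
#'   axis pairs, default `list(c(1, 2), c(3, 4))`), `hull_field` (metadata
#'   field whose classes get hulls, default `"clade"`), `plots` (write PNG
#'   scatter plots?).
#' @return invisibly, a list with both `shape_space` objects and the hull
#'   table.
#' @export
cmd_pca <- function(config) {
  config <- pipeline_config(config)
  outdir <- prepare_outdir(config)
  files <- file.path(outdir, c("scores_raw.csv", "scores_corrected.csv",
                               "percent_variance.csv", "hull_areas.csv"))
  check_overwrite(outdir, files, config$force)
  log_lines <- pipeline_log(character(), "pca", "seed=%d config=%s",
                            config$seed, config$hash)
  ds <- load_configured_dataset(config)
  aligned <- gpa(ds)
  log_lines <- pipeline_log(log_lines, "gpa", "%d iterations, converged=%s",
                            aligned$iterations, aligned$converged)
  raw <- shape_pca(aligned)
  corrected <- remove_allometry(raw)
  max_cor <- max(abs(stats::cor(corrected$scores, corrected$log_cs)))
  log_lines <- pipeline_log(log_lines, "allometry",
                            "max |cor(corrected score, log CS)| = %.3g", max_cor)
  utils::write.csv(score_table(raw, ds), files[1], row.names = FALSE)
  utils::write.csv(score_table(corrected, ds), files[2], row.names = FALSE)
  pv <- data.frame(
    component = colnames(raw$scores),
    percent_raw = raw$percent_variance,
    percent_corrected = c(corrected$percent_variance,
                          rep(NA, ncol(raw$scores) - ncol(corrected$scores)))
  )
  utils::write.csv(pv, files[3], row.names = FALSE)
  axes <- config$axes %||% list(c(1, 2), c(3, 4))
  if (is.matrix(axes)) axes <- asplit(axes, 1)
  hull_field <- config$hull_field %||% "clade"
  classes <- unique(dataset_field(ds, hull_field))
  hull_rows <- list()
  for (ax in axes) {
    ax <- as.integer(ax)
    if (max(ax) > ncol(corrected$scores)) next
    for (cl in classes) {
      members <- which(dataset_field(ds, hull_field) == cl)
      area <- suppressWarnings(
        morphospace_hull_area(corrected, members, ax))
      hull_rows[[length(hull_rows) + 1L]] <- data.frame(
        axes = paste(ax, collapse = "-"), class = cl,
        n = length(members), hull_area = area)
    }
    if (isTRUE(config$plots)) {
      plot_path <- file.path(outdir, sprintf("morphospace_PC%d_PC%d.png",
                                             ax[1], ax[2]))
      plot_morphospace(corrected, dataset_field(ds, hull_field), ax, plot_path)
      files <- c(files, plot_path)
    }
  }
  hulls <- do.call(rbind, hull_rows)
  utils::write.csv(hulls, files[4], row.names = FALSE)
  write_manifest(outdir, files, config, log_lines)
  invisible(list(raw = raw, corrected = corrected, hulls = hulls))
}

score_table <- function(space, ds) {
  cbind(ds$specimens, as.data.frame(space$scores))
}

plot_morphospace <- function(space, classes, axes, path) {
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  s <- space$scores[, axes, drop = FALSE]
  cls <- factor(classes)
  graphics::plot(s, col = as.integer(cls), pch = as.integer(cls),
                 xlab = sprintf("PC%d (%.1f%%)", axes[1],
                                space$percent_variance[axes[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2],
                                space$percent_variance[axes[2]]))
  for (li in seq_along(levels(cls))) {
    pts <- s[as.integer(cls) == li, , drop = FALSE]
    if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts)
      graphics::polygon(pts[h, ], border = li, lty = li)
    }
  }
  graphics::legend("topright", legend = levels(cls),
                   col = seq_along(levels(cls)), pch = seq_along(levels(cls)))
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `run` and `pca` subcommands. Flags:
#' `--config <path>` (JSON), `--seed <int>`, `--out <dir>`, `--regions a,b`,
#' `--grouping <preset>`, `--no-size-correction`, `--permutations <int>`,
#' `--bootstraps <int>`, `--force`. Command-line flags override the
#' configuration file. Installed as `inst/cli/morphodisp`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
morphodisp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: morphodisp <simulate|run|pca> [--config path] [--seed n] [--out dir] [--regions a,b] [--grouping preset] [--no-size-correction] [--permutations n] [--bootstraps n] [--force]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  config <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
           "--config" = { config <- jsonlite::read_json(take(),
                                                        simplifyVector = TRUE) },
           "--seed" = { config$seed <- as.integer(take()) },
           "--out" = { config$out <- take() },
           "--regions" = { config$regions <- strsplit(take(), ",")[[1]] },
           "--grouping" = { config$groupings <- take() },
           "--no-size-correction" = { config$size_correction <- FALSE },
           "--permutations" = { config$n_permutations <- as.integer(take()) },
           "--bootstraps" = { config$n_bootstrap <- as.integer(take()) },
           "--force" = { config$force <- TRUE },
           stopf("unknown flag '%s'\n%s", a, usage))
    i <- i + 1L
  }
  switch(cmd,
         simulate = cmd_simulate(config),
         run = cmd_run(config),
         pca = cmd_pca(config),
         stopf("unknown subcommand '%s'\n%s", cmd, usage))
  invisible(0L)
}
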