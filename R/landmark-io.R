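#' Landmark datasets
#'
#' A landmark dataset bundles the 3D landmark configurations of a sample of
#' specimens (a `k x 3 x n` coordinate array), the specimen table (specimen id
#' and species), an optional [landmark_scheme()], and optional per-species
#' metadata (clade, sex, ecology).
#'
#' @param coords numeric array `k x 3 x n` of landmark coordinates, or a list
#'   of `k x 3` matrices.
#' @param specimen_id character vector of specimen identifiers (length n).
#' @param species character vector of species names (length n).
#' @param landmark_ids integer landmark identifiers (length k); defaults to
#'   `1:k`.
#' @param scheme optional [landmark_scheme()]; its ids must match
#'   `landmark_ids`.
#' @param metadata optional metadata table as returned by [read_metadata()].
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, specimen_id, species,
                             landmark_ids = NULL, scheme = NULL,
                             metadata = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) != 1L) {
      bad <- specimen_id[which(ks != ks[1])[1]]
      stopf("inconsistent landmark counts across specimens (specimen '%s' has %d, expected %d)",
            bad, ks[ks != ks[1]][1], ks[1])
    }
    coords <- array(unlist(coords), dim = c(ks[1], 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (length(specimen_id) != n || length(species) != n) {
    stopf("specimen_id and species must have one entry per configuration")
  }
  if (anyDuplicated(specimen_id)) stopf("duplicated specimen ids")
  if (!all(is.finite(coords))) {
    bad <- specimen_id[which(apply(coords, 3, function(m) any(!is.finite(m))))[1]]
    stopf("non-finite coordinate in specimen '%s'", bad)
  }
  landmark_ids <- as.integer(landmark_ids %||% seq_len(k))
  if (length(landmark_ids) != k) stopf("need %d landmark ids, got %d",
                                       k, length(landmark_ids))
  if (!is.null(scheme)) {
    if (!identical(as.integer(scheme$landmark_ids), landmark_ids)) {
      stopf("scheme '%s' landmark ids do not match the dataset's", scheme$name)
    }
  }
  dimnames(coords) <- list(landmark_ids, c("x", "y", "z"), specimen_id)
  obj <- structure(
    list(coords = coords,
         specimens = data.frame(specimen_id = as.character(specimen_id),
                                species = as.character(species),
                                stringsAsFactors = FALSE),
         landmark_ids = landmark_ids,
         scheme = scheme, metadata = NULL),
    class = "landmark_dataset"
  )
  if (!is.null(metadata)) obj <- attach_metadata(obj, metadata)
  obj
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("Landmark dataset: %d specimens x %d landmarks x 3\n",
              n_specimens(x), n_landmarks(x)))
  if (!is.null(x$scheme)) cat(sprintf("Scheme: %s\n", x$scheme$name))
  if (!is.null(x$metadata)) {
    cat("Clades:", paste(sprintf("%s (%d)", names(table(dataset_field(x, "clade"))),
                                 table(dataset_field(x, "clade"))),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname landmark_dataset
#' @param dataset a `landmark_dataset`.
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' @rdname landmark_dataset
#' @export
n_landmarks <- function(dataset) dim(dataset$coords)[1]

METADATA_VOCAB <- list(
  clade = c("marsupial", "placental", "fossil_metatherian"),
  sex = c("male", "female", "unknown"),
  diet = c("folivore", "frugivore", "carnivore_insectivore", "omnivore",
           "none"),
  habitat = c("arboreal", "terrestrial", "fossorial", "none"),
  activity = c("nocturnal_crepuscular", "diurnal", "cathemeral", "none")
)

METADATA_FIELDS <- c("species", names(METADATA_VOCAB))

validate_metadata <- function(md) {
  if (!all(c("species", "clade") %in% names(md))) {
    stopf("metadata requires columns species and clade")
  }
  for (f in names(METADATA_VOCAB)) {
    if (!f %in% names(md)) {
      md[[f]] <- if (f == "clade") NA_character_ else
        if (f == "sex") "unknown" else "none"
    }
    md[[f]] <- as.character(md[[f]])
    bad <- setdiff(unique(md[[f]]), METADATA_VOCAB[[f]])
    if (length(bad)) {
      stopf("unknown %s token(s): %s (allowed: %s)", f,
            paste(bad, collapse = ", "),
            paste(METADATA_VOCAB[[f]], collapse = ", "))
    }
  }
  if (anyNA(md$clade)) stopf("metadata: clade must always be set")
  # collapse duplicate rows; conflicting duplicates are an error
  if (anyDuplicated(md$species)) {
    md <- unique(md[METADATA_FIELDS])
    dup <- md$species[duplicated(md$species)]
    if (length(dup)) {
      stopf("conflicting metadata rows for species: %s",
            paste(unique(dup), collapse = ", "))
    }
  }
  rownames(md) <- NULL
  md[METADATA_FIELDS]
}

#' Read a specimen metadata table
#'
#' The table must be a delimited file (CSV, or any whitespace/tab separation)
#' with a header and at least the columns `species` and `clade`; `sex`,
#' `diet`, `habitat` and `activity` are optional and default to
#' `"unknown"`/`"none"`. All category fields are closed vocabularies: `clade`
#' in marsupial/placental/fossil_metatherian, `diet` in
#' folivore/frugivore/carnivore_insectivore/omnivore/none, `habitat` in
#' arboreal/terrestrial/fossorial/none, `activity` in
#' nocturnal_crepuscular/diurnal/cathemeral/none. Fossils typically carry
#' `"none"` in the ecological fields. Duplicate identical rows collapse to
#' one record; conflicting duplicates are an error.
#'
#' @param path metadata file path.
#' @return a `data.frame` with one validated row per species.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file '%s' not found", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(md) == 1L) {
    md <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param metadata a metadata `data.frame`.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(validate_metadata(metadata), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Attach validated metadata to a dataset
#'
#' Every species present in the dataset must have a metadata row.
#'
#' @param dataset a [landmark_dataset()].
#' @param metadata metadata table (see [read_metadata()]).
#' @return the dataset with metadata attached.
#' @export
attach_metadata <- function(dataset, metadata) {
  metadata <- validate_metadata(metadata)
  missing <- setdiff(unique(dataset$specimens$species), metadata$species)
  if (length(missing)) {
    stopf("no metadata for species: %s", paste(missing, collapse = ", "))
  }
  dataset$metadata <- metadata
  dataset
}

#' Per-specimen value of a metadata field
#'
#' Looks up a metadata field for every specimen via its species
#' (`"species"` itself is also accepted).
#'
#' @param dataset a [landmark_dataset()] with metadata.
#' @param field one of species, clade, sex, diet, habitat, activity.
#' @return character vector, one value per specimen.
#' @export
dataset_field <- function(dataset, field) {
  if (field == "species") return(dataset$specimens$species)
  if (!field %in% METADATA_FIELDS) stopf("unknown metadata field '%s'", field)
  if (is.null(dataset$metadata)) stopf("dataset has no metadata attached")
  idx <- match(dataset$specimens$species, dataset$metadata$species)
  dataset$metadata[[field]][idx]
}

#' Read landmark coordinates from a file
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{`csv_long`}{one row per landmark with columns
#'     `specimen_id, species, landmark_id, x, y, z`.}
#'   \item{`csv_wide`}{one row per specimen with columns
#'     `specimen_id, species, x1, y1, z1, x2, ...`.}
#'   \item{`tps3d`}{TPS-style blocks: `LM3=<k>` followed by `k` lines of three
#'     whitespace-separated reals, then `ID=<specimen>` and optionally
#'     `SPECIES=<species>` (species defaults to the specimen id).}
#' }
#' All specimens must share one landmark count and order; violations name the
#' offending specimen.
#'
#' @param path input file.
#' @param format one of `"csv_long"`, `"csv_wide"`, `"tps3d"`.
#' @return a [landmark_dataset()] without metadata.
#' @export
read_landmark_table <- function(path,
                                format = c("csv_long", "csv_wide", "tps3d")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("landmark file '%s' not found", path)
  switch(format,
         csv_long = read_csv_long(path),
         csv_wide = read_csv_wide(path),
         tps3d = read_tps3d(path))
}

read_csv_long <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("specimen_id", "species", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stopf("csv_long requires columns %s", paste(need, collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stopf("non-numeric coordinate in column %s at data line %d", col, bad)
    }
  }
  split_idx <- split(seq_len(nrow(tab)), tab$specimen_id)
  # preserve file order of specimens
  split_idx <- split_idx[unique(tab$specimen_id)]
  ref_ids <- NULL
  configs <- vector("list", length(split_idx))
  species <- character(length(split_idx))
  for (i in seq_along(split_idx)) {
    rows <- tab[split_idx[[i]], ]
    rows <- rows[order(match(rows$landmark_id, unique(tab$landmark_id))), ]
    if (is.null(ref_ids)) {
      ref_ids <- rows$landmark_id
    } else if (!identical(rows$landmark_id, ref_ids)) {
      stopf("specimen '%s' has landmarks (%s) inconsistent with '%s'",
            rows$specimen_id[1], paste(rows$landmark_id, collapse = ","),
            names(split_idx)[1])
    }
    configs[[i]] <- as.matrix(rows[c("x", "y", "z")])
    species[i] <- rows$species[1]
  }
  landmark_dataset(configs, names(split_idx), species,
                   landmark_ids = ref_ids)
}

read_csv_wide <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("specimen_id", "species") %in% names(tab))) {
    stopf("csv_wide requires columns specimen_id, species")
  }
  coord_cols <- grep("^[xyz][0-9]+$", names(tab), value = TRUE)
  k <- length(coord_cols) / 3
  if (k < 1 || k != floor(k)) stopf("csv_wide: malformed coordinate columns")
  expect <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                              function(i, a) paste0(a, i))))
  if (!all(expect %in% names(tab))) {
    stopf("csv_wide: missing coordinate columns (need x1,y1,z1,...)")
  }
  mats <- lapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(as.numeric(unlist(tab[i, expect])), ncol = 3, byrow = TRUE)
    if (any(!is.finite(m))) {
      stopf("non-numeric coordinate at data line %d", i)
    }
    m
  })
  landmark_dataset(mats, tab$specimen_id, tab$species)
}

read_tps3d <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  configs <- list(); ids <- character(); species <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^LM3=", ln)) stopf("tps3d parse error at line %d: expected LM3=", i)
    k <- as.integer(sub("^LM3=", "", ln))
    if (is.na(k) || k < 1) stopf("tps3d: bad landmark count at line %d", i)
    if (i + k > length(lines)) stopf("tps3d: truncated block starting line %d", i)
    m <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[i + j], "[ \t]+")[[1]]))
      if (length(vals) != 3 || anyNA(vals)) {
        stopf("non-numeric coordinate at line %d", i + j)
      }
      m[j, ] <- vals
    }
    i <- i + k + 1L
    id <- NA_character_; sp <- NA_character_
    while (i <= length(lines) && grepl("^(ID|SPECIES)=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      if (grepl("^SPECIES=", lines[i])) sp <- sub("^SPECIES=", "", lines[i])
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("specimen_", length(configs) + 1L)
    if (is.na(sp)) sp <- id
    configs[[length(configs) + 1L]] <- m
    ids <- c(ids, id); species <- c(species, sp)
  }
  if (!length(configs)) stopf("tps3d file '%s' contains no specimens", path)
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- ids[which(ks != ks[1])[1]]
    stopf("inconsistent landmark counts across specimens (specimen '%s')", bad)
  }
  landmark_dataset(configs, ids, species)
}

#' Write landmark coordinates to a file
#'
#' @inheritParams read_landmark_table
#' @param dataset a [landmark_dataset()].
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path,
                                 format = c("csv_long", "csv_wide", "tps3d")) {
  format <- match.arg(format)
  n <- n_specimens(dataset); k <- n_landmarks(dataset)
  sp <- dataset$specimens
  if (format == "csv_long") {
    tab <- data.frame(
      specimen_id = rep(sp$specimen_id, each = k),
      species = rep(sp$species, each = k),
      landmark_id = rep(dataset$landmark_ids, n),
      x = as.vector(dataset$coords[, 1, ]),
      y = as.vector(dataset$coords[, 2, ]),
      z = as.vector(dataset$coords[, 3, ])
    )
    utils::write.csv(format_coords_df(tab), path, row.names = FALSE,
                     quote = FALSE)
  } else if (format == "csv_wide") {
    flat <- t(apply(dataset$coords, 3, function(m) as.vector(t(m))))
    colnames(flat) <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                        function(i, a) paste0(a, i))))
    tab <- cbind(sp, as.data.frame(flat))
    utils::write.csv(format_coords_df(tab), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(sprintf("LM3=%d", k), con)
      m <- dataset$coords[, , i]
      writeLines(apply(m, 1, function(r)
        paste(format_full(r), collapse = " ")), con)
      writeLines(sprintf("ID=%s", sp$specimen_id[i]), con)
      writeLines(sprintf("SPECIES=%s", sp$species[i]), con)
    }
  }
  invisible(path)
}

# full-precision decimal text so read(write(x)) round-trips exactly
format_full <- function(x) formatC(x, format = "g", digits = 17)

format_coords_df <- function(tab) {
  for (col in names(tab)) {
    if (is.numeric(tab[[col]]) && !all(tab[[col]] == round(tab[[col]]))) {
      tab[[col]] <- format_full(tab[[col]])
    }
  }
  tab
}

#' Restrict a dataset to a subset of landmarks
#'
#' Coordinates are restricted and reordered to the requested ids; specimen
#' table, metadata and (via subsetting) the scheme follow along.
#'
#' @param dataset a [landmark_dataset()].
#' @param landmark_ids integer ids, all present in the dataset.
#' @return a new [landmark_dataset()].
#' @export
subset_dataset <- function(dataset, landmark_ids) {
  landmark_ids <- as.integer(landmark_ids)
  unknown <- setdiff(landmark_ids, dataset$landmark_ids)
  if (length(unknown)) {
    stopf("unknown landmark id(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(landmark_ids) < 3L) {
    stopf("degenerate region: %d landmark(s) requested, need at least 3",
          length(landmark_ids))
  }
  pos <- match(landmark_ids, dataset$landmark_ids)
  sub_scheme <- NULL
  if (!is.null(dataset$scheme)) {
    sc <- dataset$scheme
    sub_scheme <- landmark_scheme(
      name = sc$name, landmark_ids = landmark_ids,
      regions = unname(sc$regions[as.character(landmark_ids)]),
      landmark_names = if (!is.null(sc$landmark_names))
        unname(sc$landmark_names[as.character(landmark_ids)]),
      variants = lapply(sc$variants, intersect, landmark_ids)
    )
  }
  landmark_dataset(dataset$coords[pos, , , drop = FALSE],
                   dataset$specimens$specimen_id, dataset$specimens$species,
                   landmark_ids = landmark_ids, scheme = sub_scheme,
                   metadata = dataset$metadata)
}

#' Filter a dataset by a metadata field
#'
#' Keeps specimens whose species metadata matches any of `value`. Filtering by
#' `"species"` matches species names directly. An empty result is allowed
#' (with a warning), mirroring ecological categories that drop out of an
#' analysis entirely.
#'
#' @param dataset a [landmark_dataset()] with metadata (unless filtering on
#'   species).
#' @param field one of species, clade, sex, diet, habitat, activity.
#' @param value one or more allowed values for the field.
#' @return the filtered [landmark_dataset()].
#' @export
filter_by_group <- function(dataset, field, value) {
  vals <- dataset_field(dataset, field)
  keep <- vals %in% value
  if (!any(keep)) {
    warnf("filter %s = %s matches no specimens", field,
          paste(value, collapse = "/"))
  }
  keep_specimens(dataset, which(keep))
}

# internal: restrict to specimen indices (possibly empty)
keep_specimens <- function(dataset, idx) {
  out <- dataset
  out$coords <- dataset$coords[, , idx, drop = FALSE]
  out$specimens <- dataset$specimens[idx, , drop = FALSE]
  rownames(out$specimens) <- NULL
  out
}
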