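#' Landmark schemes: region assignments for cranial landmarks
#'
#' A landmark scheme names the landmarks of a digitizing protocol and assigns
#' each one to a skull region used in disparity analyses. Regions follow the
#' standard developmental partition of the therian cranium: the early-ossifying
#' oral region, the remainder of the viscerocranium (face), landmarks shared by
#' both viscerocranial subsets, and the neurocranium (braincase).
#'
#' @param name scheme name.
#' @param landmark_ids integer vector of landmark identifiers (ordered).
#' @param regions character vector, one region tag per landmark, each one of
#'   `"oral"`, `"viscerocranium_both"`, `"viscerocranium_non_oral"`,
#'   `"neurocranium"`.
#' @param landmark_names optional character vector of landmark descriptions.
#' @param variants optional named list of landmark-id subsets (e.g. a reduced
#'   landmark set usable across more taxa).
#' @return an object of class `landmark_scheme`.
#' @seealso [load_scheme()], [region_subset_ids()]
#' @export
landmark_scheme <- function(name, landmark_ids, regions,
                            landmark_names = NULL, variants = list()) {
  landmark_ids <- as.integer(landmark_ids)
  if (anyDuplicated(landmark_ids)) {
    stopf("scheme '%s': duplicated landmark ids", name)
  }
  if (length(regions) != length(landmark_ids)) {
    stopf("scheme '%s': %d landmarks but %d region tags",
          name, length(landmark_ids), length(regions))
  }
  bad <- setdiff(unique(regions), REGION_TAGS)
  if (length(bad)) {
    stopf("scheme '%s': unknown region tag(s): %s", name,
          paste(bad, collapse = ", "))
  }
  if (anyNA(regions)) stopf("scheme '%s': landmark lacking a region", name)
  regions <- stats::setNames(as.character(regions), landmark_ids)
  if (!is.null(landmark_names)) {
    stopifnot(length(landmark_names) == length(landmark_ids))
    landmark_names <- stats::setNames(as.character(landmark_names),
                                      landmark_ids)
  }
  for (v in names(variants)) {
    extra <- setdiff(as.integer(variants[[v]]), landmark_ids)
    if (length(extra)) {
      stopf("scheme '%s': variant '%s' has ids outside the scheme: %s",
            name, v, paste(extra, collapse = ", "))
    }
  }
  structure(
    list(name = name, landmark_ids = landmark_ids, regions = regions,
         landmark_names = landmark_names, variants = variants),
    class = "landmark_scheme"
  )
}

REGION_TAGS <- c("oral", "viscerocranium_both", "viscerocranium_non_oral",
                 "neurocranium")

REGION_QUERIES <- c("whole_skull", "neurocranium", "viscerocranium",
                    "viscerocranium_non_oral", "oral")

# The built-in 32-landmark therian cranial scheme. Landmarks 1-32 cover the
# whole skull; region tags drive the disparity region queries. Eight
# viscerocranial landmarks sit at oral/facial sutures and belong to both the
# oral and the non-oral viscerocranial query sets.
builtin_scheme_32 <- function() {
  desc <- c(
    "Midline premaxilla / upper central incisors",
    "Anterior-most nasal-nasal suture (midline)",
    "Posterior nasal-frontal contact (midline)",
    "Posterior frontal-parietal contact (midline)",
    "Posterior-most extent of vault (midpoint)",
    "Anterior nasal-premaxilla/maxilla, left",
    "Anterior nasal-premaxilla/maxilla, right",
    "Premaxilla-maxilla suture, alveolar margin, left",
    "Premaxilla-maxilla suture, alveolar margin, right",
    "Nasal-frontal-maxilla/premaxilla junction, left",
    "Nasal-frontal-maxilla/premaxilla junction, right",
    "Medial-most maxilla-lacrimal contact, left",
    "Medial-most maxilla-lacrimal contact, right",
    "Lateral-most maxilla-lacrimal contact, left",
    "Lateral-most maxilla-lacrimal contact, right",
    "Jugal-squamosal, dorsal zygomatic arch, left",
    "Jugal-squamosal, dorsal zygomatic arch, right",
    "Jugal-squamosal, ventral zygomatic arch, left",
    "Jugal-squamosal, ventral zygomatic arch, right",
    "Dorsal occipital condyle-foramen magnum margin, left",
    "Dorsal occipital condyle-foramen magnum margin, right",
    "Ventral-most frontal-parietal suture, left",
    "Ventral-most frontal-parietal suture, right",
    "Posterior palatine-palatine suture (midline)",
    "Ventral-most jugal-maxilla suture, left",
    "Ventral-most jugal-maxilla suture, right",
    "Posterior-most maxilla-palatine junction, left",
    "Posterior-most maxilla-palatine junction, right",
    "Posterior lateral extent of molar row, left",
    "Posterior lateral extent of molar row, right",
    "Anterior lateral extent of molar row, left",
    "Anterior lateral extent of molar row, right"
  )
  region <- character(32)
  region[c(1, 8, 9, 24, 27, 28, 29, 30, 31, 32)] <- "oral"
  region[c(6, 7, 10, 11, 12, 13, 14, 15)] <- "viscerocranium_both"
  region[c(2, 3, 16, 17, 18, 19, 25, 26)] <- "viscerocranium_non_oral"
  region[c(4, 5, 20, 21, 22, 23)] <- "neurocranium"
  landmark_scheme(
    name = "table3", landmark_ids = 1:32, regions = region,
    landmark_names = desc,
    variants = list(maximum_landmarks = 1:32)
  )
}

#' Load a landmark scheme by name or from a scheme file
#'
#' `"table3"` (alias `"cranial32"`) names the built-in 32-landmark cranial
#' scheme with 10 oral, 8 shared oral/non-oral viscerocranial, 8 non-oral
#' viscerocranial and 6 neurocranial landmarks. Any other argument is treated
#' as the path of a delimited scheme file with columns `landmark_id`, `name`,
#' `region` (comma- or tab-separated, header required). Additional columns are
#' interpreted as 0/1 variant membership indicators and become named variants.
#'
#' @param name_or_path `"table3"`, `"cranial32"`, or a file path.
#' @return a [landmark_scheme()].
#' @examples
#' sch <- load_scheme("table3")
#' table(sch$regions)
#' @export
load_scheme <- function(name_or_path) {
  if (name_or_path %in% c("table3", "cranial32")) {
    return(builtin_scheme_32())
  }
  if (!file.exists(name_or_path)) {
    stopf("no built-in scheme or file named '%s'", name_or_path)
  }
  header <- readLines(name_or_path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else
    if (grepl("\t", header, fixed = TRUE)) "\t" else ""
  tab <- utils::read.table(name_or_path, header = TRUE, sep = sep,
                           quote = "\"", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("landmark_id", "name", "region")
  if (!all(need %in% names(tab))) {
    stopf("scheme file must have columns %s", paste(need, collapse = ", "))
  }
  if (anyNA(tab$region) || any(!nzchar(tab$region))) {
    stopf("scheme file '%s': landmark lacking a region", name_or_path)
  }
  extra <- setdiff(names(tab), need)
  variants <- list()
  for (v in extra) {
    flag <- tab[[v]]
    if (all(flag %in% c(0, 1, NA))) {
      variants[[v]] <- as.integer(tab$landmark_id[!is.na(flag) & flag == 1])
    }
  }
  landmark_scheme(
    name = tools::file_path_sans_ext(basename(name_or_path)),
    landmark_ids = tab$landmark_id, regions = tab$region,
    landmark_names = tab$name, variants = variants
  )
}

#' Write a landmark scheme to a delimited text file
#'
#' @param scheme a [landmark_scheme()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  tab <- data.frame(
    landmark_id = scheme$landmark_ids,
    name = unname(scheme$landmark_names %||%
                    paste0("lm", scheme$landmark_ids)),
    region = unname(scheme$regions),
    stringsAsFactors = FALSE
  )
  for (v in names(scheme$variants)) {
    tab[[v]] <- as.integer(tab$landmark_id %in% scheme$variants[[v]])
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Landmark ids belonging to a skull-region query
#'
#' Region queries compose the scheme's per-landmark tags. Landmarks tagged as
#' belonging to both viscerocranial subsets are included in the oral, non-oral
#' viscerocranial, and full viscerocranial queries alike, so the three
#' viscerocranial queries overlap while the neurocranium is disjoint from all
#' of them.
#'
#' @param scheme a [landmark_scheme()].
#' @param region_query one of `"whole_skull"`, `"neurocranium"`,
#'   `"viscerocranium"`, `"viscerocranium_non_oral"`, `"oral"`.
#' @param min_landmarks minimum subset size below which the query is
#'   considered degenerate (a shape needs at least 3 landmarks).
#' @return ordered integer vector of landmark ids.
#' @examples
#' region_subset_ids(load_scheme("table3"), "neurocranium")
#' @export
region_subset_ids <- function(scheme, region_query, min_landmarks = 3L) {
  region_query <- match.arg(region_query, REGION_QUERIES)
  tags <- scheme$regions
  keep <- switch(
    region_query,
    whole_skull = rep(TRUE, length(tags)),
    neurocranium = tags == "neurocranium",
    viscerocranium = tags %in% c("oral", "viscerocranium_both",
                                 "viscerocranium_non_oral"),
    viscerocranium_non_oral = tags %in% c("viscerocranium_both",
                                          "viscerocranium_non_oral"),
    oral = tags %in% c("oral", "viscerocranium_both")
  )
  ids <- scheme$landmark_ids[keep]
  if (length(ids) < min_landmarks) {
    stopf("region '%s' has %d landmark(s) in scheme '%s'; need at least %d",
          region_query, length(ids), scheme$name, min_landmarks)
  }
  ids
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("Landmark scheme '%s': %d landmarks\n", x$name,
              length(x$landmark_ids)))
  print(table(factor(x$regions, levels = REGION_TAGS)))
  if (length(x$variants)) {
    cat("Variants:",
        paste(sprintf("%s (%d)", names(x$variants),
                      lengths(x$variants)), collapse = ", "), "\n")
  }
  invisible(x)
}
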