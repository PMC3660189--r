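test_that("landmark tables round-trip through every format", {
  ds <- tiny_dataset()
  for (fmt in c("csv_long", "csv_wide", "tps3d")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_landmark_table(ds, path, fmt)
    back <- read_landmark_table(path, fmt)
    expect_equal(back$coords, ds$coords, tolerance = 0, info = fmt)
    expect_identical(back$specimens$specimen_id, ds$specimens$specimen_id)
    expect_identical(back$specimens$species, ds$specimens$species)
  }
  # full double precision survives the trip
  set.seed(4)
  noisy <- landmark_dataset(list(matrix(rnorm(12) * pi, 4, 3)), "s1", "sp1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(noisy, path, "csv_long")
  expect_identical(read_landmark_table(path, "csv_long")$coords[, , 1],
                   noisy$coords[, , 1])
})

test_that("inconsistent landmark counts and bad coordinates are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen_id,species,landmark_id,x,y,z",
    paste0("A,SpA,", 1:4, ",0,0,", 1:4),
    paste0("B,SpB,", 1:3, ",1,1,", 1:3)
  ), path)
  expect_error(read_landmark_table(path, "csv_long"), "B")

  tps <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=3", "0 0 0", "1 0 0", "0 oops 0", "ID=badspec"), tps)
  expect_error(read_landmark_table(tps, "tps3d"), "line 4")
})

test_that("metadata validation enforces the closed vocabularies", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,clade,sex,diet,habitat,activity",
    "Didelphis,marsupial,female,omnivore,terrestrial,nocturnal_crepuscular",
    "Didelphis,marsupial,female,omnivore,terrestrial,nocturnal_crepuscular",
    "Mus,placental,male,omnivore,terrestrial,nocturnal_crepuscular"
  ), path)
  md <- read_metadata(path)
  expect_equal(nrow(md), 2L)  # identical duplicate rows merge
  expect_setequal(md$species, c("Didelphis", "Mus"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,clade,diet", "X,placental,granivore"), bad)
  expect_error(read_metadata(bad), "diet")
  writeLines(c("species,clade", "X,reptile"), bad)
  expect_error(read_metadata(bad), "clade")
  # conflicting duplicates
  writeLines(c("species,clade", "X,placental", "X,marsupial"), bad)
  expect_error(read_metadata(bad), "conflict")
})

test_that("built-in scheme has the published region structure", {
  sch <- load_scheme("table3")
  expect_length(sch$landmark_ids, 32L)
  counts <- table(sch$regions)
  expect_equal(unname(counts[["oral"]]), 10L)
  expect_equal(unname(counts[["viscerocranium_both"]]), 8L)
  expect_equal(unname(counts[["viscerocranium_non_oral"]]), 8L)
  expect_equal(unname(counts[["neurocranium"]]), 6L)
  expect_identical(region_subset_ids(sch, "neurocranium"),
                   c(4L, 5L, 20L, 21L, 22L, 23L))
  expect_setequal(region_subset_ids(sch, "oral"),
                  c(1, 8, 9, 24, 27:32, 6, 7, 10:15))
  # viscerocranium = everything but the 6 neurocranial landmarks
  expect_length(region_subset_ids(sch, "viscerocranium"), 26L)
  expect_length(region_subset_ids(sch, "viscerocranium_non_oral"), 16L)
  expect_identical(region_subset_ids(sch, "whole_skull"), 1:32)
})

test_that("region queries partition and exclude the neurocranium from viscerocranial sets", {
  sch <- load_scheme("table3")
  all_tagged <- unlist(lapply(
    c("oral", "viscerocranium_both", "viscerocranium_non_oral",
      "neurocranium"),
    function(t) sch$landmark_ids[sch$regions == t]))
  expect_setequal(all_tagged, sch$landmark_ids)
  neuro <- region_subset_ids(sch, "neurocranium")
  for (q in c("viscerocranium", "viscerocranium_non_oral", "oral")) {
    expect_length(intersect(neuro, region_subset_ids(sch, q)), 0L)
  }
})

test_that("scheme files round-trip and degenerate schemes error", {
  sch <- scheme16()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scheme(sch, path)
  back <- load_scheme(path)
  expect_identical(back$landmark_ids, sch$landmark_ids)
  expect_identical(unname(back$regions), unname(sch$regions))

  # a landmark without region is a schema error
  writeLines(c("landmark_id,name,region", "1,a,oral", "2,b,"), path)
  expect_error(load_scheme(path), "region")

  # all-oral custom scheme is valid, but the neurocranium query degenerates
  tiny <- landmark_scheme("tiny", 1:5, rep("oral", 5))
  expect_error(region_subset_ids(tiny, "neurocranium"), "degenerate|at least")
  expect_length(region_subset_ids(tiny, "oral"), 5L)
})

test_that("subset_dataset restricts, reorders, and rejects unknown ids", {
  ds <- attach_metadata(tiny_dataset(), tiny_metadata())
  expect_equal(subset_dataset(ds, 1:4)$coords, ds$coords)
  sub <- subset_dataset(ds, c(4L, 2L, 1L))
  expect_equal(n_landmarks(sub), 3L)
  expect_equal(sub$coords[1, , 1], ds$coords[4, , 1])
  expect_error(subset_dataset(ds, c(1L, 9L)), "unknown landmark")
  expect_error(subset_dataset(ds, integer(0)), "degenerate")
})

test_that("filter_by_group has intersection semantics and is idempotent", {
  ds <- simulate_study(two_clade_spec(n = 10, seed = 5))
  ds$metadata$diet[ds$metadata$clade == "placental"][1:3] <- "folivore"
  mars <- filter_by_group(ds, "clade", "marsupial")
  expect_true(all(dataset_field(mars, "clade") == "marsupial"))
  expect_equal(n_specimens(filter_by_group(mars, "clade", "marsupial")),
               n_specimens(mars))
  both <- filter_by_group(filter_by_group(ds, "diet", "folivore"),
                          "clade", "placental")
  expect_equal(n_specimens(both), 3L)
  expect_warning(filter_by_group(ds, "activity", "diurnal"), "no specimens")
  expect_error(filter_by_group(ds, "wingspan", "x"), "unknown")
})
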