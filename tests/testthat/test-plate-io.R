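test_that("a valid toy table builds a dataset and validation names each violation", {
  ds <- toy_dataset()
  expect_s3_class(ds, "plate_dataset")
  expect_equal(nrow(ds$plate_map), 4L)
  expect_equal(nrow(ds$features), 3L)

  ft <- toy_features(); pm <- toy_plate_map()
  expect_error(plate_dataset(ft[, setdiff(names(ft), "mz")], pm),
               "missing-column")
  expect_error(plate_dataset(transform(ft, well = c("A01", "ZZ9", "A03")), pm),
               "unknown-well")
  expect_error(plate_dataset(ft, pm[pm$role == "elicitor", ]), "no-control")
  expect_error(plate_dataset(transform(ft, mz = -ft$mz), pm), "positive")
  expect_error(plate_dataset(transform(ft, intensity = -1), pm), ">= 0")
  pm_bad <- pm; pm_bad$elicitor[3] <- "oops"
  expect_error(plate_dataset(ft, pm_bad), "control wells")
  pm_bad2 <- pm; pm_bad2$concentration_uM[1] <- 0
  expect_error(plate_dataset(ft, pm_bad2), "only valid for control")
  ms2_bad <- data.frame(spectrum_id = "s1", precursor_mz = 400,
                        fragment_mz = 402, rel_intensity = 10)
  expect_error(plate_dataset(ft, pm, ms2 = ms2_bad), "precursor")
})

test_that("vehicle-control is accepted as a role synonym", {
  pm <- toy_plate_map()
  pm$role[pm$role == "control"] <- "vehicle-control"
  ds <- plate_dataset(toy_features(), pm)
  expect_equal(sum(ds$plate_map$role == "control"), 2L)
})

test_that("write/read round-trips are the identity on the data model", {
  sim <- small_screen(seed = 31)
  dir1 <- withr::local_tempdir()
  paths <- write_feature_table(sim$dataset, dir1)
  ds2 <- read_feature_table(paths["features"], paths["plate_map"],
                            paths["ms2"])
  dir2 <- withr::local_tempdir()
  paths2 <- write_feature_table(ds2, dir2)
  for (p in intersect(names(paths), names(paths2)))
    expect_identical(readLines(paths[[p]]), readLines(paths2[[p]]))
  expect_equal(sort(ds2$features$intensity),
               sort(sim$dataset$features$intensity), tolerance = 1e-12)
})

test_that("serialization is sorted and stable under input row permutation", {
  ds <- toy_dataset()
  set.seed(9)
  perm <- ds
  perm$features <- perm$features[sample(nrow(perm$features)), ]
  perm$plate_map <- perm$plate_map[sample(nrow(perm$plate_map)), ]
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_feature_table(ds, d1)
  p2 <- write_feature_table(perm, d2)
  expect_identical(readLines(p1[["features"]]), readLines(p2[["features"]]))
  expect_identical(readLines(p1[["plate_map"]]), readLines(p2[["plate_map"]]))
})

test_that("an empty feature table writes a header-only file", {
  pm <- toy_plate_map()
  ds <- plate_dataset(toy_features()[0, ], pm)
  d <- withr::local_tempdir()
  p <- write_feature_table(ds, d)
  expect_length(readLines(p[["features"]]), 1L)
})

test_that("mzML import reduces traces to apex features", {
  pm <- data.frame(well = c("A01", "A02"), role = c("elicitor", "control"),
                   elicitor = c("drugX", NA), concentration_uM = c(16, 0),
                   replicate = 1L, stringsAsFactors = FALSE)
  # one Gaussian trace -> one feature at its apex
  scans <- lapply(1:7, function(i)
    list(rt_sec = 6 * i, mz = 417.2931, intensity = 1e5 * exp(-(i - 4)^2 / 2)))
  f1 <- withr::local_tempfile(fileext = ".mzML")
  write_mini_mzml(f1, scans)
  # empty file -> no features
  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_mini_mzml(f2, list())
  ds <- import_mzml(c(A01 = f1, A02 = f2), pm)
  expect_equal(nrow(ds$features), 1L)
  expect_equal(ds$features$mz, 417.2931, tolerance = 1e-6)
  expect_equal(ds$features$rt, 24 / 60, tolerance = 1e-9)
  expect_equal(ds$features$intensity, 1e5)

  # two traces 1 Da apart -> two features
  scans2 <- lapply(1:5, function(i)
    list(rt_sec = 6 * i, mz = c(300.10, 301.10),
         intensity = c(2e4, 3e4) * exp(-(i - 3)^2 / 2)))
  f3 <- withr::local_tempfile(fileext = ".mzML")
  write_mini_mzml(f3, scans2)
  ds2 <- import_mzml(c(A01 = f3, A02 = f2), pm)
  expect_equal(nrow(ds2$features), 2L)
})

test_that("profile-mode mzML is rejected with an explicit error", {
  pm <- data.frame(well = "A01", role = "control", elicitor = NA,
                   concentration_uM = 0, replicate = 1L,
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mini_mzml(f, list(list(rt_sec = 6, mz = 300.1, intensity = 100)),
                  centroided = FALSE)
  expect_error(import_mzml(c(A01 = f), pm), "unsupported-mode")
})
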