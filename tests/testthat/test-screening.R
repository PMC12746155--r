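make_two_well_dataset <- function(mz2 = 417.2931 * (1 + 2e-6), rt2 = 7.2) {
  pm <- data.frame(well = c("A01", "A02"), role = c("elicitor", "control"),
                   elicitor = c("drugX", NA), concentration_uM = c(16, 0),
                   replicate = 1L, stringsAsFactors = FALSE)
  ft <- data.frame(well = c("A01", "A02"), mz = c(417.2931, mz2),
                   rt = c(7.2, rt2), intensity = c(1000, 900),
                   stringsAsFactors = FALSE)
  plate_dataset(ft, pm)
}

test_that("alignment merges within tolerance and splits outside it", {
  af <- align_features(make_two_well_dataset(), mz_tol_ppm = 10, rt_tol = 0.2)
  expect_equal(nrow(af$features), 1L)
  expect_equal(af$features$n_members, 2L)
  # same m/z but RT three tolerances apart stays split
  af2 <- align_features(make_two_well_dataset(rt2 = 7.2 + 0.6),
                        mz_tol_ppm = 10, rt_tol = 0.2)
  expect_equal(nrow(af2$features), 2L)
  # every input feature assigned exactly once
  expect_true(all(af2$assignment %in% seq_len(2)))
})

test_that("aligning a dataset with itself doubles intensities, not features", {
  ds <- toy_dataset()
  doubled <- plate_dataset(rbind(ds$features, ds$features), ds$plate_map)
  af1 <- align_features(ds)
  af2 <- align_features(doubled)
  expect_equal(nrow(af2$features), nrow(af1$features))
  expect_equal(af2$intensity, 2 * af1$intensity)
})

test_that("alignment is invariant under well/row permutation", {
  sim <- small_screen(seed = 55)
  ds <- sim$dataset
  set.seed(1)
  perm <- plate_dataset(ds$features[sample(nrow(ds$features)), ],
                        ds$plate_map[sample(nrow(ds$plate_map)), ],
                        ms2 = ds$ms2)
  m1 <- differential_map(align_features(ds))
  m2 <- differential_map(align_features(perm))
  o1 <- order(m1$features$mz); o2 <- order(m2$features$mz)
  expect_equal(m1$features$mz[o1], m2$features$mz[o2], tolerance = 1e-9)
  expect_equal(m1$dI[o1, m1$elicitors], m2$dI[o2, m1$elicitors],
               tolerance = 1e-9)
})

test_that("differential map arithmetic is definitional", {
  pm <- data.frame(well = c("E1", "C1", "C2"),
                   role = c("elicitor", "control", "control"),
                   elicitor = c("drugX", NA, NA),
                   concentration_uM = c(16, 0, 0), replicate = 1L,
                   stringsAsFactors = FALSE)
  ft <- data.frame(well = c("E1", "C1", "C2"), mz = 400.2, rt = 5,
                   intensity = c(5000, 1000, 1000), stringsAsFactors = FALSE)
  map <- differential_map(align_features(plate_dataset(ft, pm)),
                          pseudo_frac = 0)
  expect_equal(unname(map$dI[1, "drugX"]), 4000)
  expect_equal(unname(map$fold[1, "drugX"]), 5)

  # equal intensities -> dI 0, fold 1
  ft2 <- transform(ft, intensity = 1000)
  map2 <- differential_map(align_features(plate_dataset(ft2, pm)),
                           pseudo_frac = 0)
  expect_equal(unname(map2$dI[1, "drugX"]), 0)
  expect_equal(unname(map2$fold[1, "drugX"]), 1)

  # control-absent ion gets a finite fold via the pseudo-count
  ft3 <- data.frame(well = c("E1", "E1", "C1", "C2"),
                    mz = c(400.2, 500.3, 400.2, 400.2), rt = 5,
                    intensity = c(5000, 8000, 1000, 1000),
                    stringsAsFactors = FALSE)
  map3 <- differential_map(align_features(plate_dataset(ft3, pm)))
  absent <- which.min(abs(map3$features$mz - 500.3))
  expect_true(is.finite(map3$fold[absent, "drugX"]))
  expect_gt(map3$fold[absent, "drugX"], 1)
})

test_that("a dataset without control wells is a hard error for the map", {
  pm <- data.frame(well = "E1", role = "elicitor", elicitor = "drugX",
                   concentration_uM = 16, replicate = 1L,
                   stringsAsFactors = FALSE)
  ft <- data.frame(well = "E1", mz = 400.2, rt = 5, intensity = 100,
                   stringsAsFactors = FALSE)
  ds <- plate_dataset(ft, pm, require_control = FALSE)
  expect_error(differential_map(align_features(ds)), "no-control")
})

test_that("scaling all intensities scales dI and leaves fold unchanged", {
  sim <- small_screen(seed = 77)
  ds <- sim$dataset
  k <- 3.7
  scaled <- plate_dataset(transform(ds$features, intensity = intensity * k),
                          ds$plate_map, ms2 = ds$ms2)
  m1 <- differential_map(align_features(ds))
  m2 <- differential_map(align_features(scaled))
  o1 <- order(m1$features$mz); o2 <- order(m2$features$mz)
  expect_equal(m2$dI[o2, m1$elicitors], k * m1$dI[o1, m1$elicitors],
               tolerance = 1e-9)
  expect_equal(m2$fold[o2, m1$elicitors], m1$fold[o1, m1$elicitors],
               tolerance = 1e-9)
})

test_that("slices rank elicitors by induced intensity with fold annotated", {
  fam <- screen_family(mz = 520.31, rt = 6.5, elicitors = c("drug_005",
                                                            "drug_009"),
                       fold = c(5, 3))
  cfg <- screen_config(n_elicitors = 20, n_controls = 6, n_baseline = 40,
                       families = list(fam))
  sim <- simulate_screen_plate(cfg, seed = 13)
  map <- differential_map(align_features(sim$dataset))
  sl <- extract_slice(map, 520.31)
  expect_identical(sl$elicitor[1:2], c("drug_005", "drug_009"))
  expect_true(all(diff(sl$dI) <= 0))
  # no-match selector returns an empty, message-bearing result
  expect_message(empty <- extract_slice(map, 999.99), "no aligned feature")
  expect_equal(nrow(empty), 0L)
})

test_that("hit calling respects thresholds and the trivial fold-1 threshold", {
  sim <- small_screen(seed = 41)
  map <- differential_map(align_features(sim$dataset))
  hits <- call_hits(map, min_fold = 3, fdr = 0.05)
  expect_gte(nrow(hits), 3L)          # the three injected members
  expect_true(all(hits$fold >= 3))
  expect_true(all(hits$q <= 0.05))
  # fold threshold 1: every feature is a hit
  all_hits <- call_hits(map, min_fold = 1)
  expect_equal(nrow(all_hits), nrow(map$features))
  expect_error(call_hits(map, min_fold = 0), "positive")
  expect_error(call_hits(map, fdr = 1.5), "fdr")
})

test_that("EIC queries return matching wells and grow monotonically with tolerance", {
  fix <- doreamide_fixture()
  pm <- data.frame(well = "A01", role = "control", elicitor = NA,
                   concentration_uM = 0, replicate = 1L,
                   stringsAsFactors = FALSE)
  ft <- data.frame(well = "A01", mz = fix$features$mz, rt = fix$features$rt,
                   intensity = fix$features$intensity,
                   stringsAsFactors = FALSE)
  ds <- plate_dataset(ft, pm)
  tr <- eic(ds, 417.2931, ppm = 10)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mz, 417.2931)
  expect_equal(nrow(eic(ds, 200.0, ppm = 10)), 0L)
  widths <- c(5, 50, 5000, 5e5)
  counts <- vapply(widths, function(w) nrow(eic(ds, 417.2931, ppm = w)),
                   numeric(1))
  expect_true(!is.unsorted(counts))
  expect_error(eic(ds, 417.2931, ppm = -1), "positive")
})
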