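test_that("the reference ion fixture yields one 5-rung, 6-member series", {
  fix <- doreamide_fixture()
  series <- detect_homolog_series(fix$features)
  expect_length(series, 1L)
  s <- series[[1]]
  expect_length(s$rung_mass, 5L)
  expect_equal(s$n_members, 6L)
  # the two 431.309x ions share one rung and are RT-resolved isomers
  rung431 <- unique(s$rungs$rung[abs(s$rungs$mz - 431.3091) < 0.001])
  expect_length(rung431, 1L)
  expect_true(s$rt_resolved_isomers[rung431])
  # every consecutive spacing is within tolerance of one CH2
  expect_true(all(abs(s$spacings - 14.01565) <= 0.01))
})

test_that("ladder detection finds constructed chains and rejects off-spacing", {
  ft <- data.frame(mz = c(100.0, 114.0157, 128.0313), rt = c(1, 2, 3))
  series <- detect_homolog_series(ft)
  expect_length(series, 1L)
  expect_length(series[[1]]$rung_mass, 3L)

  off <- data.frame(mz = c(100.0, 113.9, 127.8), rt = c(1, 2, 3))
  expect_length(detect_homolog_series(off), 0L)
  expect_length(detect_homolog_series(off[1, , drop = FALSE]), 0L)
})

test_that("ladder recall is complete on injected synthetic ladders", {
  set.seed(77)
  for (rep in 1:5) {
    base <- runif(1, 300, 500)
    n_rungs <- sample(3:6, 1)
    ladder <- base + 14.01565 * (0:(n_rungs - 1))
    decoys <- runif(8, 600, 900)       # far from the ladder
    ft <- data.frame(mz = c(ladder, decoys),
                     rt = runif(n_rungs + 8, 1, 10))
    series <- detect_homolog_series(ft)
    found <- FALSE
    for (s in series)
      if (length(s$rung_mass) == n_rungs &&
          all(abs(s$rung_mass - ladder) < 1e-6)) found <- TRUE
    expect_true(found)
  }
})

test_that("fragment grouping selects members by diagnostic fragments", {
  fix <- doreamide_fixture()
  diag <- c(163.0726, 145.0618, 106.0506)
  fam <- group_by_fragments(fix$ms2, diag)
  expect_equal(nrow(fam$members), 6L)   # the dipeptide lipids only
  expect_false(any(grepl("acyl", fam$members$spectrum_id)))
  expect_true(all(fam$members$n_matched == 3L))
  # requiring no matches admits every spectrum
  fam0 <- group_by_fragments(fix$ms2, diag, min_matches = 0)
  expect_equal(nrow(fam0$members), 8L)
  expect_error(group_by_fragments(fix$ms2, diag, min_matches = 4),
               "cannot exceed")
})

test_that("fragment grouping is monotone in tolerance and permutation-invariant", {
  fix <- doreamide_fixture()
  diag <- c(163.0726, 145.0618, 106.0506)
  sizes <- vapply(c(1, 5, 15, 50), function(tol)
    nrow(group_by_fragments(fix$ms2, diag, tol_ppm = tol)$members),
    numeric(1))
  expect_true(!is.unsorted(sizes))
  set.seed(3)
  shuffled <- fix$ms2[sample(nrow(fix$ms2)), ]
  f1 <- group_by_fragments(fix$ms2, diag)
  f2 <- group_by_fragments(shuffled, diag)
  expect_setequal(f1$members$spectrum_id, f2$members$spectrum_id)
})

test_that("fragment annotation assigns the printed ions to dipeptide formulas", {
  fix <- doreamide_fixture()
  sp <- fix$ms2[fix$ms2$spectrum_id == "dore_2", ]
  cand <- c("C5H10N2O4", "C5H8N2O3", "C3H7NO3")
  ann <- annotate_fragments(data.frame(mz = sp$fragment_mz), cand)
  expect_equal(nrow(ann$matched), 3L)
  expect_equal(
    ann$matched$formula[order(ann$matched$observed_mz, decreasing = TRUE)],
    cand)
  expect_true(all(abs(ann$matched$ppm) <= 15))
  # empty candidate list matches nothing
  none <- annotate_fragments(data.frame(mz = sp$fragment_mz), character(0))
  expect_equal(nrow(none$matched), 0L)
  # the observed-vs-theoretical gaps (~7 ppm) exceed a 1 ppm tolerance
  tight <- annotate_fragments(data.frame(mz = sp$fragment_mz), cand,
                              tol_ppm = 1)
  expect_equal(nrow(tight$matched), 0L)
  expect_length(tight$unmatched, 3L)
})

test_that("RT-resolved same-mass pairing is selective", {
  fix <- doreamide_fixture()
  acyl <- fix$features[fix$features$group == "acyladenosine", ]
  pairs <- pair_isomers(acyl)
  expect_equal(nrow(pairs), 1L)
  expect_equal(round(pairs$mz1), 352)
  # features 1 Da apart never pair
  expect_equal(nrow(pair_isomers(data.frame(mz = c(352.16, 353.16),
                                            rt = c(3, 4)))), 0L)
  # co-eluting duplicates (RT gap below threshold) never pair
  expect_equal(nrow(pair_isomers(data.frame(mz = c(352.1611, 352.1612),
                                            rt = c(3.00, 3.05)))), 0L)
  # greedy one-pair-per-feature
  trip <- data.frame(mz = rep(352.1611, 3), rt = c(1, 2, 4))
  expect_equal(nrow(pair_isomers(trip)), 1L)
})

test_that("acyl carbon accounting spans 15-19 carbons on the reference ladder", {
  fix <- doreamide_fixture()
  s <- detect_homolog_series(fix$features)[[1]]
  aa <- infer_acyl_carbons(s, 417.2931, "C21H40N2O6")
  expect_equal(sort(aa$acyl_carbons), c(15, 16, 17, 17, 18, 19))
  expect_true(all(aa$branch == "unknown"))
  # sum rule: member formula carbons - core carbons = acyl carbons
  for (i in seq_len(nrow(aa))) {
    f <- parse_formula(aa$formula[i])
    expect_identical(unname(f["C"]) - 5, aa$acyl_carbons[i])
  }
  # inconsistent anchor formula errors with the ppm gap named
  expect_error(infer_acyl_carbons(s, 417.2931, "C21H38N2O6"), "ppm gap")
  expect_error(infer_acyl_carbons(s, 352.1611, "C15H21N5O5"),
               "not a member")
})

test_that("a single-rung series resolves to the anchor's own acyl count", {
  s <- structure(list(
    rungs = data.frame(mz = 417.2931, rt = 7.2, rung = 1L),
    rung_mass = 417.2931, spacings = numeric(0), n_members = 1L,
    rt_resolved_isomers = FALSE, repeat_unit = 14.01565, mass_tol = 0.01),
    class = "homolog_series")
  aa <- infer_acyl_carbons(s, 417.2931, "C21H40N2O6")
  expect_identical(aa$acyl_carbons, 16)
})
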