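# Metabolite-family inference: CH2 homolog ladders, diagnostic-fragment
# grouping, RT-resolved same-mass pairing, and acyl-chain carbon accounting.

#' Detect homolog series (CH2 ladders)
#'
#' Features are first collapsed into rungs (sets of features whose m/z agree
#' within `mass_tol`; same-mass features resolved in retention time are
#' isomers sharing a rung), then rungs whose mass difference matches the
#' repeat unit within `mass_tol` are chained by single linkage into maximal
#' series. A mass ladder spaced by ~14.01565 Da is the signature of a
#' compound family differing in CH2 units of the acyl chain.
#'
#' @param features Data frame with columns `mz` and `rt` (and anything else,
#'   carried through).
#' @param repeat_unit Ladder spacing in Da (default CH2 = 14.01565).
#' @param mass_tol Spacing and rung tolerance in Da (default 0.01).
#' @param rt_isomer_gap Minimum RT separation (minutes) for two same-mass
#'   rung members to be reported as resolved isomers (default 0.3).
#' @return A list of `"homolog_series"` objects ordered by minimum rung
#'   mass. Each has `rungs` (data frame of members with a `rung` index),
#'   `rung_mass` (mean m/z per rung, ascending), `spacings` (consecutive
#'   differences), and `n_members`. Series need at least two rungs;
#'   rung-only singletons are not reported.
#' @examples
#' fix <- doreamide_fixture()
#' detect_homolog_series(fix$features)
#' @export
detect_homolog_series <- function(features, repeat_unit = 14.01565,
                                  mass_tol = 0.01, rt_isomer_gap = 0.3) {
  if (!is.data.frame(features) || !all(c("mz", "rt") %in% names(features)))
    stop("`features` must be a data frame with columns mz and rt")
  if (nrow(features) < 2) return(list())
  ord <- order(features$mz)
  ft <- features[ord, , drop = FALSE]
  # rungs: chain-break grouping on sorted m/z
  rung <- cumsum(c(1, diff(ft$mz) > mass_tol))
  rung_mass <- as.numeric(tapply(ft$mz, rung, mean))
  nr <- length(rung_mass)
  # single-linkage chains over the repeat-unit graph on rungs
  comp <- seq_len(nr)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      if (abs(rung_mass[j] - rung_mass[i] - repeat_unit) <= mass_tol) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
  }
  out <- list()
  for (cc in unique(comp)) {
    rungs_in <- which(comp == cc)
    if (length(rungs_in) < 2) next
    rungs_in <- rungs_in[order(rung_mass[rungs_in])]
    members <- ft[rung %in% rungs_in, , drop = FALSE]
    members$rung <- match(rung[rung %in% rungs_in], rungs_in)
    rownames(members) <- NULL
    rm_mass <- rung_mass[rungs_in]
    iso <- vapply(seq_along(rungs_in), function(k) {
      rts <- members$rt[members$rung == k]
      length(rts) > 1 && min(dist(rts)) >= rt_isomer_gap
    }, logical(1))
    out[[length(out) + 1L]] <- structure(
      list(rungs = members, rung_mass = rm_mass,
           spacings = diff(rm_mass), n_members = nrow(members),
           rt_resolved_isomers = iso, repeat_unit = repeat_unit,
           mass_tol = mass_tol),
      class = "homolog_series")
  }
  out[order(vapply(out, function(s) s$rung_mass[1], numeric(1)))]
}

#' @export
print.homolog_series <- function(x, ...) {
  cat(sprintf(
    "homolog_series: %d rungs, %d members, masses %.4f..%.4f, spacings %s Da\n",
    length(x$rung_mass), x$n_members, min(x$rung_mass), max(x$rung_mass),
    paste(sprintf("%.4f", x$spacings), collapse = "/")))
  invisible(x)
}

# coerce ms2 input (long df, or list of data frames with mz/intensity)
.ms2_as_list <- function(ms2) {
  if (is.data.frame(ms2)) {
    .require_columns(ms2, c("spectrum_id", "precursor_mz", "fragment_mz"),
                     "ms2 table")
    split_ids <- unique(ms2$spectrum_id)
    lapply(setNames(split_ids, split_ids), function(id) {
      s <- ms2[ms2$spectrum_id == id, , drop = FALSE]
      list(precursor_mz = s$precursor_mz[1],
           fragments = data.frame(mz = s$fragment_mz,
                                  intensity = if ("rel_intensity" %in% names(s))
                                    s$rel_intensity else rep(1, nrow(s))))
    })
  } else if (is.list(ms2)) ms2
  else stop("`ms2` must be a long data frame or a list of spectra")
}

#' Group precursors into a compound family by diagnostic fragments
#'
#' Family members are precursors whose MS/MS spectra contain at least
#' `min_matches` of the diagnostic target fragments within the fragment
#' tolerance — the computational form of grouping metabolites by shared
#' substructure-reporting product ions.
#'
#' @param ms2 Spectra: a long data frame (`spectrum_id, precursor_mz,
#'   fragment_mz[, rel_intensity]`) or a named list of
#'   `list(precursor_mz, fragments = data.frame(mz, intensity))`.
#' @param targets Diagnostic fragment m/z values.
#' @param tol_ppm Fragment tolerance in ppm (default 15).
#' @param min_matches Minimum number of distinct targets a member must match
#'   (default: all of them).
#' @return An object of class `"compound_family"`: `members` (data frame
#'   `spectrum_id, precursor_mz, n_matched`) and `matches` (per member and
#'   target, the observed fragment m/z and its ppm error).
#' @export
group_by_fragments <- function(ms2, targets, tol_ppm = 15,
                               min_matches = length(targets)) {
  spectra <- .ms2_as_list(ms2)
  if (!length(spectra)) stop("`ms2` must contain at least one spectrum")
  if (min_matches > length(targets))
    stop("`min_matches` cannot exceed the number of targets")
  match_rows <- list()
  members <- list()
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    frag <- sp$fragments$mz
    matched <- 0L
    for (t in targets) {
      d <- abs(frag - t)
      ok <- which(d <= t * tol_ppm * 1e-6)
      if (length(ok)) {
        best <- ok[which.min(d[ok])]
        matched <- matched + 1L
        match_rows[[length(match_rows) + 1L]] <- data.frame(
          spectrum_id = id, precursor_mz = sp$precursor_mz,
          target_mz = t, observed_mz = frag[best],
          ppm = ppm_error(frag[best], t), stringsAsFactors = FALSE)
      }
    }
    if (matched >= min_matches)
      members[[length(members) + 1L]] <- data.frame(
        spectrum_id = id, precursor_mz = sp$precursor_mz,
        n_matched = matched, stringsAsFactors = FALSE)
  }
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(spectrum_id = character(0), precursor_mz = numeric(0),
               n_matched = integer(0))
  members <- members[order(members$precursor_mz), , drop = FALSE]
  rownames(members) <- NULL
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(spectrum_id = character(0), precursor_mz = numeric(0),
               target_mz = numeric(0), observed_mz = numeric(0),
               ppm = numeric(0))
  matches <- matches[matches$spectrum_id %in% members$spectrum_id, ,
                     drop = FALSE]
  rownames(matches) <- NULL
  structure(list(members = members, matches = matches, targets = targets,
                 tol_ppm = tol_ppm, min_matches = min_matches),
            class = "compound_family")
}

#' @export
print.compound_family <- function(x, ...) {
  cat(sprintf(
    "compound_family: %d members matching >= %d of %d diagnostic fragments (%g ppm)\n",
    nrow(x$members), x$min_matches, length(x$targets), x$tol_ppm))
  invisible(x)
}

#' Annotate MS/MS fragments with candidate formulas
#'
#' Matches each observed fragment to at most one candidate formula (as the
#' given adduct species; closest ppm wins) within the fragment tolerance.
#'
#' @param spectrum Data frame with column `mz` (observed fragment m/z;
#'   `fragment_mz` is accepted) and optionally `intensity`.
#' @param candidates Character vector of neutral fragment formulas.
#' @param a Adduct applied to the candidates (default `"[M+H]+"`).
#' @param tol_ppm Fragment tolerance in ppm (default 15).
#' @return A list: `matched` (data frame
#'   `observed_mz, formula, theoretical_mz, ppm`) and `unmatched` (observed
#'   m/z with no candidate in tolerance).
#' @examples
#' fix <- doreamide_fixture()
#' sp <- fix$ms2[fix$ms2$spectrum_id == "dore_2", ]
#' annotate_fragments(data.frame(mz = sp$fragment_mz),
#'                    c("C5H10N2O4", "C5H8N2O3", "C3H7NO3"))
#' @export
annotate_fragments <- function(spectrum, candidates, a = "[M+H]+",
                               tol_ppm = 15) {
  if (!length(candidates))
    return(list(matched = data.frame(observed_mz = numeric(0),
                                     formula = character(0),
                                     theoretical_mz = numeric(0),
                                     ppm = numeric(0)),
                unmatched = spectrum$mz))
  if (!"mz" %in% names(spectrum) && "fragment_mz" %in% names(spectrum))
    spectrum$mz <- spectrum$fragment_mz
  if (!"mz" %in% names(spectrum))
    stop("`spectrum` must have an mz (or fragment_mz) column")
  theo <- vapply(candidates, adduct_mz, numeric(1), a = a)
  rows <- list(); unmatched <- numeric(0)
  for (obs in spectrum$mz) {
    ppm <- ppm_error(obs, theo)
    ok <- which(abs(ppm) <= tol_ppm)
    if (!length(ok)) { unmatched <- c(unmatched, obs); next }
    best <- ok[which.min(abs(ppm[ok]))]
    rows[[length(rows) + 1L]] <- data.frame(
      observed_mz = obs, formula = candidates[best],
      theoretical_mz = theo[best], ppm = ppm[best],
      stringsAsFactors = FALSE)
  }
  matched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed_mz = numeric(0), formula = character(0),
               theoretical_mz = numeric(0), ppm = numeric(0))
  rownames(matched) <- NULL
  list(matched = matched, unmatched = unmatched)
}

#' Pair same-mass features resolved in retention time
#'
#' Finds pairs of features with (near-)identical m/z but disparate retention
#' times — isomers, or slowly interconverting conformers; the two cases are
#' not distinguishable from LC-MS alone, so pairs are reported neutrally as
#' RT-resolved same-mass pairs. Pairing is greedy by RT proximity and each
#' feature joins at most one pair.
#'
#' @param features Data frame with columns `mz` and `rt`.
#' @param mass_tol Maximum |delta m/z| in Da (default 0.005).
#' @param min_rt_gap Minimum RT separation in minutes (default 0.3).
#' @return Data frame `mz1, rt1, mz2, rt2, d_mz, d_rt`, one row per pair.
#' @export
pair_isomers <- function(features, mass_tol = 0.005, min_rt_gap = 0.3) {
  if (!is.data.frame(features) || !all(c("mz", "rt") %in% names(features)))
    stop("`features` must be a data frame with columns mz and rt")
  n <- nrow(features)
  empty <- data.frame(mz1 = numeric(0), rt1 = numeric(0), mz2 = numeric(0),
                      rt2 = numeric(0), d_mz = numeric(0), d_rt = numeric(0))
  if (n < 2) return(empty)
  cand <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dmz <- abs(features$mz[j] - features$mz[i])
    drt <- abs(features$rt[j] - features$rt[i])
    if (dmz <= mass_tol && drt >= min_rt_gap)
      cand[[length(cand) + 1L]] <- c(i, j, dmz, drt)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 4], cand[, 3]), , drop = FALSE]
  used <- logical(n); rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[c(i, j)] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      mz1 = features$mz[i], rt1 = features$rt[i],
      mz2 = features$mz[j], rt2 = features$rt[j],
      d_mz = cand[r, 3], d_rt = cand[r, 4])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Acyl-chain carbon accounting along a homolog ladder
#'
#' Anchors one rung of a homolog series to an assigned molecular formula and
#' propagates CH2 increments along the ladder: the rung at offset k from the
#' anchor gets formula `anchor + k * CH2`, and each member's acyl carbon
#' count is its formula's carbon count minus the carbons of the conserved
#' dipeptide core (Ser-Gly, C5H10N2O4, 5 carbons, by default). Branch type
#' (iso/anteiso) is never inferred from mass — mass-identical branch isomers
#' make that unsound — so the branch slot stays `"unknown"` unless labeling
#' evidence or user annotation fills it.
#'
#' @param series A `"homolog_series"` from [detect_homolog_series()].
#' @param anchor_mz Observed m/z of the anchor ion (must lie in the series).
#' @param anchor_formula Neutral formula assigned to the anchor ion.
#' @param core_formula Neutral formula of the conserved core
#'   (default `"C5H10N2O4"`, the Ser-Gly dipeptide).
#' @param a Adduct linking neutral formulas to observed ions
#'   (default `"[M+H]+"`).
#' @param tol_ppm MS1 tolerance for the anchor-consistency check
#'   (default 10).
#' @return A data frame of class `"acyl_assignment"`: one row per member
#'   with `rung, mz, rt, formula, acyl_carbons, branch`.
#' @examples
#' fix <- doreamide_fixture()
#' s <- detect_homolog_series(fix$features)[[1]]
#' infer_acyl_carbons(s, 417.2931, "C21H40N2O6")
#' @export
infer_acyl_carbons <- function(series, anchor_mz, anchor_formula,
                               core_formula = "C5H10N2O4", a = "[M+H]+",
                               tol_ppm = 10) {
  if (!inherits(series, "homolog_series"))
    stop("`series` must be a homolog_series")
  af <- as_formula(anchor_formula)
  cf <- as_formula(core_formula)
  theo <- adduct_mz(af, a)
  gap <- ppm_error(anchor_mz, theo)
  if (abs(gap) > tol_ppm)
    stop(sprintf(
      "anchor formula %s is inconsistent with anchor m/z %.4f: %.1f ppm gap",
      format_formula(af), anchor_mz, gap))
  anchor_rung <- which(vapply(seq_along(series$rung_mass), function(k)
    any(abs(series$rungs$mz[series$rungs$rung == k] - anchor_mz) <=
          series$mass_tol), logical(1)))
  if (!length(anchor_rung))
    stop("anchor m/z ", anchor_mz, " is not a member of the series")
  anchor_rung <- anchor_rung[1]
  cC <- function(f) if ("C" %in% names(f)) unname(f["C"]) else 0
  core_c <- cC(cf)
  members <- series$rungs
  rows <- lapply(seq_len(nrow(members)), function(i) {
    k <- members$rung[i] - anchor_rung
    f <- af
    f["C"] <- cC(af) + k
    f["H"] <- unname(af["H"]) + 2 * k
    if (f["C"] < core_c || f["H"] < 0)
      stop("CH2 offset ", k, " leads outside a chemically valid formula")
    data.frame(rung = members$rung[i], mz = members$mz[i], rt = members$rt[i],
               formula = format_formula(f),
               acyl_carbons = unname(f["C"]) - core_c,
               branch = "unknown", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rung, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("acyl_assignment", "data.frame")
  out
}
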