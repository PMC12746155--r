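# Seeded generators that emulate the screen's data-generating process:
# a log-normal baseline metabolome observed in every well, multiplicative
# log-normal technical noise, and injected elicitor-responsive metabolite
# families whose members are amplified by a known fold in responsive wells.

.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Describe one injected metabolite family
#'
#' A family is a CH2-laddered set of member ions sharing diagnostic MS/MS
#' fragments, induced by one or more responsive elicitors at known folds.
#'
#' @param mz Sorted member m/z values (the CH2 ladder).
#' @param elicitors Responsive elicitor ids.
#' @param fold True fold induction per responsive elicitor (recycled; all
#'   >= 1).
#' @param fragments Diagnostic fragment m/z values shared by the members.
#' @param rt Member retention times in minutes (defaults to an evenly spaced
#'   late-eluting window).
#' @param base_intensity Member baseline (uninduced) intensity; defaults to
#'   the plate baseline scale.
#' @return A list of class `"screen_family"`.
#' @export
screen_family <- function(mz, elicitors, fold, fragments = numeric(0),
                          rt = NULL, base_intensity = NULL) {
  if (is.unsorted(mz)) stop("family member m/z must be sorted ascending")
  fold <- rep_len(fold, length(elicitors))
  if (any(fold < 1)) stop("fold inductions must be >= 1")
  if (is.null(rt)) rt <- seq(7, 7 + 0.4 * (length(mz) - 1), by = 0.4)
  if (length(rt) != length(mz)) stop("`rt` must match `mz` in length")
  structure(list(mz = mz, rt = rt, fragments = fragments,
                 elicitors = as.character(elicitors), fold = fold,
                 base_intensity = base_intensity),
            class = "screen_family")
}

#' Configure a synthetic elicitor screen
#'
#' Defaults emulate the screening scale of the study system: a 400-member
#' drug library with vehicle-control wells, a log-normal baseline secondary
#' metabolome, and ~20% multiplicative technical noise.
#'
#' @param n_elicitors Number of library elicitors (default 400).
#' @param n_controls Number of vehicle-control wells (default 8).
#' @param n_replicates Wells per elicitor (default 1, as in a single-pass
#'   library screen).
#' @param n_baseline Baseline features per well (default 200).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   feature intensities (defaults `log(1e4)` and 1).
#' @param noise_cv Technical coefficient of variation of multiplicative
#'   intensity noise (default 0.2).
#' @param families List of [screen_family()] objects to inject (default none).
#' @param concentration_uM Screening concentration for elicitor wells
#'   (default 16, a typical sub-MIC tetracycline dose in this system).
#' @param mz_range,rt_range Ranges from which baseline m/z (Da) and retention
#'   times (minutes) are drawn.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(n_elicitors = 400, n_controls = 8,
                          n_replicates = 1, n_baseline = 200,
                          baseline_meanlog = log(1e4), baseline_sdlog = 1,
                          noise_cv = 0.2, families = list(),
                          concentration_uM = 16,
                          mz_range = c(150, 800), rt_range = c(0.5, 12)) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_elicitors < 1 || n_controls < 1)
    stop("need at least one elicitor and one control well")
  for (f in families)
    if (!inherits(f, "screen_family"))
      stop("`families` must be a list of screen_family objects")
  structure(list(n_elicitors = n_elicitors, n_controls = n_controls,
                 n_replicates = n_replicates, n_baseline = n_baseline,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, noise_cv = noise_cv,
                 families = families, concentration_uM = concentration_uM,
                 mz_range = mz_range, rt_range = rt_range),
            class = "screen_config")
}

#' Example doreamide-like injected families
#'
#' Builds `n` CH2-laddered families (3 members each, spaced 14.01565 Da)
#' with three shared diagnostic fragments, one responsive elicitor per
#' family, and fold inductions in the 5-12x range observed for elicited
#' dipeptide lipids.
#'
#' @param n Number of families (default 5).
#' @param fold Fold induction per family (recycled).
#' @param elicitors Responsive elicitor id per family; defaults to
#'   `drug_010, drug_020, ...`.
#' @return A list of [screen_family()] objects.
#' @export
example_families <- function(n = 5, fold = c(5, 6, 8, 10, 12),
                             elicitors = sprintf("drug_%03d", 10 * seq_len(n))) {
  fold <- rep_len(fold, n)
  lapply(seq_len(n), function(i) {
    base <- 380 + 60 * i + 0.123 * i       # keep families well separated
    screen_family(
      mz = base + 14.01565 * (0:2),
      rt = 6 + 0.5 * i + 0.35 * (0:2),
      fragments = c(120.0813, 138.0550, 163.0726) + 0.9 * i,
      elicitors = elicitors[i], fold = fold[i])
  })
}

#' Simulate one elicitor screen plate with ground truth
#'
#' Generates a [plate_dataset()] in which every baseline feature and every
#' injected family member is observed in every well under multiplicative
#' log-normal noise; family members are additionally amplified by their true
#' fold in the wells of their responsive elicitors. Identical seeds give
#' identical datasets. Baseline m/z values that collide with an injected
#' member within `collision_tol` Da are redrawn (a warning is raised if a
#' collision survives redrawing).
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @param collision_tol Baseline-vs-member m/z collision tolerance in Da
#'   (default 0.02).
#' @return A list of class `"screen_simulation"` with elements `dataset`
#'   (the plate) and `truth` (data frame: one row per injected member x
#'   responsive elicitor, with the true fold).
#' @export
simulate_screen_plate <- function(config, seed, collision_tol = 0.02) {
  stopifnot(inherits(config, "screen_config"))
  set.seed(seed)
  nw_e <- config$n_elicitors * config$n_replicates
  elic_ids <- sprintf("drug_%03d", seq_len(config$n_elicitors))
  pm <- rbind(
    data.frame(well = sprintf("E%04d", seq_len(nw_e)),
               role = "elicitor",
               elicitor = rep(elic_ids, each = config$n_replicates),
               concentration_uM = config$concentration_uM,
               replicate = rep(seq_len(config$n_replicates),
                               config$n_elicitors),
               stringsAsFactors = FALSE),
    data.frame(well = sprintf("C%04d", seq_len(config$n_controls)),
               role = "control", elicitor = NA_character_,
               concentration_uM = 0,
               replicate = seq_len(config$n_controls),
               stringsAsFactors = FALSE))

  member_mz <- unlist(lapply(config$families, `[[`, "mz"))
  bl_mz <- runif(config$n_baseline, config$mz_range[1], config$mz_range[2])
  if (length(member_mz)) {
    for (i in 1:10) {
      hit <- vapply(bl_mz, function(m) any(abs(m - member_mz) <= collision_tol),
                    logical(1))
      if (!any(hit)) break
      bl_mz[hit] <- runif(sum(hit), config$mz_range[1], config$mz_range[2])
    }
    if (any(vapply(bl_mz, function(m) any(abs(m - member_mz) <= collision_tol),
                   logical(1))))
      warning("baseline m/z collides with an injected family member")
  }
  bl_rt <- runif(config$n_baseline, config$rt_range[1], config$rt_range[2])
  bl_base <- rlnorm(config$n_baseline, config$baseline_meanlog,
                    config$baseline_sdlog)

  feat_mz <- bl_mz; feat_rt <- bl_rt; feat_base <- bl_base
  feat_ms2 <- rep(NA_character_, config$n_baseline)
  ms2 <- NULL
  truth <- NULL
  amp <- NULL  # rows: member feature index, elicitor, fold
  if (length(config$families)) {
    spec_rows <- list()
    for (fi in seq_along(config$families)) {
      fam <- config$families[[fi]]
      base_int <- if (is.null(fam$base_intensity))
        exp(config$baseline_meanlog) else fam$base_intensity
      idx0 <- length(feat_mz)
      feat_mz <- c(feat_mz, fam$mz)
      feat_rt <- c(feat_rt, fam$rt)
      feat_base <- c(feat_base, rep(base_int, length(fam$mz)))
      sid <- sprintf("fam%02d_m%02d", fi, seq_along(fam$mz))
      feat_ms2 <- c(feat_ms2,
                    if (length(fam$fragments)) sid
                    else rep(NA_character_, length(fam$mz)))
      if (length(fam$fragments))
        spec_rows[[fi]] <- data.frame(
          spectrum_id = rep(sid, each = length(fam$fragments)),
          precursor_mz = rep(fam$mz, each = length(fam$fragments)),
          fragment_mz = rep(fam$fragments, length(fam$mz)),
          rel_intensity = rep(100 / seq_along(fam$fragments),
                              length(fam$mz)),
          stringsAsFactors = FALSE)
      for (k in seq_along(fam$elicitors)) {
        truth <- rbind(truth, data.frame(
          family = fi, mz = fam$mz, rt = fam$rt,
          elicitor = fam$elicitors[k], fold = fam$fold[k],
          stringsAsFactors = FALSE))
        amp <- rbind(amp, data.frame(
          idx = idx0 + seq_along(fam$mz), elicitor = fam$elicitors[k],
          fold = fam$fold[k]))
      }
    }
    spec_rows <- spec_rows[!vapply(spec_rows, is.null, logical(1))]
    if (length(spec_rows)) ms2 <- do.call(rbind, spec_rows)
  }

  n_feat <- length(feat_mz)
  n_well <- nrow(pm)
  sdlog <- .cv_to_sdlog(config$noise_cv)
  noise <- matrix(exp(rnorm(n_feat * n_well, 0, sdlog)), n_feat, n_well)
  inten <- feat_base * noise
  colnames(inten) <- pm$well
  if (!is.null(amp)) {
    for (r in seq_len(nrow(amp))) {
      wells <- pm$well[!is.na(pm$elicitor) & pm$elicitor == amp$elicitor[r]]
      inten[amp$idx[r], wells] <- inten[amp$idx[r], wells] * amp$fold[r]
    }
  }

  features <- data.frame(
    well = rep(pm$well, each = n_feat),
    mz = rep(feat_mz, n_well),
    rt = rep(feat_rt, n_well),
    intensity = as.vector(inten),
    ms2_id = rep(feat_ms2, n_well),
    stringsAsFactors = FALSE)

  ds <- plate_dataset(features, pm, ms2 = ms2,
                      metadata = list(seed = seed, synthetic = TRUE))
  structure(list(dataset = ds, truth = truth, config = config, seed = seed),
            class = "screen_simulation")
}

#' Configure a synthetic dose series
#'
#' Growth follows a four-parameter logistic in elicitor dose; metabolite
#' induction is modeled phenomenologically as a rising logistic in dose
#' multiplied by the growth fraction, which reproduces the observed shape in
#' which production peaks at sub-inhibitory doses and collapses as growth
#' fails. Defaults place the growth IC50 at 4.6 uM and make the realized
#' (growth-damped) induction peak at roughly 12-fold near 5 uM, the
#' elicitation scale reported for tetracycline-induced dipeptide lipids;
#' `fold_max` is the asymptote the rising component would reach were growth
#' unaffected, which is why its default exceeds the realized peak.
#'
#' @param concentrations Strictly increasing dose grid in uM (may start at 0).
#' @param ic50 True growth IC50 in uM (default 4.6).
#' @param hill Growth Hill slope (default 1.5).
#' @param top,bottom Growth fractions at zero and saturating dose (defaults
#'   1 and 0).
#' @param fold_max Uninhibited asymptote of the rising induction component
#'   (default 25, which realizes a ~12-fold peak at sub-inhibitory doses
#'   once growth inhibition is applied).
#' @param ind_ec50,ind_hill Midpoint (uM) and slope of the rising induction
#'   component (defaults 2 and 2).
#' @param control_intensity Uninduced metabolite intensity (default 1e4).
#' @param noise_cv Multiplicative noise CV on growth and intensity
#'   (default 0.1).
#' @param n_replicates Replicates per dose (default 3).
#' @return A list of class `"dose_config"`.
#' @export
dose_config <- function(concentrations = c(0, 0.5, 1, 2, 4, 8, 16, 32),
                        ic50 = 4.6, hill = 1.5, top = 1, bottom = 0,
                        fold_max = 25, ind_ec50 = 2, ind_hill = 2,
                        control_intensity = 1e4, noise_cv = 0.1,
                        n_replicates = 3) {
  if (any(concentrations < 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be >= 0 and strictly increasing")
  if (ic50 <= 0) stop("ic50 must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(concentrations = concentrations, ic50 = ic50, hill = hill,
                 top = top, bottom = bottom, fold_max = fold_max,
                 ind_ec50 = ind_ec50, ind_hill = ind_hill,
                 control_intensity = control_intensity, noise_cv = noise_cv,
                 n_replicates = n_replicates),
            class = "dose_config")
}

#' Simulate a dose series with ground truth
#'
#' @param config A [dose_config()].
#' @param seed Integer seed.
#' @return A list of class `"dose_simulation"`: `data` (data frame
#'   `concentration, replicate, growth, intensity`) and `truth` (the config's
#'   true parameters).
#' @export
simulate_dose_series <- function(config, seed = 1) {
  stopifnot(inherits(config, "dose_config"))
  set.seed(seed)
  x <- rep(config$concentrations, each = config$n_replicates)
  growth0 <- .logistic4(x, config$bottom, config$top, config$ic50, config$hill)
  frac <- (growth0 - config$bottom) /
    max(config$top - config$bottom, .Machine$double.eps)
  ind <- 1 + (config$fold_max - 1) *
    ifelse(x > 0, x^config$ind_hill /
             (config$ind_ec50^config$ind_hill + x^config$ind_hill), 0)
  inten0 <- config$control_intensity * ind * frac
  sdlog <- .cv_to_sdlog(config$noise_cv)
  n <- length(x)
  data <- data.frame(
    concentration = x,
    replicate = rep(seq_len(config$n_replicates),
                    length(config$concentrations)),
    growth = growth0 * exp(rnorm(n, 0, sdlog)),
    intensity = inten0 * exp(rnorm(n, 0, sdlog)))
  structure(list(data = data,
                 truth = list(ic50 = config$ic50, hill = config$hill,
                              top = config$top, bottom = config$bottom,
                              fold_max = config$fold_max,
                              control_intensity = config$control_intensity),
                 config = config, seed = seed),
            class = "dose_simulation")
}

#' Configure and simulate a deuterium-labeling experiment
#'
#' Emulates feeding a uniformly deuterated precursor (e.g. valine-d8) to a
#' paired culture: the labeled sample carries an isotopologue of the base ion
#' shifted by `(n_label - n_lost)` times the deuterium-protium mass
#' difference (~1.00628 Da per retained label), with abundance proportional
#' to the incorporation fraction.
#'
#' @param base_mz Unlabeled ion m/z.
#' @param n_label Number of deuteria on the fed precursor.
#' @param n_lost Labeled positions lost along the catabolic route (default 1,
#'   the alpha position lost during transamination).
#' @param incorporation Fraction of the metabolite pool carrying the label
#'   (0-1, default 0.6).
#' @param base_intensity Base-peak intensity (default 1e5).
#' @param noise_cv Multiplicative intensity noise CV (default 0.05).
#' @return `label_config()` returns a list of class `"label_config"`.
#' @export
label_config <- function(base_mz, n_label, n_lost = 1, incorporation = 0.6,
                         base_intensity = 1e5, noise_cv = 0.05) {
  if (n_lost < 0 || n_lost > n_label)
    stop("invalid labeling: lost positions must satisfy 0 <= lost <= label count")
  if (incorporation < 0 || incorporation > 1)
    stop("incorporation fraction must lie in [0, 1]")
  structure(list(base_mz = base_mz, n_label = n_label, n_lost = n_lost,
                 incorporation = incorporation,
                 base_intensity = base_intensity, noise_cv = noise_cv),
            class = "label_config")
}

#' @rdname label_config
#' @param config A `label_config`.
#' @param seed Integer seed.
#' @return `simulate_labeling()` returns a list of class
#'   `"labeling_simulation"`: `unlabeled` and `labeled` spectra (data frames
#'   `mz, intensity`) and `truth` (retained-label count `k` and exact shift).
#' @export
simulate_labeling <- function(config, seed = 1) {
  stopifnot(inherits(config, "label_config"))
  set.seed(seed)
  k <- config$n_label - config$n_lost
  delta <- k * deuterium_shift()
  sdlog <- .cv_to_sdlog(config$noise_cv)
  bg_mz <- c(config$base_mz - 31.42, config$base_mz + 17.93)
  bg_int <- c(0.12, 0.07) * config$base_intensity
  noise <- function(n) exp(rnorm(n, 0, sdlog))
  unlabeled <- data.frame(
    mz = c(config$base_mz, bg_mz),
    intensity = c(config$base_intensity, bg_int) * noise(3))
  lab_rows <- data.frame(
    mz = c(config$base_mz, bg_mz),
    intensity = c(config$base_intensity * (1 - config$incorporation), bg_int) *
      noise(3))
  if (k > 0 && config$incorporation > 0)
    lab_rows <- rbind(lab_rows, data.frame(
      mz = config$base_mz + delta,
      intensity = config$base_intensity * config$incorporation * noise(1)))
  unlabeled <- unlabeled[order(unlabeled$mz), ]
  lab_rows <- lab_rows[order(lab_rows$mz), ]
  rownames(unlabeled) <- rownames(lab_rows) <- NULL
  structure(list(unlabeled = unlabeled, labeled = lab_rows,
                 truth = list(k = k, delta = delta), config = config,
                 seed = seed),
            class = "labeling_simulation")
}
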