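# Control-subtracted differential analysis of an elicitor screen: align
# features across wells, subtract vehicle-control intensities, rank
# elicitors per ion, call hits, and extract ion traces.

#' Align features across wells
#'
#' Greedy single-linkage grouping: the most intense unassigned feature seeds
#' a group, which claims all unassigned features within the m/z and
#' retention-time tolerances. Every input feature is assigned exactly once;
#' the result is invariant under well permutation.
#'
#' @param dataset A [plate_dataset()].
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @return An object of class `"aligned_features"`: `features` (data frame
#'   `feature_id, mz, rt, rt_min, rt_max, n_members`; consensus m/z is the
#'   intensity-weighted mean), `intensity` (features x wells matrix, 0 where
#'   absent; co-grouped features in one well are summed), and `assignment`
#'   (group index per input feature row).
#' @export
align_features <- function(dataset, mz_tol_ppm = 10, rt_tol = 0.2) {
  stopifnot(inherits(dataset, "plate_dataset"))
  ft <- dataset$features
  wells <- dataset$plate_map$well
  n <- nrow(ft)
  assignment <- integer(n)
  if (n) {
    ord <- order(-ft$intensity)
    mz <- ft$mz; rt <- ft$rt
    assigned <- rep(FALSE, n)
    gid <- 0L
    for (i in ord) {
      if (assigned[i]) next
      gid <- gid + 1L
      tol <- mz[i] * mz_tol_ppm * 1e-6
      grp <- which(!assigned & abs(mz - mz[i]) <= tol & abs(rt - rt[i]) <= rt_tol)
      assigned[grp] <- TRUE
      assignment[grp] <- gid
    }
  }
  ng <- max(assignment, 0L)
  inten <- matrix(0, ng, length(wells), dimnames = list(NULL, wells))
  feats <- data.frame(feature_id = integer(0), mz = numeric(0), rt = numeric(0),
                      rt_min = numeric(0), rt_max = numeric(0),
                      n_members = integer(0))
  if (ng) {
    wi <- match(ft$well, wells)
    for (r in seq_len(n)) {
      g <- assignment[r]
      inten[g, wi[r]] <- inten[g, wi[r]] + ft$intensity[r]
    }
    cons_mz <- vapply(seq_len(ng), function(g) {
      m <- assignment == g
      w <- ft$intensity[m]
      if (sum(w) > 0) weighted.mean(ft$mz[m], w) else mean(ft$mz[m])
    }, numeric(1))
    feats <- data.frame(
      feature_id = seq_len(ng),
      mz = cons_mz,
      rt = vapply(seq_len(ng), function(g) median(ft$rt[assignment == g]),
                  numeric(1)),
      rt_min = vapply(seq_len(ng), function(g) min(ft$rt[assignment == g]),
                      numeric(1)),
      rt_max = vapply(seq_len(ng), function(g) max(ft$rt[assignment == g]),
                      numeric(1)),
      n_members = as.integer(table(factor(assignment, levels = seq_len(ng)))))
    ord2 <- order(feats$mz)
    feats <- feats[ord2, , drop = FALSE]
    inten <- inten[ord2, , drop = FALSE]
    feats$feature_id <- seq_len(ng)
    rownames(feats) <- NULL
    assignment <- match(assignment, ord2)
  }
  structure(list(features = feats, intensity = inten,
                 plate_map = dataset$plate_map, assignment = assignment),
            class = "aligned_features")
}

#' Build the control-subtracted differential induction map
#'
#' For every aligned feature f and elicitor e, computes the induced
#' intensity `dI = max(0, median over e's replicate wells - mean over
#' control wells)` and the fold change `F = (I_e + c) / (I_ctrl + c)` with a
#' pseudo-count `c` equal to `pseudo_frac` times the median positive control
#' intensity of the plate, so that ions absent from controls get finite fold
#' changes. Negative induced intensities are floored at zero: the map
#' focuses on induced, not suppressed, metabolites. A one-sided z-test of
#' each elicitor's log intensity against the feature's control log-intensity
#' distribution supplies per-cell p-values for FDR-controlled hit calling.
#'
#' @param aligned An [align_features()] result.
#' @param pseudo_frac Pseudo-count as a fraction of the plate's median
#'   positive control intensity (default 0.05).
#' @return An object of class `"differential_map"` with feature table,
#'   elicitor ids, and matrices `dI`, `fold`, `p` (features x elicitors),
#'   plus per-feature control mean/sd and the pseudo-count used.
#' @export
differential_map <- function(aligned, pseudo_frac = 0.05) {
  stopifnot(inherits(aligned, "aligned_features"))
  pm <- aligned$plate_map
  ctrl_wells <- pm$well[pm$role == "control"]
  if (!length(ctrl_wells))
    stop("no-control error: differential map requires >= 1 control well")
  elic <- unique(pm$elicitor[pm$role == "elicitor"])
  inten <- aligned$intensity
  ctrl <- inten[, ctrl_wells, drop = FALSE]
  pos <- ctrl[ctrl > 0]
  c0 <- if (length(pos)) pseudo_frac * median(pos) else 1

  ctrl_mean <- rowMeans(ctrl)
  log_ctrl <- log(ctrl + c0)
  ctrl_logmean <- rowMeans(log_ctrl)
  ctrl_logsd <- apply(log_ctrl, 1, sd)
  if (ncol(ctrl) < 2) ctrl_logsd <- rep(NA_real_, nrow(inten))

  nf <- nrow(inten)
  dI <- fold <- p <- matrix(NA_real_, nf, length(elic),
                            dimnames = list(NULL, elic))
  n_ctrl <- length(ctrl_wells)
  for (j in seq_along(elic)) {
    wells_e <- pm$well[!is.na(pm$elicitor) & pm$elicitor == elic[j]]
    Ie <- if (length(wells_e) == 1L) inten[, wells_e] else
      apply(inten[, wells_e, drop = FALSE], 1, median)
    dI[, j] <- pmax(0, Ie - ctrl_mean)
    fold[, j] <- (Ie + c0) / (ctrl_mean + c0)
    if (!anyNA(ctrl_logsd)) {
      z <- (log(Ie + c0) - ctrl_logmean) /
        (pmax(ctrl_logsd, 1e-9) * sqrt(1 + 1 / n_ctrl))
      p[, j] <- pnorm(z, lower.tail = FALSE)
    }
  }
  structure(list(features = aligned$features, elicitors = elic,
                 dI = dI, fold = fold, p = p,
                 control_mean = ctrl_mean, control_sd = apply(ctrl, 1, sd),
                 pseudo_count = c0, n_control = n_ctrl),
            class = "differential_map")
}

#' @export
print.differential_map <- function(x, ...) {
  cat(sprintf(
    "differential_map: %d aligned features x %d elicitors (pseudo-count %.3g)\n",
    nrow(x$features), length(x$elicitors), x$pseudo_count))
  cat(sprintf("max fold change: %.2f\n", max(x$fold, na.rm = TRUE)))
  invisible(x)
}

#' Slice the induction map at one ion
#'
#' Selects the aligned feature closest in m/z to `mz` among those within the
#' ppm window and returns its elicitors ranked by induced intensity: the 2D
#' slice of the 3D (m/z x elicitor x intensity) induction map used to read
#' off the best elicitors of a metabolite.
#'
#' @param map A [differential_map()].
#' @param mz Target m/z.
#' @param ppm Matching tolerance in ppm (default 10).
#' @return Data frame `elicitor, dI, fold, rank` sorted by `dI` descending
#'   (zero rows, with a message, when no feature matches).
#' @export
extract_slice <- function(map, mz, ppm = 10) {
  stopifnot(inherits(map, "differential_map"))
  d <- abs(map$features$mz - mz)
  hit <- which(d <= mz * ppm * 1e-6)
  if (!length(hit)) {
    message("no aligned feature within ", ppm, " ppm of m/z ", mz)
    return(data.frame(elicitor = character(0), dI = numeric(0),
                      fold = numeric(0), rank = integer(0)))
  }
  f <- hit[which.min(d[hit])]
  out <- data.frame(elicitor = map$elicitors, dI = map$dI[f, ],
                    fold = map$fold[f, ], stringsAsFactors = FALSE)
  out <- out[order(-out$dI, out$elicitor), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call screen hits
#'
#' A feature is a hit when its best elicitor (largest induced intensity)
#' passes the fold-change and induced-intensity thresholds and, when `fdr`
#' is given, its Benjamini-Hochberg adjusted p-value (adjustment across all
#' feature x elicitor cells) is at or below `fdr`.
#'
#' @param map A [differential_map()].
#' @param min_fold Minimum fold change (default 3).
#' @param min_dI Minimum induced intensity (default 0).
#' @param fdr Optional BH false-discovery-rate threshold in (0, 1).
#' @param top_k Number of top elicitors reported per hit (default 5).
#' @return Data frame of class `"screen_hits"`: one row per hit feature with
#'   `feature_id, mz, rt, elicitor, dI, fold, q, top_elicitors`
#'   (semicolon-separated rank list), sorted by `dI` descending.
#' @export
call_hits <- function(map, min_fold = 3, min_dI = 0, fdr = NULL, top_k = 5) {
  stopifnot(inherits(map, "differential_map"))
  if (min_fold <= 0 || min_dI < 0) stop("thresholds must be positive")
  if (!is.null(fdr)) {
    if (fdr <= 0 || fdr >= 1) stop("`fdr` must lie in (0, 1)")
    if (anyNA(map$p))
      stop("FDR-based calling needs >= 2 control wells for per-cell tests")
  }
  q <- if (!is.null(fdr))
    matrix(p.adjust(map$p, method = "BH"), nrow(map$p), ncol(map$p),
           dimnames = dimnames(map$p))
  else NULL
  best <- apply(map$dI, 1, which.max)
  idx <- cbind(seq_len(nrow(map$dI)), best)
  ok <- map$fold[idx] >= min_fold & map$dI[idx] >= min_dI
  if (!is.null(q)) ok <- ok & q[idx] <= fdr
  hits <- data.frame(
    feature_id = map$features$feature_id[ok],
    mz = map$features$mz[ok], rt = map$features$rt[ok],
    elicitor = map$elicitors[best[ok]],
    dI = map$dI[idx][ok], fold = map$fold[idx][ok],
    q = if (!is.null(q)) q[idx][ok] else NA_real_,
    top_elicitors = vapply(which(ok), function(f) {
      ord <- order(-map$dI[f, ])[seq_len(min(top_k, length(map$elicitors)))]
      paste(map$elicitors[ord], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  hits <- hits[order(-hits$dI, hits$mz), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("screen_hits", "data.frame")
  hits
}

#' Extracted ion chromatogram table
#'
#' Collects, per well, all features matching a target m/z within a ppm
#' window — the tabular form of an extracted ion chromatogram.
#'
#' @param dataset A [plate_dataset()].
#' @param mz Target m/z.
#' @param ppm Tolerance in ppm (must be positive).
#' @return Data frame `well, mz, rt, intensity` sorted by well then rt.
#' @export
eic <- function(dataset, mz, ppm = 10) {
  stopifnot(inherits(dataset, "plate_dataset"))
  if (ppm <= 0) stop("`ppm` must be positive")
  ft <- dataset$features
  keep <- abs(ft$mz - mz) <= mz * ppm * 1e-6
  out <- ft[keep, c("well", "mz", "rt", "intensity"), drop = FALSE]
  out <- out[order(out$well, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
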