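#' Import centroided mzML files as a plate dataset
#'
#' Reduces one centroided mzML file per well to a feature table: peaks are
#' grouped across scans by m/z tolerance (greedy, seeded at the most intense
#' unassigned peak), each group is split into contiguous retention-time
#' traces, and every trace above the noise floor becomes one feature whose
#' m/z is the intensity-weighted centroid and whose retention time and
#' intensity are taken at the trace apex. This is deliberately a simple,
#' documented reduction, not a research-grade peak picker; the canonical
#' interchange format of the pipeline remains the long-format CSV feature
#' table.
#'
#' Requires the Bioconductor package \pkg{mzR}. Profile-mode spectra are
#' rejected with an explicit error.
#'
#' @param paths Named character vector of mzML paths; names are well ids
#'   present in `plate_map`.
#' @param plate_map Plate map data frame (see [plate_dataset()]).
#' @param mz_tol_ppm m/z tolerance linking peaks across scans (default 20).
#' @param noise_floor Minimum apex intensity for a trace to become a feature
#'   (default 0).
#' @param max_scan_gap Maximum number of missing scans tolerated inside one
#'   trace before it is split (default 1).
#' @param require_control Passed to [plate_dataset()].
#' @return A [plate_dataset()] whose retention times are in minutes.
#' @export
import_mzml <- function(paths, plate_map, mz_tol_ppm = 20, noise_floor = 0,
                        max_scan_gap = 1, require_control = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("import_mzml() requires the Bioconductor package 'mzR'")
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by well id")
  rows <- list()
  for (well in names(paths)) {
    ms <- mzR::openMSfile(paths[[well]])
    on.exit(try(mzR::close(ms), silent = TRUE), add = TRUE)
    hdr <- mzR::header(ms)
    if (nrow(hdr)) {
      if (any(!is.na(hdr$centroided) & !hdr$centroided))
        stop("unsupported-mode error: profile-mode spectra in '",
             paths[[well]], "'; only centroided mzML is supported")
      pk <- mzR::peaks(ms)
      if (is.matrix(pk)) pk <- list(pk)
      feats <- .pick_traces(pk, hdr$retentionTime / 60, mz_tol_ppm,
                            noise_floor, max_scan_gap)
      if (nrow(feats)) {
        feats$well <- well
        rows[[well]] <- feats
      }
    }
    mzR::close(ms)
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(0), mz = numeric(0), rt = numeric(0),
               intensity = numeric(0))
  rownames(features) <- NULL
  plate_dataset(features[, c("well", "mz", "rt", "intensity")], plate_map,
                metadata = list(source = "mzML"),
                require_control = require_control)
}

# peaks: list of [mz, intensity] matrices; rt: minutes per scan
.pick_traces <- function(peaks, rt, mz_tol_ppm, noise_floor, max_scan_gap) {
  all <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (is.null(p) || !nrow(p)) return(NULL)
    cbind(scan = i, mz = p[, 1], intensity = p[, 2])
  }))
  out <- data.frame(mz = numeric(0), rt = numeric(0), intensity = numeric(0))
  if (is.null(all) || !nrow(all)) return(out)
  all <- as.data.frame(all)
  assigned <- rep(FALSE, nrow(all))
  ord <- order(-all$intensity)
  for (i in ord) {
    if (assigned[i]) next
    tol <- all$mz[i] * mz_tol_ppm * 1e-6
    grp <- which(!assigned & abs(all$mz - all$mz[i]) <= tol)
    assigned[grp] <- TRUE
    g <- all[grp, , drop = FALSE]
    g <- g[order(g$scan), , drop = FALSE]
    # split the m/z group into contiguous scan runs
    brk <- cumsum(c(1, diff(g$scan) > max_scan_gap + 1))
    for (b in unique(brk)) {
      tr <- g[brk == b, , drop = FALSE]
      apex <- which.max(tr$intensity)
      if (tr$intensity[apex] <= noise_floor) next
      out <- rbind(out, data.frame(
        mz = weighted.mean(tr$mz, tr$intensity),
        rt = rt[tr$scan[apex]],
        intensity = tr$intensity[apex]))
    }
  }
  out[order(out$rt, out$mz), , drop = FALSE]
}
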