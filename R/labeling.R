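# Stable-isotope (deuterium) labeling interpretation: predicted and
# detected isotopologue shifts, and BCAA catabolic routing.

#' Predicted isotopologue shift from a deuterated precursor
#'
#' A precursor carrying `n_label` deuteria that loses `n_lost` labeled
#' positions along its catabolic route (by default one: the alpha proton
#' lost during transamination to the keto acid) yields an M+k isotopologue
#' with `k = n_label - n_lost` and an exact mass shift of
#' `k * (mass(D) - mass(H))`, about 1.00628 Da per retained label. Feeding
#' valine-d8 therefore predicts M+7; leucine-d10 or isoleucine-d10 predict
#' M+9.
#'
#' @param n_label Number of deuteria on the fed precursor.
#' @param n_lost Labeled positions lost en route (default 1).
#' @return A list: integer `k` and exact `delta` in Da.
#' @examples
#' expected_shift(8)   # valine-d8 -> M+7
#' expected_shift(10)  # leucine-d10 -> M+9
#' @export
expected_shift <- function(n_label, n_lost = 1) {
  if (n_label < 0 || n_lost < 0 || n_lost > n_label)
    stop("invalid labeling: need 0 <= lost positions <= label count")
  k <- as.integer(n_label - n_lost)
  list(k = k, delta = k * deuterium_shift())
}

#' Detect an isotopologue shift between paired spectra
#'
#' Searches the labeled spectrum for peaks at `base_mz + k * 1.006277` Da
#' for k = 1..`max_k` and returns the best-supported (highest-intensity)
#' retained-label count, or `NULL` when no candidate peak exceeds the noise
#' floor. Partial incorporation reports the single best-supported k, the
#' M+k readout of a labeling experiment, not a distribution.
#'
#' @param unlabeled,labeled Spectra as data frames with columns `mz` and
#'   `intensity`.
#' @param base_mz m/z of the unlabeled ion; must be present in the
#'   unlabeled spectrum within `tol`.
#' @param max_k Largest shift searched (default 12).
#' @param tol Peak-matching tolerance in Da (default 0.01).
#' @param noise_floor Minimum supporting-peak intensity; defaults to 5% of
#'   the base peak's intensity in the unlabeled spectrum.
#' @return A list of class `"isotopologue_shift"` (`k`, exact `delta`,
#'   supporting `peak`), or `NULL`.
#' @export
detect_shift <- function(unlabeled, labeled, base_mz, max_k = 12,
                         tol = 0.01, noise_floor = NULL) {
  for (nm in c("unlabeled", "labeled")) {
    sp <- get(nm)
    if (!is.data.frame(sp) || !all(c("mz", "intensity") %in% names(sp)))
      stop("`", nm, "` must be a data frame with columns mz and intensity")
  }
  base_idx <- which(abs(unlabeled$mz - base_mz) <= tol)
  if (!length(base_idx))
    stop("base peak at m/z ", base_mz,
         " not found in the unlabeled spectrum within ", tol, " Da")
  base_int <- max(unlabeled$intensity[base_idx])
  if (is.null(noise_floor)) noise_floor <- 0.05 * base_int
  best <- NULL
  for (k in seq_len(max_k)) {
    target <- base_mz + k * deuterium_shift()
    idx <- which(abs(labeled$mz - target) <= tol &
                   labeled$intensity > noise_floor)
    if (!length(idx)) next
    top <- idx[which.max(labeled$intensity[idx])]
    if (is.null(best) || labeled$intensity[top] > best$peak$intensity)
      best <- list(k = k, delta = k * deuterium_shift(),
                   peak = data.frame(mz = labeled$mz[top],
                                     intensity = labeled$intensity[top]))
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "isotopologue_shift")
}

#' @export
print.isotopologue_shift <- function(x, ...) {
  cat(sprintf("isotopologue shift: M+%d (%.5f Da), supported by m/z %.4f\n",
              x$k, x$delta, x$peak$mz))
  invisible(x)
}

#' BCAA catabolic routing to acyl-CoA starters and branch classes
#'
#' Maps a branched-chain amino acid to the acyl-CoA starter unit produced by
#' its transamination/BCKDH catabolism and the fatty-acid branch class that
#' starter seeds: valine to isobutyryl-CoA (iso branching, even-carbon
#' chains), leucine to isovaleryl-CoA (iso, odd-carbon chains), isoleucine
#' to 2-methylbutyryl-CoA (anteiso, odd-carbon chains).
#'
#' @param precursor `"valine"`, `"leucine"` or `"isoleucine"` (three-letter
#'   abbreviations accepted, case-insensitive).
#' @return A list: `starter`, `branch`, `chain_parity`.
#' @examples
#' bcaa_route("valine")
#' @export
bcaa_route <- function(precursor) {
  key <- switch(tolower(trimws(precursor)),
                "valine" = , "val" = "valine",
                "leucine" = , "leu" = "leucine",
                "isoleucine" = , "ile" = "isoleucine",
                stop("unknown BCAA precursor '", precursor,
                     "'; expected valine, leucine or isoleucine"))
  routes <- list(
    valine = list(starter = "isobutyryl-CoA", branch = "iso",
                  chain_parity = "even"),
    leucine = list(starter = "isovaleryl-CoA", branch = "iso",
                   chain_parity = "odd"),
    isoleucine = list(starter = "2-methylbutyryl-CoA", branch = "anteiso",
                      chain_parity = "odd"))
  routes[[key]]
}
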