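#' Reference ion fixture: the doreamide family and N-acyladenosine pair
#'
#' Returns the literature-reported ions of the tetracycline-induced
#' *B. dorei* metabolites as an in-memory fixture: the six doreamide
#' dipeptide-lipid precursor ions (m/z 403.2766, 417.2931, 431.3090,
#' 431.3092, 445.3259, 459.3392), each carrying the three diagnostic
#' Ser-Gly-derived MS/MS fragments (m/z 163.0726, 145.0618, 106.0506), and
#' the RT-resolved isomeric N-acyladenosine pair (m/z 352.1611 and
#' 352.1618), whose spectra carry the protonated-adenine fragment
#' (m/z 136.0618) instead. The m/z values are the reported high-resolution
#' measurements; retention times and intensities are synthetic placeholders
#' chosen only to respect the reported elution relationships (homolog rungs
#' RT-resolved, the two same-nominal-mass pairs separated by more than 0.3
#' min).
#'
#' @return A list with elements `features` (data frame `mz, rt, intensity,
#'   ms2_id, group`) and `ms2` (long-format spectra:
#'   `spectrum_id, precursor_mz, fragment_mz, rel_intensity`).
#' @examples
#' fix <- doreamide_fixture()
#' detect_homolog_series(fix$features)
#' @export
doreamide_fixture <- function() {
  dore_mz <- c(403.2766, 417.2931, 431.3090, 431.3092, 445.3259, 459.3392)
  dore_rt <- c(6.8, 7.2, 7.6, 8.0, 8.4, 8.8)          # synthetic
  acyl_mz <- c(352.1611, 352.1618)
  acyl_rt <- c(3.1, 3.6)                              # synthetic
  dore_frag <- c(163.0726, 145.0618, 106.0506)
  aden_frag <- 136.0618

  features <- data.frame(
    mz = c(dore_mz, acyl_mz),
    rt = c(dore_rt, acyl_rt),
    intensity = c(2e5, 8e5, 5e5, 3e5, 4e5, 1.5e5, 6e5, 5e5),  # synthetic
    ms2_id = c(sprintf("dore_%d", seq_along(dore_mz)),
               sprintf("acyl_%d", seq_along(acyl_mz))),
    group = c(rep("doreamide", length(dore_mz)),
              rep("acyladenosine", length(acyl_mz))),
    stringsAsFactors = FALSE)

  ms2 <- rbind(
    data.frame(
      spectrum_id = rep(sprintf("dore_%d", seq_along(dore_mz)),
                        each = length(dore_frag)),
      precursor_mz = rep(dore_mz, each = length(dore_frag)),
      fragment_mz = rep(dore_frag, length(dore_mz)),
      rel_intensity = rep(c(100, 60, 40), length(dore_mz)),
      stringsAsFactors = FALSE),
    data.frame(
      spectrum_id = sprintf("acyl_%d", seq_along(acyl_mz)),
      precursor_mz = acyl_mz,
      fragment_mz = rep(aden_frag, length(acyl_mz)),
      rel_intensity = rep(100, length(acyl_mz)),
      stringsAsFactors = FALSE))

  list(features = features, ms2 = ms2)
}
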