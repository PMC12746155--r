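# Fixed isotope / atomic-weight tables (IUPAC 2021, AME2020 isotope masses).
# Bundled so that mass arithmetic is deterministic and offline.

# mass of the most abundant isotope of each supported element; D = 2H
.ISOTOPE_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  D  = 2.01410177812,
  N  = 14.0030740044,
  O  = 15.9949146196,
  S  = 31.9720711744,
  P  = 30.9737619984,
  Na = 22.9897692820,
  K  = 38.9637064864
)

# conventional standard atomic weights
.ATOMIC_WEIGHT <- c(
  C  = 12.011,
  H  = 1.008,
  D  = 2.01410177812,
  N  = 14.007,
  O  = 15.999,
  S  = 32.06,
  P  = 30.974,
  Na = 22.98976928,
  K  = 39.0983
)

# integer (nominal) masses used by the nitrogen rule
.NOMINAL_MASS <- c(C = 12, H = 1, D = 2, N = 14, O = 16, S = 32, P = 31,
                   Na = 23, K = 39)

#' Physical constants used in adduct and labeling arithmetic
#'
#' `proton_mass()` returns the proton mass in Da (1.00727646688); the electron
#' mass is deliberately ignored in adduct arithmetic, a sub-ppm effect at the
#' masses handled here. `deuterium_shift()` returns the mass difference
#' between deuterium and protium (about 1.006277 Da), the per-label mass
#' increment of a deuterium isotopologue.
#'
#' @return A single numeric value in Da.
#' @export
proton_mass <- function() 1.00727646688

#' @rdname proton_mass
#' @export
deuterium_shift <- function() unname(.ISOTOPE_MASS["D"] - .ISOTOPE_MASS["H"])

#' Parse a molecular formula string
#'
#' Parses Hill-style element/count strings such as `"C21H40N2O6"` into a named
#' count vector. Counts default to 1; repeated mentions of an element are
#' summed. Deuterium is written `D` and counted separately from `H` (it still
#' contributes to the hydrogen total in valence and RDBE arithmetic).
#'
#' @param text A single formula string, e.g. `"C21H40N2O6"` or `"C5D7H3NO2"`.
#' @return A named numeric vector of element counts, normalized (zero counts
#'   dropped, Hill order: C, H, D, then remaining elements alphabetically).
#' @examples
#' parse_formula("C21H40N2O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single formula string")
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(.normalize_formula(numeric(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(text))
    stop("formula string '", text, "' contains unparseable characters")
  counts <- numeric(0)
  for (tok in tokens) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!el %in% names(.ISOTOPE_MASS))
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    n <- if (nzchar(num)) as.numeric(num) else 1
    if (n <= 0)
      stop("malformed count '", tok, "' in formula '", text,
           "': counts must be positive")
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + n
  }
  .normalize_formula(counts)
}

# drop zero counts, enforce Hill-style ordering
.normalize_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return(setNames(numeric(0), character(0)))
  lead <- intersect(c("C", "H", "D"), names(counts))
  rest <- sort(setdiff(names(counts), lead))
  counts[c(lead, rest)]
}

#' @rdname parse_formula
#' @param f A formula: either a string or a named count vector.
#' @return `format_formula()` returns the canonical formula string;
#'   `as_formula()` coerces either representation to a validated count vector.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1, "", format(f, scientific = FALSE, trim = TRUE)),
         collapse = "")
}

#' @rdname parse_formula
#' @export
as_formula <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (!is.numeric(f))
    stop("a formula must be a string or a named numeric count vector")
  if (length(f) > 0L) {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop("formula count vector must be fully named")
    bad <- setdiff(names(f), names(.ISOTOPE_MASS))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(f < 0)) stop("element counts must be non-negative")
  }
  .normalize_formula(f)
}

#' Exact and average molecular masses
#'
#' `monoisotopic_mass()` sums the per-element most-abundant-isotope masses from
#' the bundled table; `average_mass()` sums conventional standard atomic
#' weights; `nominal_mass()` sums integer masses (used by the nitrogen rule).
#' All are additive over formula sums.
#'
#' @param f A formula string or named count vector.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C21H40N2O6") # ~416.2886
#' average_mass("C22H24N2O8")      # tetracycline, ~444.44
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(.ISOTOPE_MASS[names(f)] * f)
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(f) {
  f <- as_formula(f)
  sum(.ATOMIC_WEIGHT[names(f)] * f)
}

#' @rdname monoisotopic_mass
#' @export
nominal_mass <- function(f) {
  f <- as_formula(f)
  sum(.NOMINAL_MASS[names(f)] * f)
}

#' Define an ionization adduct
#'
#' An adduct is a named (charge, mass delta) pair; the m/z of an ion is
#' `(neutral monoisotopic mass + delta) / |charge|`. Known names:
#' `"[M+H]+"` (`"M+H"`), `"[M-H]-"`, `"[M+Na]+"` and `"[M]+"`. Electron mass
#' is ignored (proton delta 1.007276 Da), a sub-ppm convention at these masses.
#'
#' @param name Adduct name; one of the known names above, or any label when
#'   `charge` and `delta` are supplied explicitly.
#' @param charge Signed integer charge, non-zero.
#' @param delta Mass delta in Da added to the neutral monoisotopic mass.
#' @return An object of class `"adduct"`.
#' @export
adduct <- function(name, charge = NULL, delta = NULL) {
  known <- list(
    "[M+H]+"  = list(charge = 1L,  delta = proton_mass()),
    "[M-H]-"  = list(charge = -1L, delta = -proton_mass()),
    "[M+Na]+" = list(charge = 1L,  delta = unname(.ISOTOPE_MASS["Na"])),
    "[M]+"    = list(charge = 1L,  delta = 0)
  )
  alias <- c("M+H" = "[M+H]+", "M-H" = "[M-H]-", "M+Na" = "[M+Na]+",
             "M" = "[M]+")
  if (name %in% names(alias)) name <- alias[[name]]
  if (is.null(charge) || is.null(delta)) {
    if (!name %in% names(known))
      stop("unknown adduct '", name, "'; supply `charge` and `delta`")
    charge <- known[[name]]$charge
    delta <- known[[name]]$delta
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge == 0)
    stop("adduct charge must be a non-zero integer")
  structure(list(name = name, charge = as.integer(charge), delta = delta),
            class = "adduct")
}

#' @export
print.adduct <- function(x, ...) {
  cat(sprintf("adduct %s: charge %+d, delta %.6f Da\n",
              x$name, x$charge, x$delta))
  invisible(x)
}

#' m/z of an adduct ion
#'
#' @param f A formula string or count vector (the neutral species).
#' @param a An [adduct()] object or adduct name.
#' @return m/z of the ion: `(monoisotopic mass + delta) / |charge|`.
#' @examples
#' adduct_mz("C15H21N5O5", "[M+H]+") # ~352.1615
#' @export
adduct_mz <- function(f, a = "[M+H]+") {
  if (is.character(a)) a <- adduct(a)
  if (!inherits(a, "adduct")) stop("`a` must be an adduct")
  (monoisotopic_mass(f) + a$delta) / abs(a$charge)
}

#' Parts-per-million mass error
#'
#' Signed relative error `(observed - theoretical) / theoretical * 1e6`;
#' positive when the observed ion is heavier than theory.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Rings plus double-bond equivalents
#'
#' `rdbe(f) = C + 1 + (N + P)/2 - (H + D + Na + K)/2`; oxygen and sulfur are
#' neutral. Deuterium counts with hydrogen. A plausible neutral organic
#' molecule has integer RDBE >= 0.
#'
#' @param f A formula string or count vector.
#' @return Half-integer RDBE value.
#' @examples
#' rdbe("C21H40N2O6") # 3
#' rdbe("C6H6")       # 4
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(el) if (el %in% names(f)) unname(f[el]) else 0
  cnt("C") + 1 + (cnt("N") + cnt("P")) / 2 -
    (cnt("H") + cnt("D") + cnt("Na") + cnt("K")) / 2
}

#' Nitrogen-rule check
#'
#' A neutral CHNOSP molecule has an odd nominal mass if and only if it
#' contains an odd number of nitrogens. Applied to the neutral formula (the
#' screen's ions are even-electron protonated species).
#'
#' @param f A formula string or count vector.
#' @return `TRUE` if the formula satisfies the nitrogen rule.
#' @export
nitrogen_rule <- function(f) {
  f <- as_formula(f)
  n <- if ("N" %in% names(f)) unname(f["N"]) else 0
  (nominal_mass(f) %% 2 == 1) == (n %% 2 == 1)
}

#' Bounded molecular-formula enumeration
#'
#' Exhaustively enumerates elemental formulas over a bounded lattice whose
#' monoisotopic mass falls within a ppm window of a query neutral mass,
#' optionally constrained to integer RDBE >= `rdbe_min` and to the nitrogen
#' rule. This is the formula-assignment step behind high-resolution MS ion
#' annotation: subtract the adduct delta from an observed m/z and enumerate.
#'
#' Candidates are ranked by |ppm error| ascending, ties broken by smaller
#' total atom count.
#'
#' @param mass Query neutral monoisotopic mass in Da (> 0).
#' @param tol_ppm Mass tolerance in ppm (default 10, the package's MS1
#'   assignment default).
#' @param bounds Named vector of per-element maximum counts, e.g.
#'   `c(C = 30, H = 60, N = 10, O = 10)`. Elements absent from `bounds` are
#'   not considered.
#' @param rdbe_min Minimum RDBE (default 0); set `NULL` to disable.
#' @param rdbe_integer Require integer RDBE (default `TRUE`).
#' @param use_nitrogen_rule Apply the nitrogen rule to candidates (default
#'   `TRUE`).
#' @return A data frame of class `"formula_candidates"` with columns
#'   `formula`, one column per bounded element, `mass`, `ppm`, `rdbe`,
#'   `atoms`; zero rows when nothing matches.
#' @examples
#' enumerate_formulas(352.1611 - proton_mass(), tol_ppm = 10,
#'                    bounds = c(C = 30, H = 60, N = 10, O = 10))
#' @export
enumerate_formulas <- function(mass, tol_ppm = 10,
                               bounds = c(C = 30, H = 60, N = 10, O = 10),
                               rdbe_min = 0, rdbe_integer = TRUE,
                               use_nitrogen_rule = TRUE) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("`mass` must be a single positive number")
  if (tol_ppm <= 0) stop("`tol_ppm` must be positive")
  if (is.null(names(bounds)) || any(!nzchar(names(bounds))))
    stop("`bounds` must be a named vector of per-element maxima")
  bad <- setdiff(names(bounds), names(.ISOTOPE_MASS))
  if (length(bad)) stop("unknown element(s) in bounds: ",
                        paste(bad, collapse = ", "))
  if (any(!is.finite(bounds)) || any(bounds < 0))
    stop("bounds must be finite and non-negative")

  tol_da <- mass * tol_ppm * 1e-6
  h_max <- if ("H" %in% names(bounds)) unname(bounds["H"]) else 0
  others <- setdiff(names(bounds), "H")

  # grid over non-hydrogen elements; H solved from the mass residual
  grids <- lapply(others, function(el) {
    top <- min(bounds[el], floor((mass + tol_da) / .ISOTOPE_MASS[el]))
    0:max(0, top)
  })
  names(grids) <- others
  grid <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  base_mass <- as.numeric(as.matrix(grid) %*% .ISOTOPE_MASS[others])

  m_h <- unname(.ISOTOPE_MASS["H"])
  rem <- mass - base_mass
  rows <- list()
  for (dh in -1:1) {
    h <- round(rem / m_h) + dh
    ok <- h >= 0 & h <= h_max & abs(rem - h * m_h) <= tol_da
    if (!any(ok)) next
    sub <- grid[ok, , drop = FALSE]
    sub$H <- h[ok]
    rows[[length(rows) + 1L]] <- sub
  }
  if (!length(rows)) return(.empty_candidates(names(bounds)))
  cand <- unique(do.call(rbind, rows))

  els <- intersect(c("C", "H", "D", sort(names(bounds))), names(bounds))
  cand <- cand[, els, drop = FALSE]
  cmass <- as.numeric(as.matrix(cand) %*% .ISOTOPE_MASS[els])
  ppm <- (cmass - mass) / mass * 1e6

  cnt <- function(el) if (el %in% els) cand[[el]] else 0
  rdbe_v <- cnt("C") + 1 + (cnt("N") + cnt("P")) / 2 -
    (cnt("H") + cnt("D") + cnt("Na") + cnt("K")) / 2
  keep <- rep(TRUE, nrow(cand))
  if (!is.null(rdbe_min)) keep <- keep & rdbe_v >= rdbe_min
  if (rdbe_integer) keep <- keep & (rdbe_v == round(rdbe_v))
  if (use_nitrogen_rule) {
    nominal <- as.numeric(as.matrix(cand) %*% .NOMINAL_MASS[els])
    keep <- keep & ((nominal %% 2 == 1) == (cnt("N") %% 2 == 1))
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(.empty_candidates(names(bounds)))
  cmass <- cmass[keep]; ppm <- ppm[keep]; rdbe_v <- rdbe_v[keep]

  atoms <- rowSums(cand)
  ord <- order(abs(ppm), atoms)
  cand <- cand[ord, , drop = FALSE]
  out <- data.frame(
    formula = vapply(seq_len(nrow(cand)), function(i)
      format_formula(setNames(as.numeric(cand[i, ]), colnames(cand))),
      character(1)),
    cand,
    mass = cmass[ord], ppm = ppm[ord], rdbe = rdbe_v[ord],
    atoms = atoms[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("formula_candidates", "data.frame")
  out
}

.empty_candidates <- function(elements) {
  els <- intersect(c("C", "H", "D", sort(elements)), elements)
  out <- cbind(
    data.frame(formula = character(0), stringsAsFactors = FALSE),
    as.data.frame(setNames(rep(list(numeric(0)), length(els)), els)),
    data.frame(mass = numeric(0), ppm = numeric(0), rdbe = numeric(0),
               atoms = numeric(0))
  )
  class(out) <- c("formula_candidates", "data.frame")
  out
}
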