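# Independent oracles used to freeze expected values. These deliberately
# re-state isotope masses and use plain nested loops so they share no code
# with the package implementation.

oracle_mass <- c(C = 12.0, H = 1.00782503207, N = 14.0030740044,
                 O = 15.9949146196, D = 2.01410177812, S = 31.9720711744)

# hand-summed monoisotopic mass from a named count vector
oracle_mono <- function(counts) {
  s <- 0
  for (el in names(counts)) s <- s + oracle_mass[[el]] * counts[[el]]
  s
}

# exhaustive nested-loop formula enumeration over a CHNO lattice
oracle_enumerate <- function(mass, tol_ppm, cmax, hmax, nmax, omax,
                             rdbe_integer = TRUE, nitrogen_rule = TRUE) {
  tol <- mass * tol_ppm * 1e-6
  out <- list()
  for (C in 0:cmax) for (H in 0:hmax) for (N in 0:nmax) for (O in 0:omax) {
    m <- C * oracle_mass[["C"]] + H * oracle_mass[["H"]] +
      N * oracle_mass[["N"]] + O * oracle_mass[["O"]]
    if (abs(m - mass) > tol) next
    r <- C - H / 2 + N / 2 + 1
    if (r < 0 || (rdbe_integer && r != round(r))) next
    if (nitrogen_rule) {
      nominal <- 12 * C + H + 14 * N + 16 * O
      if ((nominal %% 2 == 1) != (N %% 2 == 1)) next
    }
    out[[length(out) + 1L]] <- c(C = C, H = H, N = N, O = O)
  }
  if (!length(out)) return(matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL, c("C","H","N","O"))))
  do.call(rbind, out)
}

# canonical string set for comparing candidate sets regardless of order
formula_set <- function(m) {
  if (!nrow(m)) return(character(0))
  sort(apply(m, 1, function(r) paste(names(r), r, sep = ":", collapse = " ")))
}

# random valid CHNOS count vector for property tests
random_formula <- function() {
  els <- c("C", "H", "N", "O", "S")
  n <- sample(2:5, 1)
  pick <- sample(els, n)
  setNames(sample(0:40, n, replace = TRUE), pick)
}
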