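# Small hand-built datasets shared across tests.

toy_plate_map <- function() {
  data.frame(
    well = c("A01", "A02", "A03", "A04"),
    role = c("elicitor", "elicitor", "control", "control"),
    elicitor = c("drugX", "drugY", NA, NA),
    concentration_uM = c(16, 16, 0, 0),
    replicate = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

toy_features <- function() {
  data.frame(
    well = c("A01", "A02", "A03"),
    mz = c(417.2931, 417.2930, 417.2932),
    rt = c(7.2, 7.21, 7.19),
    intensity = c(5000, 1200, 1000),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() plate_dataset(toy_features(), toy_plate_map())

# a small screen with one fold-5 family responsive to drug_037
small_screen <- function(seed = 101, fold = 5, elicitor = "drug_037",
                         n_elicitors = 50) {
  fam <- screen_family(mz = 500.25 + 14.01565 * (0:2),
                       rt = c(7, 7.4, 7.8),
                       fragments = c(163.0726, 145.0618),
                       elicitors = elicitor, fold = fold)
  cfg <- screen_config(n_elicitors = n_elicitors, n_controls = 6,
                       n_baseline = 60, families = list(fam))
  simulate_screen_plate(cfg, seed = seed)
}
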