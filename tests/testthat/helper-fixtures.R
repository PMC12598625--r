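# Shared heavy fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fx$ref)) {
    .fx$registry <- default_registry()
    .fx$ref <- synth_family_sequences(.fx$registry, seed = 7)
  }
  list(registry = .fx$registry, ref = .fx$ref)
}

# full 14-family panel over the synthetic target database
fixture_panel <- function() {
  if (is.null(.fx$panel)) {
    fx <- fixture_ref()
    .fx$tdb <- dereplicate(fx$ref$variants)
    .fx$panel <- design_panel(.fx$tdb)
  }
  list(tdb = .fx$tdb, panel = .fx$panel)
}

# calibrated protein db over all consensus proteins (families + decoys)
fixture_pdb <- function() {
  if (is.null(.fx$pdb)) {
    fx <- fixture_ref()
    .fx$pdb <- calibrate_protein_db(
      protein_db(fx$ref$proteins, family = names(fx$ref$proteins)),
      seed = 99)
  }
  .fx$pdb
}

# the 6-family non-homolog benchmark mock (used by several tests)
fixture_mock6 <- function() {
  if (is.null(.fx$mock6)) {
    fx <- fixture_ref()
    fams6 <- c("nifH", "nirK", "nirS", "nosZ", "mmoX", "mcrA")
    strains <- data.frame(
      name = paste0("strain", 1:6), kind = "genome",
      length_bp = c(40000, 36000, 44000, 40000, 38000, 42000),
      gc = c(45, 50, 55, 60, 48, 62), stringsAsFactors = FALSE)
    copies <- matrix(0L, 6, length(fams6),
                     dimnames = list(strains$name, fams6))
    copies[1, "nifH"] <- 2; copies[1, "nosZ"] <- 1
    copies[2, "nirK"] <- 1; copies[2, "nirS"] <- 2
    copies[3, "nosZ"] <- 3; copies[3, "mcrA"] <- 1
    copies[4, "mmoX"] <- 2; copies[4, "nirK"] <- 2
    copies[5, "mcrA"] <- 2; copies[5, "nifH"] <- 1
    copies[6, "nirS"] <- 1; copies[6, "mmoX"] <- 1; copies[6, "nosZ"] <- 1
    tdb <- dereplicate(fx$ref$variants[fx$ref$variants$family %in% fams6, ])
    panel <- design_panel(tdb)
    design <- mock_design(strains, copies, target_gc = 53)
    comm <- synth_community(strains, copies, fx$ref$consensus, seed = 21)
    pdb <- calibrate_protein_db(
      protein_db(fx$ref$proteins[fams6], fams6), seed = 25)
    .fx$mock6 <- list(families = fams6, strains = strains, copies = copies,
                      panel = panel, design = design, comm = comm, pdb = pdb)
  }
  .fx$mock6
}
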