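#' Registry of the literature ligand fixtures
#'
#' The worked molecules the package is validated against: aspirin and the
#' three GA-derived aspirin variants, the tuned-run molecule and its
#' hand-edited redesign, the acyclic fluorinated pair, and simeprevir (in
#' non-isomeric and isomeric form) with its three GA-derived variants.
#'
#' Expected properties are the package's ground truth: heavy-atom count,
#' SSSR ring count, donors, acceptors (N+O), integer-rounded molecular mass,
#' rotatable dihedrals under the package convention, and stereoisomer count
#' (2^k over tetrahedral centers plus acyclic stereogenic double bonds).
#' `strict` marks fixtures that satisfy the valence model exactly; the
#' edited design (`aspirin_edited`) is printed with a pentavalent ring
#' carbon and parses only leniently.
#'
#' @return data.frame, one fixture per row.
#' @export
fixture_registry <- function() {
  rows <- list(
    list("aspirin", "CC(=O)OC1=CC=CC=C1C(=O)O",
         13L, 1L, 1L, 4L, 180L, 3L, 1L, TRUE),
    list("aspirin_prime_1", "CC(=O)C(=O)OC=CC=CC=CC(=O)O",
         15L, 0L, 1L, 5L, 210L, 6L, 8L, TRUE),
    list("aspirin_prime_2", "C(=C)C(=O)CC(=O)OC1=CC=CC=C1C(=O)O",
         17L, 1L, 1L, 5L, 234L, 6L, 1L, TRUE),
    list("aspirin_prime_3", "CC(=O)OC=CC=CC=CC(=O)O",
         13L, 0L, 1L, 4L, 182L, 5L, 8L, TRUE),
    list("aspirin_tuned", "C3CCC3=CC=C4C=C4OC=COC1=CC=C2C=C1CC2",
         21L, 4L, 0L, 2L, 278L, 5L, 4L, TRUE),
    list("aspirin_edited", "C1C=CC=C1=CCC=CNCCOC2=CC=CC=C2",
         19L, 2L, 1L, 2L, 254L, 7L, 4L, FALSE),
    list("aspirin_acyclic_1", "C(C)(F)C(=O)ON=CCCC=CC(=O)O",
         15L, 0L, 1L, 5L, 217L, 7L, 4L, TRUE),
    list("aspirin_acyclic_2", "C(F)C(=O)ON=CCCC=CC(=O)O",
         14L, 0L, 1L, 5L, 203L, 7L, 2L, TRUE),
    list("simeprevir",
         paste0("CC1=C(C=CC2=C1N=C(C=C2OC3CC4C(C3)C(=O)N(CCCCC=CC5CC5(NC4=O)",
                "C(=O)NS(=O)(=O)C6CC6)C)C7=NC(=CS7)C(C)C)OC"),
         52L, 7L, 2L, 12L, 750L, 8L, 32L, TRUE),
    list("simeprevir_isomeric",
         paste0("CC1=C(C=CC2=C1N=C(C=C2O[C@@H]3C[C@@H]4[C@@H](C3)C(=O)N(CCCC",
                "/C=C\\[C@@H]5C[C@]5(NC4=O)C(=O)NS(=O)(=O)C6CC6)C)C7=NC(=CS7)",
                "C(C)C)OC"),
         52L, 7L, 2L, 12L, 750L, 8L, 32L, TRUE),
    list("simeprevir_prime_1",
         paste0("CC=C(C=CC1=CN=C(C=C1OC2CCC(C2)CN(C#CCCC=CN3CC3(NC=O)C(=O)NS",
                "(=O)(=O)C4CC4)C)C=NC(=CS)C(C)C)OC"),
         51L, 4L, 2L, 12L, 739L, 19L, 128L, TRUE),
    list("simeprevir_prime_2",
         paste0("CC1=C(C=CC2=C1N=C(C=C2OC3CCC(C37)C(=O)N(C(S)C7C#CC=CC4CC4(N",
                "C=O)CNS(=O)(=O)C5C(O)C5)C)C6=NC(=CS6)C(C)C)OC"),
         53L, 7L, 3L, 12L, 780L, 13L, 1024L, TRUE),
    list("simeprevir_prime_3",
         paste0("CC=C(C=CC2=CN=C(C=C2OC3CCC(C3)NS(=O)(=O)C1CC1)C=NC(=CS)C(C)",
                "C)OC"),
         34L, 3L, 1L, 7L, 506L, 11L, 32L, TRUE)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], smiles = r[[2]], heavy_atoms = r[[3]],
               n_rings = r[[4]], hbd = r[[5]], hba = r[[6]],
               mass_round = r[[7]], rotatable_dihedrals = r[[8]],
               n_stereoisomers = r[[9]], strict = r[[10]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fetch one fixture SMILES by name
#' @param name registry name, e.g. "aspirin" or "simeprevir".
#' @return the SMILES string.
#' @export
fixture_smiles <- function(name) {
  reg <- fixture_registry()
  hit <- match(name, reg$name)
  if (is.na(hit)) {
    mol_error(sprintf("unknown fixture '%s' (have: %s)", name,
                      paste(reg$name, collapse = ", ")), "io_error")
  }
  reg$smiles[hit]
}

#' Recompute and verify every fixture's expected properties
#'
#' @param molecular a [molecular_config()].
#' @return data.frame with one row per (fixture, property): expected,
#'   computed, ok.
#' @export
verify_fixtures <- function(molecular = molecular_config()) {
  reg <- fixture_registry()
  rows <- list()
  for (k in seq_len(nrow(reg))) {
    g <- parse_smiles(reg$smiles[k], molecular, strict = reg$strict[k])
    p <- compute_properties(g)
    got <- c(heavy_atoms = p$heavy_atoms,
             n_rings = p$n_rings,
             hbd = p$hbd,
             hba = p$hba,
             mass_round = round(p$molecular_mass),
             rotatable_dihedrals = p$rotatable_dihedrals,
             n_stereoisomers = 2^(p$n_tetra_centers + p$n_stereo_dbs))
    for (prop in names(got)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = reg$name[k], property = prop,
        expected = reg[[prop]][k], computed = unname(got[[prop]]),
        ok = reg[[prop]][k] == got[[prop]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
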