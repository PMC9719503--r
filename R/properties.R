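#' Default atomic mass table (Daltons)
#'
#' Heavy-atom masses for the standard alphabet plus hydrogen at 1.008 Da
#' (needed to price the implicit hydrogens).
#' @return named numeric vector.
#' @export
default_atomic_masses <- function() {
  c(C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.065, F = 18.998,
    H = 1.008)
}

#' Read a two-column element/mass table
#' @param path text file with element symbol and mass per line.
#' @return named numeric vector.
#' @export
read_mass_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("element", "mass"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$mass, tab$element)
}

# amide-style C-N single bonds: carbon carries a double-bonded O
is_amide_cn_bond <- function(graph, adj = adjacency(graph)) {
  b <- graph$bonds
  m <- nrow(b)
  out <- logical(m)
  if (!m) return(out)
  has_carbonyl <- vapply(seq_len(n_atoms(graph)), function(a) {
    if (graph$element[a] != "C") return(FALSE)
    nb <- adj[[a]]
    if (is.null(nb)) return(FALSE)
    any(nb[, 2] == 2L & graph$element[nb[, 1]] == "O")
  }, TRUE)
  for (r in seq_len(m)) {
    if (b[r, 3] != 1L) next
    x <- b[r, 1]; y <- b[r, 2]
    ex <- graph$element[x]; ey <- graph$element[y]
    if ((ex == "C" && ey == "N" && has_carbonyl[x]) ||
        (ex == "N" && ey == "C" && has_carbonyl[y])) {
      out[r] <- TRUE
    }
  }
  out
}

#' Count rotatable dihedral bonds
#'
#' Convention: a non-ring single bond whose two endpoints each have at least
#' two heavy-atom neighbours, excluding carboxamide C(=O)-N bonds. This single
#' rule reproduces the printed flexibility of aspirin (3), the edited
#' 19-heavy-atom design (7), the vinyl aspirin variant (6) and simeprevir (8).
#'
#' @param graph a `mol_graph`.
#' @return integer count.
#' @export
count_rotatable_dihedrals <- function(graph) {
  m <- n_bonds(graph)
  if (!m) return(0L)
  b <- graph$bonds
  deg <- heavy_degree(graph)
  nonring <- bond_is_bridge(graph)
  amide <- is_amide_cn_bond(graph)
  sum(b[, 3] == 1L & nonring & deg[b[, 1]] >= 2L & deg[b[, 2]] >= 2L & !amide)
}

#' Structural and ADME-relevant property profile of a molecule
#'
#' Heavy-atom count, molecular mass (implicit hydrogens priced at 1.008 Da),
#' Lipinski-style donor/acceptor counts (donors: N/O bearing at least one H;
#' acceptors: N plus O count), rotatable dihedrals, ring census and stereo
#' element counts. The octanol-water partition coefficient is never computed;
#' it is carried through as a user-supplied input when available.
#'
#' @param graph a `mol_graph`.
#' @param masses atomic mass table covering the alphabet plus H.
#' @param log_kow optional user-supplied log K_ow.
#' @param hba_override optional acceptor count to use in place of N+O (for
#'   pharmacophore-style literature counts).
#' @param stereo compute stereo element counts (set FALSE to skip the
#'   refinement work when only scalar descriptors are needed).
#' @return an object of class `property_profile`.
#' @export
compute_properties <- function(graph, masses = default_atomic_masses(),
                               log_kow = NULL, hba_override = NULL,
                               stereo = TRUE) {
  els <- unique(graph$element)
  missing <- setdiff(c(els, "H"), names(masses))
  if (length(missing)) {
    mol_error(sprintf("mass table lacks entries for: %s",
                      paste(missing, collapse = ",")),
              "config_error")
  }
  mass <- sum(masses[graph$element]) + sum(graph$implicit_h) * masses[["H"]]
  is_no <- graph$element %in% c("N", "O")
  hbd <- sum(is_no & graph$implicit_h >= 1L)
  hba <- if (is.null(hba_override)) sum(is_no) else as.integer(hba_override)
  nonbridge <- !bond_is_bridge(graph)
  if (stereo) {
    st <- find_stereo_elements(graph)
    n_tetra <- length(st$tetra_centers)
    n_sdb <- length(st$stereo_double_bonds)
  } else {
    n_tetra <- NA_integer_
    n_sdb <- NA_integer_
  }
  structure(list(
    heavy_atoms = n_atoms(graph),
    molecular_mass = unname(mass),
    hbd = hbd,
    hba = hba,
    rotatable_dihedrals = count_rotatable_dihedrals(graph),
    n_rings = max(0L, n_bonds(graph) - n_atoms(graph) + 1L),
    n_ring_bonds = sum(nonbridge),
    n_tetra_centers = n_tetra,
    n_stereo_dbs = n_sdb,
    log_kow = if (is.null(log_kow)) NA_real_ else as.numeric(log_kow)
  ), class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf(paste0("<property_profile> heavy=%d mass=%.2f hbd=%d hba=%d ",
                     "rot=%d rings=%d tetra=%s stereo_db=%s log_kow=%s\n"),
              x$heavy_atoms, x$molecular_mass, x$hbd, x$hba,
              x$rotatable_dihedrals, x$n_rings,
              as.character(x$n_tetra_centers), as.character(x$n_stereo_dbs),
              ifelse(is.na(x$log_kow), "-", format(x$log_kow))))
  invisible(x)
}

# profile vector the surrogate site scorer consumes
profile_vector <- function(profile) {
  c(heavy_atoms = profile$heavy_atoms,
    hbd = profile$hbd,
    hba = profile$hba,
    n_rings = profile$n_rings,
    rotatable_dihedrals = profile$rotatable_dihedrals)
}
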