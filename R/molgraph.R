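#' Molecular configuration
#'
#' Atom alphabet, valence model and structural limits used by the parser and
#' the mutation operators. Defaults follow the standard neutral-organic
#' alphabet C, N, O, P, S, F with valences 4, 3, 2, 3, 2, 1.
#'
#' Sulfur is special-cased on input: the parser accepts S at valence 2, 4 or 6
#' so that sulfonamide-bearing drugs (S(=O)(=O)) parse, while mutation
#' operators only ever create divalent S.
#'
#' @param atom_type character vector of allowed element symbols.
#' @param atom_val named integer vector of valences, one per element.
#' @param unnorm_percent_atom unnormalized draw weights per element used when
#'   an operator inserts or substitutes an atom.
#' @param max_tries number of retries for random site selection in operators.
#' @param min_heavy_atoms minimum heavy-atom count for chromosomes admitted to
#'   a population; deletions never shrink a molecule below it.
#' @param max_stereoisomers cap on enumerated stereoisomers per molecule.
#' @param cutoff_bond_percentage tolerance factor applied to tabulated bond
#'   lengths when a 3D-capable scorer supplies coordinates (geometric ring
#'   post-filter; inert in the 3D-free core).
#' @param inter_bond_distance matrix of single-bond lengths (Angstrom) per
#'   element pair; used only by the optional geometric post-filter.
#' @return a list of class `molecular_config`.
#' @export
molecular_config <- function(atom_type = c("C", "N", "O", "P", "S", "F"),
                             atom_val = c(C = 4L, N = 3L, O = 2L, P = 3L, S = 2L, F = 1L),
                             unnorm_percent_atom = stats::setNames(rep(1, length(atom_type)), atom_type),
                             max_tries = 20L,
                             min_heavy_atoms = 10L,
                             max_stereoisomers = 512L,
                             cutoff_bond_percentage = 1.10,
                             inter_bond_distance = default_bond_lengths()) {
  stopifnot(length(atom_type) >= 1, all(atom_type %in% names(atom_val)),
            max_tries >= 1, min_heavy_atoms >= 1, max_stereoisomers >= 1)
  structure(list(
    atom_type = atom_type,
    atom_val = atom_val[atom_type],
    unnorm_percent_atom = unnorm_percent_atom[atom_type],
    max_tries = as.integer(max_tries),
    min_heavy_atoms = as.integer(min_heavy_atoms),
    max_stereoisomers = as.integer(max_stereoisomers),
    cutoff_bond_percentage = cutoff_bond_percentage,
    inter_bond_distance = inter_bond_distance
  ), class = "molecular_config")
}

#' Tabulated single-bond lengths (Angstrom)
#' @return symmetric matrix over C, N, O, P, S, F.
#' @export
default_bond_lengths <- function() {
  el <- c("C", "N", "O", "P", "S", "F")
  m <- matrix(NA_real_, 6, 6, dimnames = list(el, el))
  set <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set("C", "C", 1.53); set("C", "N", 1.49); set("C", "O", 1.43)
  set("C", "P", 1.82); set("C", "S", 1.81); set("C", "F", 1.40)
  set("N", "N", 1.45); set("N", "O", 1.46); set("N", "P", 1.68)
  set("N", "S", 1.77); set("N", "F", 1.30)
  set("O", "O", 1.49); set("O", "P", 1.61); set("O", "S", 1.52)
  set("O", "F", 1.21)
  set("P", "P", 2.18); set("P", "S", 2.12); set("P", "F", 1.67)
  set("S", "S", 2.05); set("S", "F", 1.61)
  m
}

# valences an element may take on input; only S is promotable
allowed_valences <- function(element, config) {
  if (element == "S") c(2L, 4L, 6L) else config$atom_val[[element]]
}

mol_error <- function(msg, class) {
  stop(structure(class = c(class, "evoligand_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

new_mol_graph <- function(element, bonds, config, source_smiles = NA_character_,
                          ring_closure = NULL, strict = TRUE) {
  n <- length(element)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3)
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("i", "j", "order")
  # valence bookkeeping: assign the smallest allowed valence >= bond-order sum
  bsum <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds[r, 1]] <- bsum[bonds[r, 1]] + bonds[r, 3]
      bsum[bonds[r, 2]] <- bsum[bonds[r, 2]] + bonds[r, 3]
    }
  }
  implicit_h <- integer(n)
  valence_ok <- logical(n)
  valence <- integer(n)
  for (a in seq_len(n)) {
    vals <- allowed_valences(element[a], config)
    fit <- vals[vals >= bsum[a]]
    if (length(fit)) {
      valence[a] <- min(fit)
      valence_ok[a] <- TRUE
    } else {
      valence[a] <- max(vals)
      valence_ok[a] <- FALSE
    }
    implicit_h[a] <- max(0L, valence[a] - bsum[a])
  }
  if (strict && !all(valence_ok)) {
    bad <- which(!valence_ok)
    mol_error(sprintf("valence violation at atom(s) %s (%s)",
                      paste(bad, collapse = ","),
                      paste(element[bad], collapse = ",")),
              "smiles_valence_error")
  }
  if (is.null(ring_closure)) ring_closure <- rep(FALSE, nrow(bonds))
  structure(list(
    element = element,
    implicit_h = implicit_h,
    valence = valence,
    valence_ok = valence_ok,
    bonds = bonds,
    ring_closure = ring_closure,
    source_smiles = source_smiles
  ), class = "mol_graph")
}

#' Parse a Kekule SMILES string into a molecular graph
#'
#' The dialect is deliberately narrow: uppercase atoms from the configured
#' alphabet, bonds `-`, `=`, `#` (directional `/` and `\` read as single),
#' branches in parentheses, ring closures `1`-`9` and `%nn`, and bracket atoms
#' such as `[C@@H]` whose stereo marks are accepted and dropped (chromosomes
#' are non-isomeric). Aromatic lowercase tokens are not part of the alphabet.
#'
#' Implicit hydrogens are assigned to fill each atom's valence. With
#' `strict = TRUE` (the chromosome contract) any atom whose bond orders exceed
#' its largest allowed valence raises a `smiles_valence_error`; with
#' `strict = FALSE` the graph is returned with implicit hydrogens floored at
#' zero and per-atom flags in `$valence_ok`, which permits measuring printed
#' literature structures that are not strictly valence-correct.
#'
#' @param text a SMILES string.
#' @param config a [molecular_config()].
#' @param strict error on valence violations (default) or record them.
#' @return an object of class `mol_graph` with fields `element`, `implicit_h`,
#'   `valence`, `bonds` (matrix i, j, order), `ring_closure` (logical per
#'   bond: written as a ring-closure digit pair) and `source_smiles`.
#' @export
parse_smiles <- function(text, config = molecular_config(), strict = TRUE) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    mol_error("SMILES must be a single nonempty string", "smiles_syntax_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  element <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0); bring <- logical(0)
  prev <- NA_integer_
  pend <- NA_integer_
  stack <- integer(0)
  ring_open <- list() # digit label -> list(atom, order)
  bond_orders <- c("-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L, "#" = 3L)

  add_atom <- function(el) {
    if (!el %in% config$atom_type) {
      mol_error(sprintf("element '%s' not in alphabet [%s]", el,
                        paste(config$atom_type, collapse = "")),
                "smiles_syntax_error")
    }
    element <<- c(element, el)
    a <- length(element)
    if (!is.na(prev)) {
      bi <<- c(bi, prev); bj <<- c(bj, a)
      bo <<- c(bo, if (is.na(pend)) 1L else pend)
      bring <<- c(bring, FALSE)
    } else if (!is.na(pend)) {
      mol_error("bond symbol before first atom", "smiles_syntax_error")
    }
    prev <<- a
    pend <<- NA_integer_
    invisible(a)
  }
  close_ring <- function(lab) {
    if (is.na(prev)) mol_error("ring digit before any atom", "smiles_syntax_error")
    key <- as.character(lab)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      order <- if (!is.na(pend)) pend else if (!is.na(op$order)) op$order else 1L
      if (!is.na(pend) && !is.na(op$order) && pend != op$order) {
        mol_error(sprintf("conflicting bond orders on ring closure %s", key),
                  "smiles_syntax_error")
      }
      if (op$atom == prev) mol_error("ring closure to self", "smiles_syntax_error")
      if (any((bi == op$atom & bj == prev) | (bi == prev & bj == op$atom))) {
        mol_error("duplicate bond via ring closure", "smiles_syntax_error")
      }
      bi <<- c(bi, op$atom); bj <<- c(bj, prev)
      bo <<- c(bo, order); bring <<- c(bring, TRUE)
    } else {
      ring_open[[key]] <<- list(atom = prev, order = pend)
    }
    pend <<- NA_integer_
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch %in% names(bond_orders)) {
      pend <- bond_orders[[ch]]
      k <- k + 1L
    } else if (ch == "(") {
      if (is.na(prev)) mol_error("branch before first atom", "smiles_syntax_error")
      stack <- c(stack, prev)
      k <- k + 1L
    } else if (ch == ")") {
      if (!length(stack)) mol_error("unbalanced ')'", "smiles_syntax_error")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- k + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      k <- k + 1L
    } else if (ch == "%") {
      if (k + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[k + 1L], chars[k + 2L]))) {
        mol_error("'%' must be followed by two digits", "smiles_syntax_error")
      }
      close_ring(paste0(chars[k + 1L], chars[k + 2L]))
      k <- k + 3L
    } else if (ch == "[") {
      end <- k
      while (end <= n && chars[end] != "]") end <- end + 1L
      if (end > n) mol_error("unterminated bracket atom", "smiles_syntax_error")
      body <- paste(chars[(k + 1L):(end - 1L)], collapse = "")
      el <- regmatches(body, regexpr("^[A-Z][a-z]?", body))
      if (!length(el)) mol_error(sprintf("bad bracket atom [%s]", body), "smiles_syntax_error")
      # stereo marks (@, @@) and explicit H counts are recorded only via the
      # valence model; chromosomes are non-isomeric
      add_atom(el)
      k <- end + 1L
    } else if (grepl("[A-Z]", ch)) {
      add_atom(ch)
      k <- k + 1L
    } else {
      mol_error(sprintf("unexpected character '%s' at position %d", ch, k),
                "smiles_syntax_error")
    }
  }
  if (length(stack)) mol_error("unbalanced '('", "smiles_syntax_error")
  if (length(ring_open)) {
    mol_error(sprintf("unmatched ring closure digit(s): %s",
                      paste(names(ring_open), collapse = ",")),
              "smiles_syntax_error")
  }
  if (!length(element)) mol_error("no atoms in SMILES", "smiles_syntax_error")
  bonds <- cbind(i = bi, j = bj, order = bo)
  g <- new_mol_graph(element, bonds, config, source_smiles = text,
                     ring_closure = bring, strict = strict)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d heavy atoms, %d bonds, formula %s\n",
              n_atoms(x), n_bonds(x), molecular_formula(x)))
  if (!is.na(x$source_smiles)) cat("  source:", x$source_smiles, "\n")
  invisible(x)
}

#' Number of heavy atoms / bonds in a graph
#' @param graph a `mol_graph`.
#' @return integer count.
#' @export
n_atoms <- function(graph) length(graph$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(graph) nrow(graph$bonds)

#' Molecular formula (Hill-ish ordering, implicit H included)
#' @param graph a `mol_graph`.
#' @return a string such as "C9H8O4".
#' @export
molecular_formula <- function(graph) {
  counts <- table(graph$element)
  h <- sum(graph$implicit_h)
  els <- c("C", "H", setdiff(sort(names(counts)), c("C", "H")))
  out <- ""
  for (el in els) {
    k <- if (el == "H") h else if (el %in% names(counts)) counts[[el]] else 0L
    if (k > 0) out <- paste0(out, el, if (k > 1) k else "")
  }
  out
}

# adjacency list: for each atom, data.frame-free list of (nbr, order, bond)
adjacency <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  b <- graph$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- rbind(adj[[b[r, 1]]], c(b[r, 2], b[r, 3], r))
      adj[[b[r, 2]]] <- rbind(adj[[b[r, 2]]], c(b[r, 1], b[r, 3], r))
    }
  }
  adj
}

heavy_degree <- function(graph) {
  n <- n_atoms(graph)
  d <- integer(n)
  b <- graph$bonds
  if (nrow(b)) {
    t1 <- tabulate(b[, 1], n)
    t2 <- tabulate(b[, 2], n)
    d <- t1 + t2
  }
  d
}

bond_order_sum <- function(graph) {
  n <- n_atoms(graph)
  s <- integer(n)
  b <- graph$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      s[b[r, 1]] <- s[b[r, 1]] + b[r, 3]
      s[b[r, 2]] <- s[b[r, 2]] + b[r, 3]
    }
  }
  s
}

# connectivity check via DFS over the bond list
is_connected_graph <- function(graph) {
  n <- n_atoms(graph)
  if (n <= 1) return(TRUE)
  adj <- adjacency(graph)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    a <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[a]]
    if (!is.null(nb)) {
      for (v in nb[, 1]) {
        if (!seen[v]) {
          seen[v] <- TRUE
          stack <- c(stack, v)
        }
      }
    }
  }
  all(seen)
}

#' Validity check for a chromosome graph
#'
#' A chromosome is admissible when it is a single connected component and every
#' atom's bond orders are covered by an allowed valence (S may sit at 2, 4 or
#' 6 on input). This is the clash check run after every operator application.
#'
#' @param graph a `mol_graph`.
#' @param config a [molecular_config()].
#' @return TRUE/FALSE.
#' @export
is_valid_graph <- function(graph, config = molecular_config()) {
  if (!n_atoms(graph)) return(FALSE)
  if (!all(graph$valence_ok)) return(FALSE)
  if (!is_connected_graph(graph)) return(FALSE)
  if (nrow(graph$bonds)) {
    key <- paste(pmin(graph$bonds[, 1], graph$bonds[, 2]),
                 pmax(graph$bonds[, 1], graph$bonds[, 2]))
    if (anyDuplicated(key)) return(FALSE)
  }
  TRUE
}

# rebuild a graph from raw pieces after operator surgery; lenient=FALSE so an
# infeasible edit surfaces as a condition the operator layer can catch
rebuild_graph <- function(element, bonds, config, strict = TRUE) {
  new_mol_graph(element, bonds, config, source_smiles = NA_character_,
                ring_closure = NULL, strict = strict)
}

# bridges (cut edges) via Tarjan low-link; returns logical per bond row
bond_is_bridge <- function(graph) {
  n <- n_atoms(graph)
  m <- n_bonds(graph)
  if (!m) return(logical(0))
  adj <- adjacency(graph)
  disc <- integer(n); low <- integer(n)
  bridge <- logical(m)
  timer <- 0L
  # iterative DFS to be safe on long chains
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, parent_bond = 0L, idx = 1L))
    timer <- timer + 1L
    disc[root] <- timer; low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      nb <- adj[[v]]
      if (!is.null(nb) && fr$idx <= nrow(nb)) {
        stack[[length(stack)]]$idx <- fr$idx + 1L
        u <- nb[fr$idx, 1]; bid <- nb[fr$idx, 3]
        if (bid == fr$parent_bond) next
        if (disc[u] == 0L) {
          timer <- timer + 1L
          disc[u] <- timer; low[u] <- timer
          stack[[length(stack) + 1L]] <- list(v = u, parent_bond = bid, idx = 1L)
        } else {
          low[v] <- min(low[v], disc[u])
          stack[[length(stack)]]$low_merge <- TRUE
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) bridge[fr$parent_bond] <- TRUE
        }
      }
    }
  }
  bridge
}

# atoms lying on at least one cycle: incident to a non-bridge edge
atom_in_ring <- function(graph) {
  n <- n_atoms(graph)
  inring <- logical(n)
  if (!n_bonds(graph)) return(inring)
  br <- bond_is_bridge(graph)
  b <- graph$bonds
  for (r in which(!br)) {
    inring[b[r, 1]] <- TRUE
    inring[b[r, 2]] <- TRUE
  }
  inring
}
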