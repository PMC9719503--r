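#' The mutation alphabet
#'
#' The fourteen named molecular mutations. OPEN_BOND (scission of general
#' in-ring bonds rather than ring-closure bonds) is deliberately absent.
#' @return character vector of operator names.
#' @export
mutation_kinds <- function() {
  c("CHANGE_ATOM", "ADD_ATOM", "DELETE_ATOM", "ADD_BRANCH", "DELETE_BRANCH",
    "CLOSE_RING", "OPEN_RING", "INTERCHANGE_DIHEDRAL",
    "SINGLE_DOUBLE_BOND", "DOUBLE_SINGLE_BOND",
    "SINGLE_TRIPLE_BOND", "TRIPLE_SINGLE_BOND",
    "DOUBLE_TRIPLE_BOND", "TRIPLE_DOUBLE_BOND")
}

#' Operator configuration
#'
#' Mutation dispatch weights are keyed by operator name (robust to enabling or
#' disabling operators), unnormalized, and normalized at use.
#'
#' @param unnorm_mut_probability named nonnegative weights over
#'   [mutation_kinds()]; unnamed defaults to uniform.
#' @param molecular a [molecular_config()] providing the atom alphabet,
#'   valences, atom draw weights and structural limits.
#' @return list of class `operator_config`.
#' @export
operator_config <- function(unnorm_mut_probability = NULL,
                            molecular = molecular_config()) {
  kinds <- mutation_kinds()
  if (is.null(unnorm_mut_probability)) {
    unnorm_mut_probability <- stats::setNames(rep(1, length(kinds)), kinds)
  } else {
    bad <- setdiff(names(unnorm_mut_probability), kinds)
    if (length(bad)) {
      mol_error(sprintf("unknown mutation kind(s): %s", paste(bad, collapse = ",")),
                "config_error")
    }
    w <- stats::setNames(rep(0, length(kinds)), kinds)
    w[names(unnorm_mut_probability)] <- unnorm_mut_probability
    unnorm_mut_probability <- w
  }
  if (any(unnorm_mut_probability < 0) || !any(unnorm_mut_probability > 0)) {
    mol_error("mutation weights must be nonnegative with at least one positive",
              "config_error")
  }
  structure(list(unnorm_mut_probability = unnorm_mut_probability,
                 molecular = molecular),
            class = "operator_config")
}

# uniform draw that is safe for length-1 vectors
draw1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

draw_element <- function(config, min_valence = 1L) {
  mc <- config$molecular
  ok <- mc$atom_val >= min_valence & mc$unnorm_percent_atom > 0
  # operators only ever create divalent S, so the base valence table applies
  if (!any(ok)) return(NA_character_)
  els <- names(mc$atom_val)[ok]
  w <- mc$unnorm_percent_atom[ok]
  els[sample.int(length(els), 1L, prob = w)]
}

operator_failure <- function() structure(list(), class = "operator_failure")
failed <- function(x) inherits(x, "operator_failure")

# ---- elementary operators -------------------------------------------------
# each takes a graph (and pre-drawn random choices where sensible) and returns
# a new valid graph or an operator_failure; the dispatcher owns the retries

op_change_atom <- function(graph, config) {
  bsum <- bond_order_sum(graph)
  mc <- config$molecular
  sites <- which(vapply(seq_len(n_atoms(graph)), function(a) {
    any(mc$atom_val >= bsum[a] & names(mc$atom_val) != graph$element[a] &
          mc$unnorm_percent_atom > 0)
  }, TRUE))
  if (!length(sites)) return(operator_failure())
  a <- draw1(sites)
  ok <- mc$atom_val >= bsum[a] & names(mc$atom_val) != graph$element[a] &
    mc$unnorm_percent_atom > 0
  els <- names(mc$atom_val)[ok]
  el <- els[sample.int(length(els), 1L, prob = mc$unnorm_percent_atom[ok])]
  element <- graph$element
  element[a] <- el
  rebuild_or_fail(element, graph$bonds, config)
}

op_add_atom <- function(graph, config) {
  # two insertion modes: splice into a single bond, or grow a new terminal
  single_bonds <- which(graph$bonds[, 3] == 1L)
  free <- which(graph$implicit_h >= 1L)
  modes <- c(if (length(single_bonds)) "splice", if (length(free)) "terminal")
  if (!length(modes)) return(operator_failure())
  mode <- draw1(modes)
  if (mode == "splice") {
    el <- draw_element(config, min_valence = 2L)
    if (is.na(el)) return(operator_failure())
    r <- draw1(single_bonds)
    x <- graph$bonds[r, 1]; y <- graph$bonds[r, 2]
    element <- c(graph$element, el)
    a <- length(element)
    bonds <- rbind(graph$bonds[-r, , drop = FALSE],
                   c(x, a, 1L), c(a, y, 1L))
    rebuild_or_fail(element, bonds, config)
  } else {
    el <- draw_element(config, min_valence = 1L)
    if (is.na(el)) return(operator_failure())
    x <- draw1(free)
    element <- c(graph$element, el)
    bonds <- rbind(graph$bonds, c(x, length(element), 1L))
    rebuild_or_fail(element, bonds, config)
  }
}

op_delete_atom <- function(graph, config) {
  if (n_atoms(graph) <= config$molecular$min_heavy_atoms) return(operator_failure())
  deg <- heavy_degree(graph)
  adj <- adjacency(graph)
  sites <- which(deg <= 2L & deg >= 1L)
  if (!length(sites)) return(operator_failure())
  a <- draw1(sites)
  nb <- adj[[a]]
  element <- graph$element[-a]
  shift <- function(v) ifelse(v > a, v - 1L, v)
  keep <- graph$bonds[, 1] != a & graph$bonds[, 2] != a
  bonds <- graph$bonds[keep, , drop = FALSE]
  bonds[, 1] <- shift(bonds[, 1]); bonds[, 2] <- shift(bonds[, 2])
  if (deg[a] == 2L) {
    u <- shift(nb[1, 1]); v <- shift(nb[2, 1])
    already <- any((bonds[, 1] == u & bonds[, 2] == v) |
                     (bonds[, 1] == v & bonds[, 2] == u))
    if (!already) bonds <- rbind(bonds, c(u, v, 1L))
  }
  g <- rebuild_or_fail(element, bonds, config)
  if (!failed(g) && !is_connected_graph(g)) return(operator_failure())
  g
}

op_add_branch <- function(graph, config) {
  deg <- heavy_degree(graph)
  sites <- which(graph$implicit_h >= 1L & deg >= 2L)
  if (!length(sites)) return(operator_failure())
  el <- draw_element(config, min_valence = 1L)
  if (is.na(el)) return(operator_failure())
  x <- draw1(sites)
  element <- c(graph$element, el)
  bonds <- rbind(graph$bonds, c(x, length(element), 1L))
  rebuild_or_fail(element, bonds, config)
}

op_delete_branch <- function(graph, config) {
  br <- bond_is_bridge(graph)
  if (!any(br)) return(operator_failure())
  n <- n_atoms(graph)
  min_heavy <- config$molecular$min_heavy_atoms
  adj <- adjacency(graph)
  # candidate: bridge whose smaller side is an acyclic terminal subtree
  side_atoms <- function(r, from) {
    # atoms reachable from `from` without crossing bond r
    seen <- logical(n); seen[from] <- TRUE
    stack <- from
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        if (nb[k, 3] == r) next
        u <- nb[k, 1]
        if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
      }
    }
    which(seen)
  }
  inring <- atom_in_ring(graph)
  deg <- heavy_degree(graph)
  cands <- list()
  for (r in which(br)) {
    for (end in 1:2) {
      s <- side_atoms(r, graph$bonds[r, end])
      if (length(s) >= n) next
      if (any(inring[s])) next              # branch must be a pure subtree
      # the retained anchor must be a genuine branch point: an unbranched
      # chain has no deletable branch
      anchor <- graph$bonds[r, c(2L, 1L)[end]]
      if (deg[anchor] < 3L) next
      if (n - length(s) < min_heavy && n >= min_heavy) next
      cands[[length(cands) + 1L]] <- s
    }
  }
  if (!length(cands)) return(operator_failure())
  s <- cands[[draw1(seq_along(cands))]]
  keep <- setdiff(seq_len(n), s)
  remap <- match(seq_len(n), keep)
  sel <- !(graph$bonds[, 1] %in% s) & !(graph$bonds[, 2] %in% s)
  bonds <- graph$bonds[sel, , drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]
  g <- rebuild_or_fail(graph$element[keep], bonds, config)
  if (!failed(g) && !is_connected_graph(g)) return(operator_failure())
  g
}

op_close_ring <- function(graph, config) {
  free <- which(graph$implicit_h >= 1L)
  if (length(free) < 2) return(operator_failure())
  ig <- atoms_igraph(graph)
  d <- igraph::distances(ig, v = free, to = free)
  pairs <- which(d >= 2 & d <= 7, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(operator_failure())
  k <- draw1(seq_len(nrow(pairs)))
  u <- free[pairs[k, 1]]; v <- free[pairs[k, 2]]
  bonds <- rbind(graph$bonds, c(u, v, 1L))
  rebuild_or_fail(graph$element, bonds, config)
}

op_open_ring <- function(graph, config) {
  # opens at the chromosome's own SMILES ring points (digit-pair bonds), not
  # at arbitrary in-ring bonds; that scission is OPEN_BOND and is excluded
  closures <- which(graph$ring_closure)
  if (!length(closures)) {
    # graph assembled by surgery: recover closure bonds from a fresh traversal
    if (!n_bonds(graph)) return(operator_failure())
    trav <- smiles_traversal(graph)
    closures <- trav$back_edges
  }
  if (!length(closures)) return(operator_failure())
  r <- draw1(closures)
  bonds <- graph$bonds[-r, , drop = FALSE]
  g <- rebuild_graph(graph$element, bonds, config$molecular, strict = FALSE)
  g$ring_closure <- graph$ring_closure[-r]
  if (!is_connected_graph(g) || !all(g$valence_ok)) return(operator_failure())
  g
}

op_change_bond_order <- function(graph, config, from_order, to_order) {
  cand <- which(graph$bonds[, 3] == from_order)
  if (!length(cand)) return(operator_failure())
  if (to_order > from_order) {
    delta <- to_order - from_order
    ok <- graph$implicit_h[graph$bonds[cand, 1]] >= delta &
      graph$implicit_h[graph$bonds[cand, 2]] >= delta
    cand <- cand[ok]
  }
  if (!length(cand)) return(operator_failure())
  r <- draw1(cand)
  bonds <- graph$bonds
  bonds[r, 3] <- to_order
  rebuild_or_fail(graph$element, bonds, config, ring_closure = graph$ring_closure)
}

op_interchange_dihedral <- function(graph, config) {
  br <- bond_is_bridge(graph)
  b <- graph$bonds
  adj <- adjacency(graph)
  n <- n_atoms(graph)
  # acyclic single bond with a detachable (bridge) substituent on both sides
  branch_of <- function(center, avoid) {
    nb <- adj[[center]]
    outs <- nb[nb[, 1] != avoid & br[nb[, 3]], , drop = FALSE]
    outs
  }
  cands <- integer(0)
  for (r in seq_len(n_bonds(graph))) {
    if (b[r, 3] != 1L || !br[r]) next
    u <- b[r, 1]; v <- b[r, 2]
    if (nrow(branch_of(u, v)) >= 1 && nrow(branch_of(v, u)) >= 1) {
      cands <- c(cands, r)
    }
  }
  if (!length(cands)) return(operator_failure())
  r <- draw1(cands)
  u <- b[r, 1]; v <- b[r, 2]
  bu <- branch_of(u, v); bv <- branch_of(v, u)
  eu <- bu[draw1(seq_len(nrow(bu))), ]
  ev <- bv[draw1(seq_len(nrow(bv))), ]
  if (eu[3] == ev[3]) return(operator_failure())
  bonds <- b
  # swap the attachment points of the two substituent branches
  swap_end <- function(bonds, bond_row, from, to) {
    if (bonds[bond_row, 1] == from) bonds[bond_row, 1] <- to else bonds[bond_row, 2] <- to
    bonds
  }
  bonds <- swap_end(bonds, eu[3], u, v)
  bonds <- swap_end(bonds, ev[3], v, u)
  g <- rebuild_or_fail(graph$element, bonds, config)
  if (!failed(g) && !is_connected_graph(g)) return(operator_failure())
  g
}

rebuild_or_fail <- function(element, bonds, config, ring_closure = NULL) {
  g <- tryCatch(
    rebuild_graph(element, bonds, config$molecular, strict = TRUE),
    error = function(e) operator_failure()
  )
  if (failed(g)) return(g)
  if (!is.null(ring_closure) && length(ring_closure) == nrow(g$bonds)) {
    g$ring_closure <- ring_closure
  }
  g
}

apply_mutation_kind <- function(graph, kind, config) {
  switch(kind,
    CHANGE_ATOM = op_change_atom(graph, config),
    ADD_ATOM = op_add_atom(graph, config),
    DELETE_ATOM = op_delete_atom(graph, config),
    ADD_BRANCH = op_add_branch(graph, config),
    DELETE_BRANCH = op_delete_branch(graph, config),
    CLOSE_RING = op_close_ring(graph, config),
    OPEN_RING = op_open_ring(graph, config),
    INTERCHANGE_DIHEDRAL = op_interchange_dihedral(graph, config),
    SINGLE_DOUBLE_BOND = op_change_bond_order(graph, config, 1L, 2L),
    DOUBLE_SINGLE_BOND = op_change_bond_order(graph, config, 2L, 1L),
    SINGLE_TRIPLE_BOND = op_change_bond_order(graph, config, 1L, 3L),
    TRIPLE_SINGLE_BOND = op_change_bond_order(graph, config, 3L, 1L),
    DOUBLE_TRIPLE_BOND = op_change_bond_order(graph, config, 2L, 3L),
    TRIPLE_DOUBLE_BOND = op_change_bond_order(graph, config, 3L, 2L),
    mol_error(sprintf("unknown mutation kind '%s'", kind), "config_error")
  )
}

#' Apply one random molecular mutation
#'
#' Draws an operator by normalized dispatch weight and applies it; infeasible
#' draws are retried up to `max_tries` times, after which the input is
#' returned unchanged (mutation never raises). The result is always a valid
#' connected graph, and never below `min_heavy_atoms` unless the input
#' already was.
#'
#' @param graph a valid `mol_graph`.
#' @param config an [operator_config()].
#' @return a `mol_graph`.
#' @export
mutate_molecule <- function(graph, config = operator_config()) {
  w <- config$unnorm_mut_probability
  kinds <- names(w)[w > 0]
  w <- w[w > 0]
  for (try in seq_len(config$molecular$max_tries)) {
    kind <- kinds[sample.int(length(kinds), 1L, prob = w)]
    out <- apply_mutation_kind(graph, kind, config)
    if (!failed(out)) {
      out$source_smiles <- write_smiles(out)
      # re-parse so ring-closure bookkeeping matches the fresh serialization
      return(parse_smiles(out$source_smiles, config$molecular))
    }
  }
  graph
}

#' Classify the crossover segment rooted at an atom
#'
#' An atom lying on a ring is `ring-blocked` (a ring cannot be split by one
#' cut). Otherwise the segment spans the atom's subtree in the chromosome's
#' own SMILES traversal: `branch` when the atom sits inside a parenthesised
#' branch, `tail` when the span runs to the end of the expression.
#'
#' @param graph a `mol_graph`.
#' @param atom atom index.
#' @return list of class `segment_span` with `anchor`, `kind`, `atoms`.
#' @export
classify_segment <- function(graph, atom) {
  stopifnot(atom >= 1, atom <= n_atoms(graph))
  if (atom_in_ring(graph)[atom]) {
    return(structure(list(anchor = atom, kind = "ring-blocked", atoms = integer(0)),
                     class = "segment_span"))
  }
  trav <- smiles_traversal(graph)
  span <- sort(as.integer(unname(subtree_atoms(trav, atom))))
  # branch iff some ancestor step leaves the last-child ("main chain") path
  kind <- "tail"
  v <- atom
  while (!is.na(trav$parent[v])) {
    p <- trav$parent[v]
    ch <- trav$children[[p]]
    if (ch[length(ch)] != v) { kind <- "branch"; break }
    v <- p
  }
  structure(list(anchor = atom, kind = kind, atoms = span), class = "segment_span")
}

# cut the subtree rooted at `atom` out of the graph; returns remainder,
# segment, the remainder-side attachment atom and the cut-bond order
excise_segment <- function(graph, atom, trav) {
  span <- subtree_atoms(trav, atom)
  pb <- trav$parent_bond[atom]
  attach <- trav$parent[atom]
  order <- graph$bonds[pb, 3]
  n <- n_atoms(graph)
  keep <- setdiff(seq_len(n), span)
  remap_keep <- match(seq_len(n), keep)
  remap_span <- match(seq_len(n), sort(span))
  sel_keep <- !(graph$bonds[, 1] %in% span) & !(graph$bonds[, 2] %in% span)
  sel_span <- (graph$bonds[, 1] %in% span) & (graph$bonds[, 2] %in% span)
  bk <- graph$bonds[sel_keep, , drop = FALSE]
  bk[, 1] <- remap_keep[bk[, 1]]; bk[, 2] <- remap_keep[bk[, 2]]
  bs <- graph$bonds[sel_span, , drop = FALSE]
  bs[, 1] <- remap_span[bs[, 1]]; bs[, 2] <- remap_span[bs[, 2]]
  list(rest_element = graph$element[keep], rest_bonds = bk,
       seg_element = graph$element[sort(span)], seg_bonds = bs,
       attach = remap_keep[attach], seg_root = remap_span[atom], order = order)
}

join_segments <- function(rest, seg, config) {
  element <- c(rest$rest_element, seg$seg_element)
  off <- length(rest$rest_element)
  sb <- seg$seg_bonds
  if (nrow(sb)) { sb[, 1] <- sb[, 1] + off; sb[, 2] <- sb[, 2] + off }
  bonds <- rbind(rest$rest_bonds, sb,
                 c(rest$attach, seg$seg_root + off, rest$order))
  rebuild_or_fail(element, bonds, config)
}

#' Segment-exchange crossover of two chromosomes
#'
#' Picks a random non-ring-blocked, non-root atom in each parent (retrying up
#' to `max_tries` on ring-blocked picks), excises each atom's SMILES subtree
#' and swaps the two right-segments. Each child is re-validated; a child that
#' is invalid or falls below `min_heavy_atoms` is replaced by a copy of its
#' parent, and total failure returns both parents unchanged — crossover never
#' raises.
#'
#' @param parent_a,parent_b valid `mol_graph` parents.
#' @param config an [operator_config()].
#' @return list of two `mol_graph` children.
#' @export
crossover_molecules <- function(parent_a, parent_b, config = operator_config()) {
  mc <- config$molecular
  pick_cut <- function(graph) {
    if (n_atoms(graph) < 2) return(NULL)
    inring <- atom_in_ring(graph)
    trav <- smiles_traversal(graph)
    for (try in seq_len(mc$max_tries)) {
      a <- draw1(setdiff(seq_len(n_atoms(graph)), trav$root))
      if (!inring[a]) return(list(atom = a, trav = trav))
    }
    NULL
  }
  ca <- pick_cut(parent_a)
  cb <- pick_cut(parent_b)
  if (is.null(ca) || is.null(cb)) return(list(parent_a, parent_b))
  ea <- excise_segment(parent_a, ca$atom, ca$trav)
  eb <- excise_segment(parent_b, cb$atom, cb$trav)
  make_child <- function(rest, seg, fallback) {
    g <- join_segments(rest, seg, config)
    if (failed(g) || !is_connected_graph(g) ||
        n_atoms(g) < mc$min_heavy_atoms) {
      return(fallback)
    }
    g$source_smiles <- write_smiles(g)
    parse_smiles(g$source_smiles, mc)
  }
  list(make_child(ea, eb, parent_a), make_child(eb, ea, parent_b))
}
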