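bond_symbol <- function(order) c("", "=", "#")[order]

ring_digit_token <- function(d) if (d <= 9) as.character(d) else sprintf("%%%02d", d)

# DFS traversal of a mol_graph from a root, producing the pieces the writer
# and the crossover segment logic both need: tree parents, visit order, back
# edges, and which atoms sit inside a parenthesised branch.
smiles_traversal <- function(graph, root = 1L) {
  n <- n_atoms(graph)
  adj <- adjacency(graph)
  parent <- rep(NA_integer_, n)       # tree parent atom
  parent_bond <- rep(NA_integer_, n)  # bond row to parent
  order <- integer(0)                 # visit order
  visited <- logical(n)
  tree_children <- vector("list", n)
  back_edges <- integer(0)            # bond rows that are DFS back edges
  stack <- root
  visited[root] <- TRUE
  # iterative DFS preserving adjacency order (stack of iterators)
  frames <- list(list(v = root, idx = 1L))
  order <- root
  used_bond <- logical(n_bonds(graph))
  while (length(frames)) {
    fr <- frames[[length(frames)]]
    v <- fr$v
    nb <- adj[[v]]
    if (!is.null(nb) && fr$idx <= nrow(nb)) {
      frames[[length(frames)]]$idx <- fr$idx + 1L
      u <- nb[fr$idx, 1]; bid <- nb[fr$idx, 3]
      if (used_bond[bid]) next
      used_bond[bid] <- TRUE
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        parent_bond[u] <- bid
        tree_children[[v]] <- c(tree_children[[v]], u)
        order <- c(order, u)
        frames[[length(frames) + 1L]] <- list(v = u, idx = 1L)
      } else {
        back_edges <- c(back_edges, bid)
      }
    } else {
      frames[[length(frames)]] <- NULL
    }
  }
  list(parent = parent, parent_bond = parent_bond, order = order,
       children = tree_children, back_edges = back_edges, root = root)
}

# all atoms in the DFS subtree rooted at `atom`
subtree_atoms <- function(trav, atom) {
  out <- atom
  stack <- atom
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- trav$children[[v]]
    if (length(ch)) {
      out <- c(out, ch)
      stack <- c(stack, ch)
    }
  }
  out
}

#' Serialize a molecular graph to a Kekule SMILES string
#'
#' Depth-first traversal from the first atom; ring-closure digits are freshly
#' numbered 1, 2, ... in traversal order (digits above 9 use the `%nn` form),
#' which is the ring-renumbering step the operators rely on after surgery.
#' No stereo marks are ever written: chromosomes are non-isomeric.
#'
#' @param graph a valid `mol_graph`.
#' @return a SMILES string that re-parses to a graph isomorphic to `graph`.
#' @export
write_smiles <- function(graph) {
  if (!n_atoms(graph)) mol_error("empty graph", "smiles_write_error")
  trav <- smiles_traversal(graph, root = 1L)
  if (length(trav$order) < n_atoms(graph)) {
    mol_error("graph is disconnected", "smiles_write_error")
  }
  b <- graph$bonds
  # assign digits to back edges in order of the opener atom's visit position
  pos <- match(seq_len(n_atoms(graph)), trav$order)
  openers <- vector("list", n_atoms(graph)) # per atom: bond rows it opens
  closers <- vector("list", n_atoms(graph))
  if (length(trav$back_edges)) {
    be <- trav$back_edges
    first_end <- ifelse(pos[b[be, 1]] < pos[b[be, 2]], b[be, 1], b[be, 2])
    last_end <- ifelse(pos[b[be, 1]] < pos[b[be, 2]], b[be, 2], b[be, 1])
    ord <- order(pos[first_end], pos[last_end])
    digit <- seq_along(be)
    for (k in seq_along(be)) {
      e <- be[ord[k]]
      fe <- first_end[ord[k]]; le <- last_end[ord[k]]
      openers[[fe]] <- rbind(openers[[fe]], c(e, k))
      closers[[le]] <- rbind(closers[[le]], c(e, k))
    }
  }
  out <- character(0)
  emit <- function(v, bond_to_parent) {
    s <- if (is.na(bond_to_parent)) "" else bond_symbol(b[bond_to_parent, 3])
    s <- paste0(s, graph$element[v])
    op <- openers[[v]]
    if (!is.null(op)) for (r in seq_len(nrow(op))) s <- paste0(s, ring_digit_token(op[r, 2]))
    cl <- closers[[v]]
    if (!is.null(cl)) {
      for (r in seq_len(nrow(cl))) {
        s <- paste0(s, bond_symbol(b[cl[r, 1], 3]), ring_digit_token(cl[r, 2]))
      }
    }
    ch <- trav$children[[v]]
    if (length(ch) > 1) {
      for (u in ch[-length(ch)]) s <- paste0(s, "(", emit(u, trav$parent_bond[u]), ")")
    }
    if (length(ch)) {
      u <- ch[length(ch)]
      s <- paste0(s, emit(u, trav$parent_bond[u]))
    }
    s
  }
  emit(trav$root, NA_integer_)
}

# igraph handle on the bond-subdivided, vertex-coloured representation:
# atoms keep their element colour, every bond becomes an extra vertex
# coloured by its order. BLISS/VF2 on this graph respect bond orders.
subdivided_igraph <- function(graph) {
  n <- n_atoms(graph)
  m <- n_bonds(graph)
  el_code <- match(graph$element, c("C", "N", "O", "P", "S", "F"))
  el_code[is.na(el_code)] <- 9L
  colors <- c(el_code, 20L + graph$bonds[, 3])
  if (m) {
    edges <- rbind(cbind(graph$bonds[, 1], n + seq_len(m)),
                   cbind(graph$bonds[, 2], n + seq_len(m)))
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  g <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  list(g = g, colors = as.integer(colors), n_atoms = n)
}

#' Canonical deduplication key for a molecular graph
#'
#' Two graphs receive the same key iff they are isomorphic as element- and
#' bond-order-labelled graphs; stereochemistry is ignored. Built on a BLISS
#' canonical permutation of the bond-subdivided, vertex-coloured graph, so it
#' is deterministic across sessions. The key is used only for reporting and
#' deduplication, never as the chromosome itself.
#'
#' @param graph a `mol_graph`.
#' @return a character key.
#' @export
canonical_key <- function(graph) {
  sg <- subdivided_igraph(graph)
  if (igraph::vcount(sg$g) == 1L) {
    return(paste0("v1:", graph$element[1]))
  }
  cp <- igraph::canonical_permutation(sg$g, colors = sg$colors)
  perm <- cp$labeling
  gp <- igraph::permute(sg$g, perm)
  colp <- integer(length(sg$colors))
  colp[perm] <- sg$colors
  e <- igraph::as_edgelist(gp, names = FALSE)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste0("v1:", paste(colp, collapse = ","), ";",
         paste(e[, 1], e[, 2], sep = "-", collapse = ","))
}

#' Test two molecular graphs for labelled-graph isomorphism
#'
#' Elements and bond orders must match; stereo and implicit hydrogens (which
#' are determined by the valence model) are not compared.
#'
#' @param a,b `mol_graph` objects.
#' @return TRUE/FALSE.
#' @export
graphs_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  if (!identical(sort(a$element), sort(b$element))) return(FALSE)
  identical(canonical_key(a), canonical_key(b))
}
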