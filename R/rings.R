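atoms_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n_atoms(graph), directed = FALSE)
  if (n_bonds(graph)) g <- igraph::add_edges(g, t(graph$bonds[, 1:2, drop = FALSE]))
  g
}

# bond row index lookup for an unordered atom pair
bond_lookup <- function(graph) {
  b <- graph$bonds
  keys <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  stats::setNames(seq_len(nrow(b)), keys)
}

path_to_bonds <- function(path, lut) {
  if (length(path) < 2) return(integer(0))
  a <- path[-length(path)]; b <- path[-1]
  unname(lut[paste(pmin(a, b), pmax(a, b))])
}

#' Perceive the smallest set of smallest rings
#'
#' Computes a minimum cycle basis (Horton candidate cycles, greedy GF(2)
#' selection), whose size equals the cyclomatic number bonds - atoms + 1 for a
#' connected graph. Ring membership flags on bonds are derived from the
#' selected basis.
#'
#' @param graph a `mol_graph`.
#' @return a list with `n_rings`, `rings` (list of bond-index vectors, sorted
#'   by ring size), `ring_atoms` (list of atom-index vectors), and `bond_in_ring`
#'   (logical per bond: member of at least one SSSR ring).
#' @export
perceive_rings <- function(graph) {
  n <- n_atoms(graph)
  m <- n_bonds(graph)
  mu <- m - n + 1L
  empty <- list(n_rings = 0L, rings = list(), ring_atoms = list(),
                bond_in_ring = rep(FALSE, m))
  if (mu <= 0L) return(empty)
  ig <- atoms_igraph(graph)
  lut <- bond_lookup(graph)
  dist <- igraph::distances(ig)
  b <- graph$bonds
  # Horton candidates: for each vertex v and edge (x,y), shortest-path cycle
  cand <- list()
  seen <- character(0)
  for (v in seq_len(n)) {
    sp <- igraph::shortest_paths(ig, from = v, to = igraph::V(ig))$vpath
    for (r in seq_len(m)) {
      x <- b[r, 1]; y <- b[r, 2]
      if (!is.finite(dist[v, x]) || !is.finite(dist[v, y])) next
      px <- as.integer(sp[[x]]); py <- as.integer(sp[[y]])
      # vertex-disjoint except at v
      if (length(intersect(px[-1], py[-1]))) next
      cyc_bonds <- sort(unique(c(path_to_bonds(px, lut), path_to_bonds(py, lut), r)))
      # must be a simple cycle: every vertex degree 2 within the edge set
      verts <- unique(c(b[cyc_bonds, 1], b[cyc_bonds, 2]))
      if (length(cyc_bonds) != length(verts)) next
      key <- paste(cyc_bonds, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- cyc_bonds
    }
  }
  cand <- cand[order(vapply(cand, length, 1L),
                     vapply(cand, function(x) paste(x, collapse = ","), ""))]
  # greedy GF(2) independence over edge-incidence vectors
  basis <- matrix(FALSE, nrow = 0, ncol = m)
  rings <- list()
  for (cyc in cand) {
    vec <- rep(FALSE, m)
    vec[cyc] <- TRUE
    red <- vec
    if (nrow(basis)) {
      for (k in seq_len(nrow(basis))) {
        piv <- which(basis[k, ])[1]
        if (red[piv]) red <- xor(red, basis[k, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      # keep rows in echelon form: sort by pivot
      basis <- basis[order(apply(basis, 1, function(x) which(x)[1])), , drop = FALSE]
      rings[[length(rings) + 1L]] <- cyc
      if (length(rings) == mu) break
    }
  }
  bond_in_ring <- rep(FALSE, m)
  ring_atoms <- vector("list", length(rings))
  for (k in seq_along(rings)) {
    bond_in_ring[rings[[k]]] <- TRUE
    ring_atoms[[k]] <- sort(unique(c(b[rings[[k]], 1], b[rings[[k]], 2])))
  }
  list(n_rings = length(rings), rings = rings, ring_atoms = ring_atoms,
       bond_in_ring = bond_in_ring)
}

#' Census of ring bonds and of bonds that open the largest ring
#'
#' A ring bond is any bond lying on a cycle (equivalently, a non-bridge edge:
#' one whose removal keeps the graph connected, so an operator "could open"
#' it). A bond opens the largest ring when, after its removal, no SSSR ring of
#' at least the original largest size remains — a bond shared between the
#' macrocycle and a fused small ring merges the two into an even larger ring
#' and therefore does not open it.
#'
#' @param graph a `mol_graph`.
#' @return list with `n_ring_bonds`, `n_large_ring_opening`,
#'   `largest_ring_size`, and per-bond logicals `ring_bond`, `opens_large`.
#' @export
ring_bond_census <- function(graph) {
  m <- n_bonds(graph)
  br <- bond_is_bridge(graph)
  ring_bond <- !br
  if (!any(ring_bond)) {
    return(list(n_ring_bonds = 0L, n_large_ring_opening = 0L,
                largest_ring_size = 0L,
                ring_bond = ring_bond, opens_large = rep(FALSE, m)))
  }
  ss <- perceive_rings(graph)
  sizes <- vapply(ss$rings, length, 1L)
  L <- max(sizes)
  opens <- rep(FALSE, m)
  for (r in which(ring_bond)) {
    sub <- graph
    sub$bonds <- graph$bonds[-r, , drop = FALSE]
    sub$ring_closure <- graph$ring_closure[-r]
    ss2 <- perceive_rings(sub)
    mx <- if (ss2$n_rings) max(vapply(ss2$rings, length, 1L)) else 0L
    opens[r] <- mx < L
  }
  list(n_ring_bonds = sum(ring_bond),
       n_large_ring_opening = sum(opens),
       largest_ring_size = L,
       ring_bond = ring_bond, opens_large = opens)
}
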