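# Iterative neighbourhood refinement (Morgan-style) on the graph with one
# atom removed. Returns the final equivalence class id per remaining atom;
# two substituents of the removed atom are structurally interchangeable iff
# their class ids coincide. Classes are comparable only within one call,
# which is all substituent-distinctness needs.
refine_without_atom <- function(graph, drop_atom) {
  n <- n_atoms(graph)
  keep <- setdiff(seq_len(n), drop_atom)
  idx <- match(seq_len(n), keep)      # old -> new
  b <- graph$bonds
  sel <- b[, 1] != drop_atom & b[, 2] != drop_atom
  bi <- idx[b[sel, 1]]; bj <- idx[b[sel, 2]]; bo <- b[sel, 3]
  nn <- length(keep)
  adj <- vector("list", nn)
  for (r in seq_along(bi)) {
    adj[[bi[r]]] <- rbind(adj[[bi[r]]], c(bj[r], bo[r]))
    adj[[bj[r]]] <- rbind(adj[[bj[r]]], c(bi[r], bo[r]))
  }
  lab <- match(paste(graph$element[keep], graph$implicit_h[keep]),
               unique(paste(graph$element[keep], graph$implicit_h[keep])))
  for (it in seq_len(nn)) {
    sig <- vapply(seq_len(nn), function(v) {
      nb <- adj[[v]]
      if (is.null(nb)) return(paste0(lab[v], "|"))
      paste0(lab[v], "|", paste(sort(paste(nb[, 2], lab[nb[, 1]])), collapse = ","))
    }, "")
    new_lab <- match(sig, unique(sig))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  out <- rep(NA_integer_, n)
  out[keep] <- lab
  out
}

#' Detect stereogenic elements of a molecular graph
#'
#' Tetrahedral stereocenters are atoms with four substituents (implicit H
#' counting as one, so at most one H), all single bonds, and all four
#' substituents structurally distinguishable. Stereogenic double bonds are
#' acyclic order-2 bonds whose two ends each carry exactly two
#' distinguishable substituents; double bonds inside rings are excluded,
#' their geometry being fixed by the ring.
#'
#' @param graph a `mol_graph`.
#' @return list with `tetra_centers` (atom indices) and `stereo_double_bonds`
#'   (bond row indices), both sorted.
#' @export
find_stereo_elements <- function(graph) {
  n <- n_atoms(graph)
  adj <- adjacency(graph)
  deg <- heavy_degree(graph)
  inring_bond <- !bond_is_bridge(graph)
  b <- graph$bonds

  tetra <- integer(0)
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (is.null(nb)) next
    if (any(nb[, 2] != 1L)) next                    # sp3 only
    if (deg[a] + graph$implicit_h[a] != 4L) next
    if (graph$implicit_h[a] > 1L) next              # two H's are identical
    cls <- refine_without_atom(graph, a)
    sub <- cls[nb[, 1]]
    if (anyDuplicated(sub)) next                    # two identical heavy branches
    tetra <- c(tetra, a)
  }

  dbs <- integer(0)
  if (n_bonds(graph)) {
    for (r in seq_len(n_bonds(graph))) {
      if (b[r, 3] != 2L || inring_bond[r]) next
      x <- b[r, 1]; y <- b[r, 2]
      end_ok <- function(e, partner) {
        nb <- adj[[e]]
        heavy <- nb[nb[, 1] != partner, 1]
        k <- length(heavy) + graph$implicit_h[e]
        if (k != 2L) return(FALSE)
        if (length(heavy) == 2L) {
          cls <- refine_without_atom(graph, e)
          return(cls[heavy[1]] != cls[heavy[2]])
        }
        length(heavy) == 1L                          # one heavy + one H
      }
      if (end_ok(x, y) && end_ok(y, x)) dbs <- c(dbs, r)
    }
  }
  list(tetra_centers = sort(tetra), stereo_double_bonds = sort(dbs))
}

#' Enumerate stereoisomer assignments
#'
#' Expands the detected stereo elements over their two states each, in a
#' deterministic lexicographic order over the (+, -) / (cis, trans) basis,
#' truncated at `cap`. Assignment `index` makes the "stereoisomer 5 of 32"
#' labelling reproducible: the last stereo element varies fastest.
#'
#' @param graph a `mol_graph`.
#' @param cap maximum number of assignments returned (default 512).
#' @return list of `stereo_assignment` objects, each with `index`,
#'   `tetra` (data.frame atom/parity) and `db` (data.frame bond/label). The
#'   attribute `n_total` carries the uncapped count 2^k.
#' @export
enumerate_stereoisomers <- function(graph, cap = 512L) {
  stopifnot(cap >= 1)
  st <- find_stereo_elements(graph)
  k_t <- length(st$tetra_centers)
  k_d <- length(st$stereo_double_bonds)
  k <- k_t + k_d
  total <- 2^k
  n_out <- as.integer(min(total, cap))
  out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    bits <- integer(k)
    v <- i - 1L
    if (k > 0) {
      for (p in k:1) {
        bits[p] <- v %% 2L
        v <- v %/% 2L
      }
    }
    tpar <- if (k_t) c("+", "-")[bits[seq_len(k_t)] + 1L] else character(0)
    dlab <- if (k_d) c("cis", "trans")[bits[k_t + seq_len(k_d)] + 1L] else character(0)
    out[[i]] <- structure(list(
      index = i,
      tetra = data.frame(atom = st$tetra_centers, parity = tpar,
                         stringsAsFactors = FALSE),
      db = data.frame(bond = st$stereo_double_bonds, label = dlab,
                      stringsAsFactors = FALSE)
    ), class = "stereo_assignment")
  }
  attr(out, "n_total") <- total
  out
}
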