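# shared fixtures and independent oracles for the suite

smi <- function(name) fixture_smiles(name)

# permissive config for tiny toy molecules
tiny_config <- function(...) molecular_config(min_heavy_atoms = 1L, ...)

# a random linear C4-C6 alkane population (the convergence-harness start)
random_alkane_population <- function(n) {
  vapply(seq_len(n), function(i) {
    strrep("C", sample(4:6, 1))
  }, "")
}

# grow a random valid small molecule by repeated mutation from methane;
# exercises the operators and guarantees chemical validity
random_small_molecule <- function(n_steps = 8, config = operator_config(molecular = tiny_config())) {
  g <- parse_smiles("C", config$molecular)
  for (k in seq_len(n_steps)) g <- mutate_molecule(g, config)
  g
}

# ---- brute-force cycle-space oracle (independent of perceive_rings) ------

# all simple cycles of a small mol_graph, as sorted bond-index vectors
all_simple_cycles <- function(graph) {
  b <- graph$bonds
  m <- nrow(b)
  if (!m) return(list())
  ig <- igraph::make_empty_graph(n_atoms(graph), directed = FALSE)
  ig <- igraph::add_edges(ig, t(b[, 1:2, drop = FALSE]))
  lut <- stats::setNames(seq_len(m), paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  seen <- character(0)
  out <- list()
  for (r in seq_len(m)) {
    sub <- igraph::delete_edges(ig, r)
    paths <- igraph::all_simple_paths(sub, from = b[r, 1], to = b[r, 2])
    for (p in paths) {
      v <- as.integer(p)
      eb <- lut[paste(pmin(v[-length(v)], v[-1]), pmax(v[-length(v)], v[-1]))]
      cyc <- sort(unname(c(eb, r)))
      key <- paste(cyc, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cyc
      }
    }
  }
  out
}

# minimum cycle basis weight by greedy GF(2) over the complete cycle set
brute_min_cycle_basis <- function(graph) {
  cycles <- all_simple_cycles(graph)
  m <- n_bonds(graph)
  mu <- m - n_atoms(graph) + 1L
  if (mu <= 0 || !length(cycles)) return(list(n = 0L, sizes = integer(0)))
  cycles <- cycles[order(vapply(cycles, length, 1L))]
  basis <- matrix(FALSE, 0, m)
  sizes <- integer(0)
  for (cyc in cycles) {
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
      basis <- basis[order(apply(basis, 1, function(x) which(x)[1])), , drop = FALSE]
      sizes <- c(sizes, length(cyc))
      if (length(sizes) == mu) break
    }
  }
  list(n = length(sizes), sizes = sort(sizes))
}

expect_valid_molecule <- function(graph, config = molecular_config()) {
  expect_true(is_valid_graph(graph, config))
  s <- write_smiles(graph)
  reparsed <- parse_smiles(s, config)
  expect_true(graphs_isomorphic(graph, reparsed))
}
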