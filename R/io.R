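#' Load an initial population file
#'
#' One SMILES per line; blank lines and `#` comments are skipped. The
#' population size is the number of chromosomes read. Every line must parse
#' as a strictly valid chromosome — an invalid initial population is a user
#' error and is reported with line numbers.
#'
#' @param path population file.
#' @param molecular a [molecular_config()].
#' @return character vector of chromosomes with attribute `pop_size`.
#' @export
load_population <- function(path, molecular = molecular_config()) {
  if (!file.exists(path)) mol_error(sprintf("no such file: %s", path), "io_error")
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  if (!length(keep)) mol_error(sprintf("empty population file: %s", path), "io_error")
  smiles <- trimws(raw[keep])
  errs <- character(0)
  for (k in seq_along(smiles)) {
    res <- tryCatch({ parse_smiles(smiles[k], molecular); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errs <- c(errs, sprintf("line %d: %s", keep[k], res))
    }
  }
  if (length(errs)) {
    mol_error(paste(c("invalid population file:", errs), collapse = "\n  "),
              "io_error")
  }
  structure(smiles, pop_size = length(smiles))
}

#' Write a population file
#' @param chromosomes character vector of SMILES.
#' @param path destination.
#' @return invisibly, the path.
#' @export
save_population <- function(chromosomes, path) {
  writeLines(chromosomes, path)
  invisible(path)
}

#' Sorted, deduplicated report over a run history
#'
#' Takes the union of all generations, deduplicates by the stereo-agnostic
#' canonical key, keeps the best fitness per molecule and the generation it
#' was first seen, and sorts best-first. Property profiles are attached per
#' representative.
#'
#' @param history a `run_history`.
#' @param molecular a [molecular_config()].
#' @return data.frame: key, smiles, best_fitness, first_seen_generation,
#'   heavy_atoms, molecular_mass, hbd, hba, rotatable_dihedrals, n_rings.
#' @export
generate_report <- function(history, molecular = history$molecular %||% molecular_config()) {
  gens <- history$generations
  if (!length(gens)) mol_error("empty history", "io_error")
  seen <- new.env(parent = emptyenv())
  for (g in gens) {
    for (k in seq_along(g$chromosomes)) {
      smi <- g$chromosomes[k]
      fit <- g$fitness[k]
      gr <- tryCatch(parse_smiles(smi, molecular, strict = FALSE),
                     error = function(e) NULL)
      if (is.null(gr)) next
      key <- canonical_key(gr)
      cur <- seen[[key]]
      if (is.null(cur)) {
        seen[[key]] <- list(key = key, smiles = smi, best_fitness = fit,
                            first_seen_generation = g$generation, graph = gr)
      } else if (fit < cur$best_fitness) {
        cur$best_fitness <- fit
        seen[[key]] <- cur
      }
    }
  }
  entries <- as.list(seen)
  rows <- lapply(entries, function(e) {
    p <- compute_properties(e$graph, stereo = FALSE)
    data.frame(key = e$key, smiles = e$smiles, best_fitness = e$best_fitness,
               first_seen_generation = e$first_seen_generation,
               heavy_atoms = p$heavy_atoms, molecular_mass = p$molecular_mass,
               hbd = p$hbd, hba = p$hba,
               rotatable_dihedrals = p$rotatable_dihedrals,
               n_rings = p$n_rings, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$best_fitness, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a report as TSV
#' @param report data.frame from [generate_report()].
#' @param path destination.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- run configuration file ----------------------------------------------

config_block_keys <- list(
  ga = c("generations", "elite_fraction", "crossover_rate", "mutation_rate",
         "selection", "stall_gen_limit", "tol_fun", "tol_con",
         "rescore_elites", "seed"),
  molecular = c("atom_type", "atom_val", "unnorm_percent_atom", "max_tries",
                "min_heavy_atoms", "max_stereoisomers",
                "cutoff_bond_percentage"),
  operators = c("unnorm_mut_probability"),
  adme = c("mode", "max_mass", "max_donor", "max_acceptor",
           "max_rotatable_dihedrals", "max_log_kow", "penalty_mass",
           "penalty_donor", "penalty_acceptor", "penalty_dihedrals",
           "penalty_log_kow", "hard_violation_penalty", "soft_scale"),
  scorer = c("type", "target", "weights", "s_max", "hbond_residues", "path",
             "stereo_sensitive", "conf_file"),
  constraints = c("forbidden_patterns", "per_match_penalty",
                  "required_hbond_residues", "hbond_penalty_each",
                  "localization"),
  paths = c("ligand_dir", "initial_population", "checkpoint", "output",
            "mass_table")
)

#' Load and validate a YAML run configuration
#'
#' Every omitted parameter takes its documented default; unknown blocks or
#' keys are rejected, and all problems are reported in a single error.
#'
#' @param path YAML file (an empty file yields the full default set).
#' @return list with validated `ga`, `molecular`, `operators`, `adme`,
#'   `scorer`, `constraints`, `paths` blocks.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else {
    mol_error(sprintf("no such config file: %s", path), "config_error")
  }
  if (is.null(raw)) raw <- list()
  problems <- character(0)
  bad_blocks <- setdiff(names(raw), names(config_block_keys))
  if (length(bad_blocks)) {
    problems <- c(problems, sprintf("unknown config block(s): %s",
                                    paste(bad_blocks, collapse = ", ")))
  }
  for (blk in intersect(names(raw), names(config_block_keys))) {
    bad <- setdiff(names(raw[[blk]]), config_block_keys[[blk]])
    if (length(bad)) {
      problems <- c(problems, sprintf("unknown key(s) in '%s': %s", blk,
                                      paste(bad, collapse = ", ")))
    }
  }
  build <- function(fn, args) {
    tryCatch(list(value = do.call(fn, args), error = NULL),
             error = function(e) list(value = NULL,
                                      error = conditionMessage(e)))
  }
  mol_args <- raw$molecular %||% list()
  if (!is.null(mol_args$atom_val)) mol_args$atom_val <- unlist(mol_args$atom_val)
  if (!is.null(mol_args$unnorm_percent_atom)) {
    mol_args$unnorm_percent_atom <- unlist(mol_args$unnorm_percent_atom)
  }
  mol <- build(molecular_config, mol_args)
  if (!is.null(mol$error)) problems <- c(problems, paste("molecular:", mol$error))
  op_args <- raw$operators %||% list()
  if (!is.null(op_args$unnorm_mut_probability)) {
    op_args$unnorm_mut_probability <- unlist(op_args$unnorm_mut_probability)
  }
  if (!is.null(mol$value)) op_args$molecular <- mol$value
  op <- build(operator_config, op_args)
  if (!is.null(op$error)) problems <- c(problems, paste("operators:", op$error))
  ga <- build(ga_config, raw$ga %||% list())
  if (!is.null(ga$error)) problems <- c(problems, paste("ga:", ga$error))
  adme_args <- raw$adme %||% list(mode = "None")
  adme <- build(adme_config, adme_args)
  if (!is.null(adme$error)) problems <- c(problems, paste("adme:", adme$error))
  scorer <- raw$scorer %||% list(type = "synthetic")
  if (!is.null(scorer$type) &&
      !scorer$type %in% c("synthetic", "replay", "external")) {
    problems <- c(problems, sprintf("scorer: unknown type '%s'", scorer$type))
  }
  if (length(problems)) {
    mol_error(paste(c("invalid configuration:", problems), collapse = "\n  "),
              "config_error")
  }
  list(ga = ga$value, molecular = mol$value, operators = op$value,
       adme = adme$value, scorer = scorer,
       constraints = raw$constraints %||% list(),
       paths = raw$paths %||% list())
}

#' Dump a validated configuration back to YAML
#'
#' Writes the fully-defaulted, normalized form; loading the dump yields a
#' configuration identical to the one dumped.
#'
#' @param config a configuration set from [load_config()].
#' @param path destination YAML file.
#' @return invisibly, the path.
#' @export
dump_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v)) strip(v) else v)
  }
  mol <- strip(config$molecular)
  mol$inter_bond_distance <- NULL  # fixed table, not a config key
  ops <- list(unnorm_mut_probability = as.list(config$operators$unnorm_mut_probability))
  out <- list(ga = strip(config$ga),
              molecular = lapply(mol, function(v) if (length(names(v))) as.list(v) else v),
              operators = ops,
              adme = strip(config$adme),
              scorer = config$scorer,
              constraints = config$constraints,
              paths = config$paths)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Instantiate the scorer described by a config block
#'
#' `synthetic` builds the deterministic surrogate site; `replay` wraps a
#' precomputed score table; `external` is a contract only — the descriptor
#' (e.g. a docking configuration path) is passed through untouched and the
#' caller must supply the adapter.
#'
#' @param descriptor the `scorer` block of a loaded config.
#' @return a scorer object, or an error for `external` without an adapter.
#' @export
build_scorer <- function(descriptor) {
  type <- descriptor$type %||% "synthetic"
  if (type == "synthetic") {
    args <- list()
    if (!is.null(descriptor$target)) args$target <- unlist(descriptor$target)
    if (!is.null(descriptor$weights)) args$weights <- unlist(descriptor$weights)
    if (!is.null(descriptor$s_max)) args$s_max <- descriptor$s_max
    if (!is.null(descriptor$hbond_residues)) {
      args$hbond_residues <- unlist(descriptor$hbond_residues)
    }
    return(do.call(synthetic_site_scorer, args))
  }
  if (type == "replay") {
    return(replay_scorer(descriptor$path,
                         stereo_sensitive = descriptor$stereo_sensitive %||% TRUE))
  }
  mol_error("external scorer requires a user-supplied adapter", "config_error")
}
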