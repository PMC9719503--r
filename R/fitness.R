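#' ADME restriction configuration
#'
#' Lipinski Rule-of-5 limits extended with a rotatable-dihedral cap, plus the
#' per-rule penalty coefficients and the hard-mode violation penalty.
#'
#' @param mode "None", "SoftLipinski" or "HardLipinski".
#' @param max_mass,max_donor,max_acceptor,max_rotatable_dihedrals,max_log_kow
#'   rule limits (500 Da, 5, 10, 7, 5).
#' @param penalty_mass,penalty_donor,penalty_acceptor,penalty_dihedrals,penalty_log_kow
#'   soft-mode coefficients.
#' @param hard_violation_penalty penalty per violated rule in hard mode (20).
#' @param soft_scale "relative" charges coefficient x (violation/limit) so
#'   penalties stay commensurate with docking-score magnitudes; "raw" charges
#'   coefficient x violation directly.
#' @return list of class `adme_config`.
#' @export
adme_config <- function(mode = c("None", "SoftLipinski", "HardLipinski"),
                        max_mass = 500, max_donor = 5, max_acceptor = 10,
                        max_rotatable_dihedrals = 7, max_log_kow = 5,
                        penalty_mass = 4, penalty_donor = 10,
                        penalty_acceptor = 10, penalty_dihedrals = 10,
                        penalty_log_kow = 10,
                        hard_violation_penalty = 20,
                        soft_scale = c("relative", "raw")) {
  mode <- match.arg(mode)
  soft_scale <- match.arg(soft_scale)
  lims <- c(max_mass, max_donor, max_acceptor, max_rotatable_dihedrals, max_log_kow)
  pens <- c(penalty_mass, penalty_donor, penalty_acceptor, penalty_dihedrals,
            penalty_log_kow, hard_violation_penalty)
  if (any(lims <= 0)) mol_error("ADME limits must be positive", "config_error")
  if (any(pens < 0)) mol_error("ADME penalties must be nonnegative", "config_error")
  structure(list(mode = mode, max_mass = max_mass, max_donor = max_donor,
                 max_acceptor = max_acceptor,
                 max_rotatable_dihedrals = max_rotatable_dihedrals,
                 max_log_kow = max_log_kow,
                 penalty_mass = penalty_mass, penalty_donor = penalty_donor,
                 penalty_acceptor = penalty_acceptor,
                 penalty_dihedrals = penalty_dihedrals,
                 penalty_log_kow = penalty_log_kow,
                 hard_violation_penalty = hard_violation_penalty,
                 soft_scale = soft_scale),
            class = "adme_config")
}

#' Lipinski/ADME penalty for a property profile
#'
#' Soft mode charges each violated rule `coefficient * max(0, excess)` where
#' the excess is relative (`(x - limit)/limit`, default) or raw (`x - limit`);
#' hard mode charges `hard_violation_penalty` per violated rule; mode None is
#' always 0. The log K_ow rule is skipped when the profile carries no
#' user-supplied value (it is never computed internally).
#'
#' @param profile a `property_profile`.
#' @param config an [adme_config()].
#' @return nonnegative penalty value.
#' @export
lipinski_penalty <- function(profile, config = adme_config()) {
  if (config$mode == "None") return(0)
  x <- c(mass = profile$molecular_mass, donor = profile$hbd,
         acceptor = profile$hba, dihedrals = profile$rotatable_dihedrals)
  lim <- c(mass = config$max_mass, donor = config$max_donor,
           acceptor = config$max_acceptor,
           dihedrals = config$max_rotatable_dihedrals)
  coef <- c(mass = config$penalty_mass, donor = config$penalty_donor,
            acceptor = config$penalty_acceptor,
            dihedrals = config$penalty_dihedrals)
  if (!is.na(profile$log_kow)) {
    x <- c(x, log_kow = profile$log_kow)
    lim <- c(lim, log_kow = config$max_log_kow)
    coef <- c(coef, log_kow = config$penalty_log_kow)
  }
  excess <- pmax(0, x - lim)
  if (config$mode == "HardLipinski") {
    return(config$hard_violation_penalty * sum(excess > 0))
  }
  if (config$soft_scale == "relative") excess <- excess / lim
  sum(coef * excess)
}

parse_pattern <- function(pattern, config) {
  if (is.character(pattern)) pattern <- list(smiles = pattern, terminal = FALSE)
  g <- parse_smiles(pattern$smiles, config, strict = FALSE)
  list(graph = g, terminal = isTRUE(pattern$terminal), smiles = pattern$smiles)
}

#' Penalty for forbidden substructures
#'
#' Patterns are small SMILES-like fragments (e.g. the hydrolytically unstable
#' enol ether `C=COC`, the thioenolate `C=CS`, the acetal `OCO`). A pattern
#' flagged `terminal = TRUE` additionally requires its final pattern atom to
#' land on a branch end-point (heavy degree 1) of the molecule. The penalty is
#' `per_match_penalty` times the number of distinct matched atom sets.
#'
#' @param graph a `mol_graph`.
#' @param patterns character vector of pattern SMILES, or a list of
#'   `list(smiles=, terminal=)` entries.
#' @param per_match_penalty penalty per match (default 10).
#' @param config a [molecular_config()].
#' @return nonnegative penalty; the match count is in attribute `n_matches`.
#' @export
substructure_penalty <- function(graph, patterns, per_match_penalty = 10,
                                 config = molecular_config()) {
  if (!length(patterns)) return(structure(0, n_matches = 0L))
  if (is.character(patterns)) patterns <- as.list(patterns)
  deg <- heavy_degree(graph)
  total <- 0L
  host <- subdivided_igraph(graph)
  for (p in patterns) {
    pp <- parse_pattern(p, config)
    pat <- subdivided_igraph(pp$graph)
    maps <- igraph::subgraph_isomorphisms(
      pattern = pat$g, target = host$g, method = "vf2",
      vertex.color1 = host$colors, vertex.color2 = pat$colors)
    if (!length(maps)) next
    np <- n_atoms(pp$graph)
    sets <- unique(lapply(maps, function(m) sort(as.integer(m[seq_len(np)]))))
    if (pp$terminal) {
      last_atom <- np  # final pattern atom in parse order
      keep <- vapply(maps, function(m) deg[as.integer(m[last_atom])] == 1L, TRUE)
      sets <- unique(lapply(maps[keep],
                            function(m) sort(as.integer(m[seq_len(np)]))))
    }
    total <- total + length(sets)
  }
  structure(per_match_penalty * total, n_matches = total)
}

#' Default forbidden-substructure patterns
#'
#' The instability motifs used when a run enables substructure constraints:
#' enol ether, terminal thioenolate, and the acetal-like O-C-O linkage.
#' @return list of pattern descriptors.
#' @export
default_forbidden_patterns <- function() {
  list(list(smiles = "C=COC", terminal = FALSE),
       list(smiles = "C=CS", terminal = TRUE),
       list(smiles = "OCO", terminal = FALSE))
}

#' Penalty for missing required hydrogen bonds
#'
#' Charges `penalty_each` for every required residue that shares no hydrogen
#' bond with the ligand in the scorer's interaction report. An empty report
#' counts as zero hydrogen bonds.
#'
#' @param report an interaction report (list with `hbonds` data.frame of
#'   residue/atom, possibly NULL).
#' @param required_residues character vector of residue labels (opaque,
#'   matched exactly).
#' @param penalty_each penalty per missing residue (default 10).
#' @return nonnegative penalty.
#' @export
hbond_requirement_penalty <- function(report, required_residues,
                                      penalty_each = 10) {
  if (!length(required_residues)) return(0)
  seen <- character(0)
  if (!is.null(report) && !is.null(report$hbonds) && nrow(report$hbonds)) {
    seen <- unique(report$hbonds$residue)
  }
  penalty_each * sum(!(required_residues %in% seen))
}

#' Penalty for failed spatial localization
#'
#' Active only when the scorer supplies pose coordinates: the full penalty is
#' charged unless every anchor point has at least one ligand heavy atom
#' within `radius`. Without coordinates the rule is inactive (0, with a
#' warning).
#'
#' @param report interaction report (may carry `pose_coords`, an n x 3 matrix).
#' @param anchors k x 3 matrix of anchor coordinates.
#' @param radius coverage radius in Angstrom.
#' @param penalty penalty when any anchor is uncovered.
#' @return 0 or `penalty`.
#' @export
localization_penalty <- function(report, anchors, radius, penalty = 10) {
  if (is.null(report) || is.null(report$pose_coords)) {
    warning("localization rule inactive: no pose coordinates in report")
    return(0)
  }
  xyz <- report$pose_coords
  anchors <- matrix(anchors, ncol = 3)
  for (k in seq_len(nrow(anchors))) {
    d2 <- (xyz[, 1] - anchors[k, 1])^2 + (xyz[, 2] - anchors[k, 2])^2 +
      (xyz[, 3] - anchors[k, 3])^2
    if (!any(d2 <= radius^2)) return(penalty)
  }
  0
}

# ---- scorer contract ------------------------------------------------------
# a scorer is a list: identity (name), deterministic (flag), stereo_sensitive
# (flag), and score(graph, assignment, profile) -> list(score, report) where
# score is the best pose score (>= 0) or NA for "no pose found".

#' Deterministic surrogate binding-site scorer
#'
#' A stand-in site model for development and testing: the score is
#' `max(0, s_max - sum(w * |p - t|))` where `p` is the molecule's profile
#' vector (heavy atoms, H-bond donors, acceptors, rings, rotatable dihedrals)
#' and `t` the site's target profile. Optionally emits synthetic hydrogen-bond
#' records for the given residues whenever the molecule has a donor or
#' acceptor, so constraint plumbing can be exercised end to end.
#'
#' @param target named numeric vector over the profile components.
#' @param weights nonnegative weights, recycled over the components.
#' @param s_max maximum attainable score (> 0).
#' @param hbond_residues residues reported as hydrogen-bonded.
#' @param identity scorer name.
#' @return a scorer object.
#' @export
synthetic_site_scorer <- function(target = c(heavy_atoms = 13, hbd = 1, hba = 4,
                                             n_rings = 1, rotatable_dihedrals = 3),
                                  weights = 1, s_max = 100,
                                  hbond_residues = character(0),
                                  identity = "synthetic_site") {
  stopifnot(s_max > 0, all(weights >= 0))
  comp <- c("heavy_atoms", "hbd", "hba", "n_rings", "rotatable_dihedrals")
  t <- stats::setNames(rep(0, length(comp)), comp)
  t[names(target)] <- target
  w <- stats::setNames(rep_len(weights, length(comp)), comp)
  structure(list(
    identity = identity, deterministic = TRUE, stereo_sensitive = FALSE,
    target = t, weights = w, s_max = s_max,
    score = function(graph, assignment, profile) {
      p <- profile_vector(profile)
      s <- max(0, s_max - sum(w * abs(p - t)))
      report <- list(hbonds = NULL, pose_coords = NULL)
      if (length(hbond_residues) && (profile$hbd > 0 || profile$hba > 0)) {
        anchor_atom <- which(graph$element %in% c("N", "O"))[1]
        report$hbonds <- data.frame(residue = hbond_residues,
                                    atom = anchor_atom,
                                    stringsAsFactors = FALSE)
      }
      list(score = s, report = report)
    }
  ), class = "ligand_scorer")
}

#' Replay scorer backed by a precomputed score table
#'
#' Reads a TSV of (canonical key, stereoisomer index, score) and serves
#' lookups; a missing entry means "no pose found". Used for integration tests
#' and for replaying scores produced by an external docking engine.
#'
#' @param path TSV file with columns key, stereo_index, score.
#' @param stereo_sensitive whether scores differ across stereoisomers.
#' @return a scorer object.
#' @export
replay_scorer <- function(path, stereo_sensitive = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("key", "stereo_index", "score") %in% names(tab)))
  structure(list(
    identity = paste0("replay:", basename(path)),
    deterministic = TRUE, stereo_sensitive = stereo_sensitive,
    score = function(graph, assignment, profile) {
      key <- canonical_key(graph)
      hit <- tab$key == key & tab$stereo_index == assignment$index
      if (!any(hit)) return(list(score = NA_real_, report = NULL))
      list(score = tab$score[which(hit)[1]], report = NULL)
    }
  ), class = "ligand_scorer")
}

#' Evaluate fitness of a batch of SMILES chromosomes
#'
#' Per chromosome: parse (strictly), expand stereoisomers up to the cap,
#' score each via the scorer, take the best score over stereoisomers, and add
#' the ADME, substructure, hydrogen-bond and localization penalties. Fitness
#' is `-best_score + total_penalty`, so more negative is better. Any parse or
#' total scoring failure yields the sentinel fitness 0 with the failure flag
#' set — individual failures never abort the batch. Note the documented sharp
#' edge: the sentinel 0 can rank better than a valid positive fitness.
#'
#' For scorers that declare `stereo_sensitive = FALSE` the score of the first
#' assignment is reused across stereoisomers (the surrogate site model cannot
#' distinguish them); stereo-aware scorers are called once per assignment.
#'
#' When `ligand_dir` is given, the per-molecule work tree
#' `<ligand_dir>/mol_NNN/stereo_MMM/score.txt` is deleted and recreated on
#' each call.
#'
#' @param chromosomes character vector of SMILES strings.
#' @param scorer a scorer object.
#' @param molecular a [molecular_config()].
#' @param adme an [adme_config()].
#' @param constraints list with optional entries `forbidden_patterns`,
#'   `per_match_penalty`, `required_hbond_residues`, `hbond_penalty_each`,
#'   `localization` (list(anchors, radius, penalty)).
#' @param log_kow optional numeric vector (recycled) of user-supplied log
#'   K_ow values.
#' @param ligand_dir optional work-product directory.
#' @return data.frame of class `fitness_records`: chromosome, fitness,
#'   failure, best_score, best_stereoisomer, n_stereoisomers and the penalty
#'   breakdown.
#' @export
evaluate_fitness <- function(chromosomes, scorer,
                             molecular = molecular_config(),
                             adme = adme_config(),
                             constraints = list(),
                             log_kow = NULL,
                             ligand_dir = NULL) {
  n <- length(chromosomes)
  if (!is.null(ligand_dir)) {
    unlink(ligand_dir, recursive = TRUE)
    dir.create(ligand_dir, recursive = TRUE, showWarnings = FALSE)
  }
  kow <- if (is.null(log_kow)) rep(NA_real_, n) else rep_len(log_kow, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      evaluate_one(chromosomes[i], scorer, molecular, adme, constraints,
                   kow[i],
                   if (is.null(ligand_dir)) NULL
                   else file.path(ligand_dir, sprintf("mol_%03d", i))),
      error = function(e) failure_record(chromosomes[i])
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fitness_records", class(out))
  out
}

failure_record <- function(chromosome) {
  data.frame(chromosome = chromosome, fitness = 0, failure = TRUE,
             best_score = NA_real_, best_stereoisomer = NA_integer_,
             n_stereoisomers = NA_integer_,
             adme_penalty = 0, substructure_penalty = 0,
             hbond_penalty = 0, localization_penalty = 0, penalty_total = 0,
             stringsAsFactors = FALSE)
}

evaluate_one <- function(chromosome, scorer, molecular, adme, constraints,
                         log_kow, mol_dir) {
  g <- parse_smiles(chromosome, molecular, strict = TRUE)
  profile <- compute_properties(g, log_kow = if (is.na(log_kow)) NULL else log_kow)
  assignments <- enumerate_stereoisomers(g, cap = molecular$max_stereoisomers)
  scores <- rep(NA_real_, length(assignments))
  reports <- vector("list", length(assignments))
  for (k in seq_along(assignments)) {
    if (k > 1L && !isTRUE(scorer$stereo_sensitive)) {
      scores[k] <- scores[1]
      reports[k] <- reports[1]
      next
    }
    res <- scorer$score(g, assignments[[k]], profile)
    scores[k] <- res$score
    reports[k] <- list(res$report)
  }
  if (!is.null(mol_dir)) {
    for (k in seq_along(assignments)) {
      sd <- file.path(mol_dir, sprintf("stereo_%03d", k))
      dir.create(sd, recursive = TRUE, showWarnings = FALSE)
      writeLines(c(paste0("chromosome\t", chromosome),
                   paste0("stereoisomer\t", k, " of ",
                          attr(assignments, "n_total")),
                   paste0("score\t", format(scores[k]))),
                 file.path(sd, "score.txt"))
    }
  }
  if (all(is.na(scores))) return(failure_record(chromosome))
  best_k <- which.max(scores)
  best <- scores[best_k]
  report <- reports[[best_k]]

  p_adme <- lipinski_penalty(profile, adme)
  p_sub <- 0
  if (!is.null(constraints$forbidden_patterns)) {
    p_sub <- as.numeric(substructure_penalty(
      g, constraints$forbidden_patterns,
      per_match_penalty = constraints$per_match_penalty %||% 10,
      config = molecular))
  }
  p_hb <- 0
  if (!is.null(constraints$required_hbond_residues) &&
      length(constraints$required_hbond_residues)) {
    p_hb <- hbond_requirement_penalty(
      report, constraints$required_hbond_residues,
      penalty_each = constraints$hbond_penalty_each %||% 10)
  }
  p_loc <- 0
  if (!is.null(constraints$localization)) {
    loc <- constraints$localization
    p_loc <- suppressWarnings(localization_penalty(
      report, loc$anchors, loc$radius, loc$penalty %||% 10))
  }
  ptot <- p_adme + p_sub + p_hb + p_loc
  data.frame(chromosome = chromosome, fitness = -best + ptot, failure = FALSE,
             best_score = best, best_stereoisomer = best_k,
             n_stereoisomers = length(assignments),
             adme_penalty = p_adme, substructure_penalty = p_sub,
             hbond_penalty = p_hb, localization_penalty = p_loc,
             penalty_total = ptot, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
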