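asp_profile <- function() compute_properties(parse_smiles(smi("aspirin")))

test_that("Lipinski penalties: compliant molecules pay nothing, violations scale", {
  p <- asp_profile()
  expect_equal(lipinski_penalty(p, adme_config("SoftLipinski")), 0)
  expect_equal(lipinski_penalty(p, adme_config("HardLipinski")), 0)
  expect_equal(lipinski_penalty(p, adme_config("None")), 0)

  # the printed simeprevir profile (mass 750, donors 2, acceptors 10,
  # log K_ow 5.16, 8 dihedrals) violates three rules in hard mode
  sim <- compute_properties(parse_smiles(smi("simeprevir")),
                            log_kow = 5.16, hba_override = 10)
  expect_equal(lipinski_penalty(sim, adme_config("HardLipinski")), 60)

  # soft relative scaling: mass 600 alone costs 4 x (100/500)
  p600 <- p
  p600$molecular_mass <- 600
  expect_equal(lipinski_penalty(p600, adme_config("SoftLipinski")), 0.8)
  # raw scaling available behind the switch
  expect_equal(lipinski_penalty(p600, adme_config("SoftLipinski", soft_scale = "raw")),
               4 * 100)
})

test_that("soft ADME penalty is nondecreasing in each violated quantity and zero iff compliant", {
  cfg <- adme_config("SoftLipinski")
  base <- asp_profile()
  expect_equal(lipinski_penalty(base, cfg), 0)
  prev <- 0
  for (mass in c(500, 550, 700, 900)) {
    p <- base
    p$molecular_mass <- mass
    cur <- lipinski_penalty(p, cfg)
    expect_gte(cur, prev)
    prev <- cur
  }
  p <- base
  p$rotatable_dihedrals <- 9L
  expect_gt(lipinski_penalty(p, cfg), 0)
})

test_that("forbidden substructures are found, with terminal flags honoured", {
  enol <- list(list(smiles = "C=COC", terminal = FALSE))
  tuned <- parse_smiles(smi("aspirin_tuned"))
  expect_gte(attr(substructure_penalty(tuned, enol), "n_matches"), 2L)
  expect_equal(attr(substructure_penalty(parse_smiles("CCO", tiny_config()), enol),
                    "n_matches"), 0L)
  pats <- list(list(smiles = "C=COC", terminal = FALSE),
               list(smiles = "C=CS", terminal = TRUE))
  small_variant <- parse_smiles(smi("simeprevir_prime_3"))
  expect_gte(attr(substructure_penalty(small_variant, pats), "n_matches"), 2L)
  # terminal flag: thioether S buried mid-chain never matches the -SH pattern
  mid <- parse_smiles("C=CSC", tiny_config())
  expect_equal(attr(substructure_penalty(mid, list(list(smiles = "C=CS", terminal = TRUE))),
                    "n_matches"), 0L)
  expect_equal(substructure_penalty(tuned, enol, per_match_penalty = 5),
               5 * attr(substructure_penalty(tuned, enol), "n_matches"),
               ignore_attr = TRUE)
})

test_that("hydrogen-bond requirement penalties count missing residues", {
  rep1 <- list(hbonds = data.frame(residue = "SER531", atom = 4L))
  expect_equal(hbond_requirement_penalty(rep1, "SER531", 10), 0)
  expect_equal(hbond_requirement_penalty(list(hbonds = NULL), "SER531", 10), 10)
  expect_equal(hbond_requirement_penalty(NULL, c("SER531", "TYR385"), 10), 20)
  expect_equal(hbond_requirement_penalty(rep1, character(0), 10), 0)
})

test_that("localization penalty is active only with pose coordinates", {
  coords <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE)
  rep1 <- list(pose_coords = coords)
  expect_equal(localization_penalty(rep1, anchors = c(0, 0, 0), radius = 1, penalty = 10), 0)
  expect_equal(localization_penalty(rep1, anchors = c(100, 100, 100), radius = 1, penalty = 10), 10)
  expect_warning(out <- localization_penalty(list(), anchors = c(0, 0, 0), radius = 1),
                 "inactive")
  expect_equal(out, 0)
})

test_that("evaluate_fitness scores, penalizes and survives failures", {
  asp <- smi("aspirin")
  sc <- synthetic_site_scorer(target = profile_vector(asp_profile()), s_max = 100)
  fr <- evaluate_fitness(c(asp, "C1CC", smi("aspirin_prime_1")), sc,
                         adme = adme_config("None"))
  expect_equal(fr$fitness[1], -100)        # exact profile match, no penalties
  expect_false(fr$failure[1])
  expect_equal(fr$fitness[2], 0)           # unparseable: sentinel
  expect_true(fr$failure[2])
  expect_false(fr$failure[3])
  expect_equal(fr$n_stereoisomers[3], 8L)
  expect_true(fr$fitness[3] < 0)
})

test_that("per-molecule work tree holds one subdirectory per stereoisomer", {
  dir <- withr::local_tempdir()
  sc <- synthetic_site_scorer()
  evaluate_fitness(smi("aspirin_prime_1"), sc, ligand_dir = dir)
  subdirs <- list.dirs(file.path(dir, "mol_001"), recursive = FALSE)
  expect_length(subdirs, 8L)
  expect_true(file.exists(file.path(subdirs[1], "score.txt")))
  # the tree is recreated per call
  evaluate_fitness(smi("aspirin"), sc, ligand_dir = dir)
  expect_false(dir.exists(file.path(dir, "mol_001", "stereo_002")))
})

test_that("fitness never worsens as the stereoisomer cap increases", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  g <- parse_smiles(smi("aspirin_prime_1"))
  key <- canonical_key(g)
  # stereo-sensitive replay scores improving with isomer index
  utils::write.table(
    data.frame(key = key, stereo_index = 1:8, score = seq(10, 80, by = 10)),
    tab, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- replay_scorer(tab, stereo_sensitive = TRUE)
  fit_at_cap <- function(cap) {
    mc <- molecular_config(max_stereoisomers = cap)
    evaluate_fitness(smi("aspirin_prime_1"), sc, molecular = mc)$fitness
  }
  fits <- vapply(c(1L, 2L, 4L, 8L), fit_at_cap, 0)
  expect_true(all(diff(fits) <= 0))
  expect_equal(fits[4], -80)
})

test_that("swapping scorers changes scores but never the penalty components", {
  asp <- smi("simeprevir")
  cons <- list(forbidden_patterns = default_forbidden_patterns(),
               per_match_penalty = 10)
  sc1 <- synthetic_site_scorer(s_max = 100)
  sc2 <- synthetic_site_scorer(target = c(heavy_atoms = 52, hbd = 2, hba = 12,
                                          n_rings = 7, rotatable_dihedrals = 8),
                               s_max = 60, identity = "site2")
  f1 <- evaluate_fitness(asp, sc1, adme = adme_config("SoftLipinski"), constraints = cons)
  f2 <- evaluate_fitness(asp, sc2, adme = adme_config("SoftLipinski"), constraints = cons)
  expect_false(isTRUE(all.equal(f1$best_score, f2$best_score)))
  expect_equal(f1$adme_penalty, f2$adme_penalty)
  expect_equal(f1$substructure_penalty, f2$substructure_penalty)
  expect_equal(f1$penalty_total, f2$penalty_total)
})

test_that("successful fitness is negative whenever the score beats the penalties", {
  sc <- synthetic_site_scorer(s_max = 100)
  set.seed(71)
  pop <- replicate(10, write_smiles(random_small_molecule(12)))
  fr <- evaluate_fitness(pop, sc, molecular = tiny_config(),
                         adme = adme_config("SoftLipinski"))
  ok <- !fr$failure & fr$best_score > fr$penalty_total
  expect_true(all(fr$fitness[ok] < 0))
})
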