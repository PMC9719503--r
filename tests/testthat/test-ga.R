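aspirin_scorer <- function(s_max = 100) {
  synthetic_site_scorer(
    target = profile_vector(compute_properties(parse_smiles(smi("aspirin")))),
    s_max = s_max)
}

test_that("selection handles edge cases and equal fitness symmetrically", {
  expect_length(select_parents(c(-1, -2, -3), 0), 0L)
  expect_warning(idx <- select_parents(rep(0, 5), 10), "failure sentinel")
  expect_true(all(idx %in% 1:5))

  # equal fitnesses: stochastic-uniform selection counts are near-uniform
  set.seed(100)
  counts <- table(factor(unlist(replicate(100, select_parents(rep(-50, 10), 100,
                                                              "stochastic_uniform"),
                                          simplify = FALSE)), levels = 1:10))
  # ranks are tie-broken arbitrarily but reselection each spin evens out;
  # chi-square against uniform should not reject wildly
  chi <- sum((counts - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 9) * 5)
  expect_equal(sum(counts), 10000)
})

test_that("tournament selection prefers the strictly best individual at the closed-form rate", {
  fit <- c(-10, -1, -2, -3, -4, -5, -6, -7, -8, -9)  # individual 1 best
  m <- length(fit)
  set.seed(101)
  n <- 20000
  idx <- select_parents(fit, n, "tournament")
  # P(best selected per draw) = 1 - (1 - 1/m)^2
  p_best <- 1 - (1 - 1 / m)^2
  expect_equal(mean(idx == 1), p_best, tolerance = 0.05)
  expect_gt(mean(idx == 1), max(table(idx[idx != 1])) / n)
})

test_that("elites are carried and degenerate rates reduce to resampling", {
  pop <- rep(smi("aspirin"), 20)
  sc <- aspirin_scorer()
  rec <- evaluate_fitness(pop, sc)
  set.seed(5)
  nx <- next_generation(pop, rec, sc, ga_config(elite_fraction = 0.1))
  expect_length(nx$chromosomes, 20L)

  # elite count follows round(fraction x pop size)
  set.seed(6)
  mixed <- c(rep(smi("aspirin"), 5), replicate(15, write_smiles(random_small_molecule(10))))
  mrec <- evaluate_fitness(mixed, sc, molecular = tiny_config())
  nx2 <- next_generation(mixed, mrec, sc, ga_config(elite_fraction = 0.2),
                         operators = operator_config(molecular = tiny_config()))
  best4 <- mixed[order(mrec$fitness)][1:4]
  expect_identical(nx2$chromosomes[1:4], best4)

  # crossover_rate 0 and mutation_rate 0: pure selection resample
  set.seed(7)
  nx3 <- next_generation(mixed, mrec, sc,
                         ga_config(crossover_rate = 0, mutation_rate = 0),
                         operators = operator_config(molecular = tiny_config()))
  expect_true(all(vapply(nx3$chromosomes, function(s) {
    any(vapply(mixed, function(m) graphs_isomorphic(parse_smiles(s, tiny_config()),
                                                    parse_smiles(m, tiny_config())), TRUE))
  }, TRUE)))
})

test_that("a population already at the optimum stays there under elitism", {
  h <- run_ga(rep(smi("aspirin"), 15), aspirin_scorer(),
              ga_config(generations = 5, seed = 11))
  tr <- fitness_trace(h)
  expect_equal(tr$best, rep(-100, 6))
})

test_that("best fitness is non-increasing under a deterministic scorer", {
  set.seed(200)
  pop <- random_alkane_population(16)
  sc <- synthetic_site_scorer(target = c(heavy_atoms = 12, hbd = 0, hba = 0,
                                         n_rings = 1, rotatable_dihedrals = 4),
                              s_max = 100)
  oc <- operator_config(molecular = molecular_config(min_heavy_atoms = 4L))
  h <- run_ga(pop, sc, ga_config(generations = 15, seed = 12), operators = oc)
  best <- fitness_trace(h)$best
  expect_true(all(diff(best) <= 0))
  # population size and validity conserved every generation
  for (g in h$generations) {
    expect_length(g$chromosomes, 16L)
    for (s in g$chromosomes) {
      expect_true(is_valid_graph(parse_smiles(s, molecular_config(min_heavy_atoms = 4L))))
    }
  }
})

test_that("identical seed, configs and scorer give byte-identical histories", {
  set.seed(300)
  pop <- random_alkane_population(12)
  sc <- aspirin_scorer()
  oc <- operator_config(molecular = molecular_config(min_heavy_atoms = 4L))
  h1 <- run_ga(pop, sc, ga_config(generations = 6, seed = 77), operators = oc)
  h2 <- run_ga(pop, sc, ga_config(generations = 6, seed = 77), operators = oc)
  expect_identical(h1$generations, h2$generations)
})

test_that("checkpoints round-trip, reject corruption and replay identically", {
  dir <- withr::local_tempdir()
  sc <- aspirin_scorer()
  oc <- operator_config(molecular = molecular_config(min_heavy_atoms = 4L))
  set.seed(400)
  pop <- random_alkane_population(10)

  full_cp <- file.path(dir, "full.rds")
  h_full <- run_ga(pop, sc, ga_config(generations = 8, seed = 9), operators = oc,
                   checkpoint_path = full_cp)

  # round-trip identity on the stored history
  cp <- load_checkpoint(full_cp)
  expect_identical(cp$history$generations, h_full$generations)

  # a two-individual run reloads with all generation records intact
  small_cp <- file.path(dir, "small.rds")
  h_small <- run_ga(rep(smi("aspirin"), 2), sc, ga_config(generations = 2, seed = 1),
                    checkpoint_path = small_cp)
  expect_length(load_checkpoint(small_cp)$history$generations, 3L)

  # truncation is reported as corruption, not misread
  bad <- file.path(dir, "bad.rds")
  bytes <- readBin(full_cp, "raw", file.size(full_cp))
  writeBin(bytes[1:40], bad)
  expect_error(load_checkpoint(bad), class = "checkpoint_error")
  not_cp <- file.path(dir, "not.rds")
  saveRDS(list(a = 1), not_cp)
  expect_error(load_checkpoint(not_cp), class = "checkpoint_error")

  # kill at generation 3, restart: generations 4+ identical to the full run
  part_cp <- file.path(dir, "part.rds")
  run_ga(pop, sc, ga_config(generations = 3, seed = 9), operators = oc,
         checkpoint_path = part_cp)
  cp3 <- load_checkpoint(part_cp)
  cp3$history$ga$generations <- 8L
  saveRDS(list(format = "evoligand-checkpoint", version = 1L,
               history = cp3$history, rng_state = cp3$rng_state), part_cp)
  h_res <- resume_ga(part_cp, sc, operators = oc)
  expect_identical(lapply(h_res$generations, `[[`, "chromosomes"),
                   lapply(h_full$generations, `[[`, "chromosomes"))
  expect_identical(fitness_trace(h_res), fitness_trace(h_full))
})

test_that("soft-ADME restriction drags mean fitness relative to the unrestricted run", {
  set.seed(500)
  pop <- random_alkane_population(16)
  # a site rewarding flexibility beyond the dihedral limit, so the ADME
  # penalty binds as molecules adapt
  sc <- synthetic_site_scorer(target = c(heavy_atoms = 22, hbd = 0, hba = 1,
                                         n_rings = 0, rotatable_dihedrals = 12),
                              s_max = 100)
  oc <- operator_config(molecular = molecular_config(min_heavy_atoms = 4L))
  h_free <- run_ga(pop, sc, ga_config(generations = 20, seed = 31), operators = oc,
                   adme = adme_config("None"))
  h_adme <- run_ga(pop, sc, ga_config(generations = 20, seed = 31), operators = oc,
                   adme = adme_config("SoftLipinski"))
  tr_free <- fitness_trace(h_free)
  tr_adme <- fitness_trace(h_adme)
  expect_gt(utils::tail(tr_adme$mean, 1), utils::tail(tr_free$mean, 1))
  expect_gte(utils::tail(tr_adme$best, 1), utils::tail(tr_free$best, 1))
})

test_that("the stall rule stops a run that no longer improves", {
  h <- run_ga(rep(smi("aspirin"), 8), aspirin_scorer(),
              ga_config(generations = 50, stall_gen_limit = 5, seed = 2))
  expect_lt(length(h$generations), 51L)
})
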