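test_that("simulated broods follow the cross-model expectations", {
  # enormous brood: male fraction within 0.001 of 1/4 under viable-WW ZW
  cfg <- experiment_config("ZW", ww_viable = TRUE, n_females_injected = 1,
                           reversal_failure_rate = 0, death_rate = 0,
                           wolbachia_prevalence = 0, broods_per_neomale = 1,
                           brood_mean = 1e6, brood_dispersion = 1e6)
  sim <- simulate_experiment(cfg, seed = 1)
  frac <- sim$broods$n_male / (sim$broods$n_male + sim$broods$n_female)
  expect_lt(abs(frac - 0.25), 0.001)
  expect_equal(sim$truth$expected_male_prop, 0.25)

  cfg$ww_viable <- FALSE
  sim <- simulate_experiment(cfg, seed = 1)
  frac <- sim$broods$n_male / (sim$broods$n_male + sim$broods$n_female)
  expect_lt(abs(frac - 1 / 3), 0.001)

  # XY system with zero leak: every brood all-female
  cfg <- experiment_config("XY", n_females_injected = 8,
                           reversal_failure_rate = 0, death_rate = 0,
                           wolbachia_prevalence = 0)
  sim <- simulate_experiment(cfg, seed = 2)
  expect_true(all(sim$broods$n_male == 0))
  expect_true(all(sim$broods$n_female > 0))

  # total reversal failure: all broods near 1:1 (genetic-male sires)
  cfg <- experiment_config("ZW", n_females_injected = 6,
                           reversal_failure_rate = 1, death_rate = 0,
                           wolbachia_prevalence = 0, brood_mean = 2000)
  sim <- simulate_experiment(cfg, seed = 3)
  expect_true(all(sim$truth$sire_type == "genetic_male"))
  frac <- sim$broods$n_male / (sim$broods$n_male + sim$broods$n_female)
  expect_true(all(abs(frac - 0.5) < 0.06))
})

test_that("Wolbachia-infected mothers produce transmission-biased broods", {
  cfg <- experiment_config("ZW", n_females_injected = 4,
                           reversal_failure_rate = 0, death_rate = 0,
                           wolbachia_prevalence = 1,
                           wolbachia_transmission = 0.9, brood_mean = 5000)
  sim <- simulate_experiment(cfg, seed = 4)
  expect_true(all(sim$broods$mother_wolbachia == "positive"))
  frac <- sim$broods$n_female / (sim$broods$n_male + sim$broods$n_female)
  expect_true(all(abs(frac - 0.9) < 0.03))
})

test_that("simulation is reproducible and warns on an empty neomale pool", {
  cfg <- experiment_config("ZW")
  a <- simulate_experiment(cfg, seed = 10)
  b <- simulate_experiment(cfg, seed = 10)
  expect_identical(a, b)

  dead <- experiment_config("ZW", death_rate = 1)
  expect_warning(sim <- simulate_experiment(dead, seed = 1), "zero surviving")
  expect_equal(nrow(sim$broods), 0)
})

test_that("simulate -> filter -> classify recovers the true system", {
  # study-like contamination levels; pooled offspring per species >> 200
  recover <- function(system, ww, seed) {
    cfg <- experiment_config(system, ww_viable = ww)
    sim <- simulate_experiment(cfg, species = "sp", seed = seed)
    if (nrow(sim$broods) == 0) return(NA_character_)
    kept <- suppressWarnings(filter_broods(sim$broods))$kept
    if (nrow(kept) == 0) return(NA_character_)
    classify_species(kept)$system
  }
  zw <- vapply(1:60, function(s) recover("ZW", TRUE, s), character(1))
  xy <- vapply(61:120, function(s) recover("XY", TRUE, s), character(1))
  expect_gte(mean(zw == "ZW", na.rm = TRUE), 0.9)
  expect_gte(mean(xy == "XY", na.rm = TRUE), 0.9)
})

test_that("Gillespie Mk histories have Poisson-consistent event counts and parity", {
  tr <- fixture_isopod_tree()
  q <- 0.01
  m <- mk_model(c("XY", "ZW"), "ER", q)
  total_len <- sum(tr$edge.length)
  counts <- vapply(1:200, function(s)
    simulate_mk_history(tr, m, seed = s)$n_events, numeric(1))
  expect_equal(mean(counts), q * total_len, tolerance = 0.12)

  # zero rate: all tips share the root state
  m0 <- mk_model(c("XY", "ZW"), "ER", 1e-300)
  h0 <- simulate_mk_history(tr, m0, seed = 1)
  expect_equal(h0$n_events, 0)
  expect_length(unique(unclass(h0$tip_states)), 1)

  # two-state parity: a tip differs from the root iff its path has an odd
  # number of events
  h <- simulate_mk_history(tr, m, seed = 17)
  if (h$n_events > 0) {
    tt <- isopodSD:::tree_traversal(tr)
    parents <- integer(length(h$node_states))
    for (p in seq_along(tt$children))
      if (!is.null(tt$children[[p]])) parents[tt$children[[p]]] <- p
    per_edge <- table(factor(h$events$edge, levels = seq_along(parents)))
    for (tip in seq_len(tt$n_tip)) {
      v <- tip; n_path <- 0
      while (v != tt$root) {
        n_path <- n_path + as.numeric(per_edge[v]); v <- parents[v]
      }
      differs <- h$node_states[tip] != h$root_state
      expect_equal(differs, n_path %% 2 == 1)
    }
  }
})

test_that("WW-viability verdict recovery improves with pooled brood size", {
  # grid over brood sizes at a fixed number of clean broods: the fraction
  # of ZW/WW-viable simulations called "viable" must rise with size
  frac_viable <- function(brood_mean, n_rep = 60) {
    hits <- vapply(seq_len(n_rep), function(r) {
      cfg <- experiment_config("ZW", ww_viable = TRUE,
                               n_females_injected = 3,
                               reversal_failure_rate = 0, death_rate = 0,
                               wolbachia_prevalence = 0,
                               broods_per_neomale = 2,
                               brood_mean = brood_mean,
                               brood_dispersion = 10)
      sim <- simulate_experiment(cfg, seed = r + round(brood_mean) * 101)
      kept <- suppressWarnings(filter_broods(sim$broods))$kept
      if (nrow(kept) == 0) return(NA)
      classify_species(kept)$ww_viability == "viable"
    }, logical(1))
    mean(hits, na.rm = TRUE)
  }
  grid <- vapply(c(15, 60, 250), frac_viable, numeric(1))
  expect_true(all(diff(grid) > -0.05))   # non-decreasing within MC noise
  expect_gt(grid[3], grid[1])
  expect_gt(grid[3], 0.8)
})
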