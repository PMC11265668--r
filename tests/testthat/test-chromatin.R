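test_that("the effective methylation probability follows the proximity-gated rule", {
  nbr <- linear_neighbors(5)
  lat <- c(0L, 0L, 1L, 0L, 0L)  # centre modified
  # no complex proximal -> 0 regardless of neighbours
  expect_identical(effective_methylation_prob(2, lat, nbr, FALSE, 0.5, 1), 0)
  # proximal complex, modified neighbour: the pure reader-writer regime
  expect_identical(effective_methylation_prob(2, lat, nbr, TRUE, 0, 1), 1)
  # proximal complex, no modified neighbour, writer-only pathway
  expect_identical(effective_methylation_prob(5, lat, nbr, TRUE, 0.1, 1), 0.1)
  # clamped at 1
  expect_identical(effective_methylation_prob(2, lat, nbr, TRUE, 0.3, 0.9), 1)
  # contract: must not be called on a modified site
  expect_error(effective_methylation_prob(3, lat, nbr, TRUE, 0, 1),
               "already-modified")
})

test_that("a methylation sweep is synchronous and respects proximity", {
  sites <- tibble::tibble(x = as.numeric(-2:2), y = 0)
  nbr <- linear_neighbors(5)
  lat <- c(0L, 0L, 1L, 0L, 0L)

  # no complexes anywhere: unchanged
  none <- particle_system()
  expect_identical(methylation_sweep(lat, none, nbr, sites, 1, 0, 1), lat)

  # complexes proximal to every site, p_m = 1: exactly the +-1 neighbours
  # flip in one sweep; +-2 must wait (synchronous update)
  set.seed(501)
  everywhere <- particle_system(x = as.numeric(-2:2), y = rep(0, 5),
                                species = rep("C", 5))
  out <- methylation_sweep(lat, everywhere, nbr, sites, 0.5, 0, 1)
  expect_identical(out, c(0L, 1L, 1L, 1L, 0L))

  # island flanked by two modified neighbours: methylated with probability
  # exactly 1 (binary neighbour term), never more
  lat2 <- c(0L, 1L, 0L, 1L, 0L)
  out2 <- methylation_sweep(lat2, everywhere, nbr, sites, 0.5, 0, 1)
  expect_identical(out2[3], 1L)
})

test_that("demethylation spares the pinned nucleation point", {
  lat <- rep(1L, 11)
  out <- demethylation_sweep(lat, 1, nucleation_enabled = TRUE, np_site = 6)
  expect_identical(out, c(rep(0L, 5), 1L, rep(0L, 5)))
  expect_identical(demethylation_sweep(lat, 0), lat)

  # binomial flip count at small p
  set.seed(502)
  flips <- replicate(2000, {
    sum(demethylation_sweep(rep(1L, 61), 0.01, TRUE, 31) == 0)
  })
  expect_lt(abs(mean(flips) - 0.6), 3 * sd(flips) / sqrt(2000))
})

test_that("with no writer pathway and no nucleation an all-U lattice is absorbing", {
  p <- rd_params(n_nucleosomes = 11, radius = 8, n_enzymes = 30,
                 p_rp = 0.05, p_rd = 0.01, p_cd = 1e-4, p_w = 0,
                 nucleation = FALSE, n_steps = 2e4, burn_in = 0,
                 sample_interval = 100, seed = 503)
  run <- run_rd_simulation(p)
  expect_identical(sum(run$samples), 0L)
})
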