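test_that("RNA production is a single Bernoulli source at the origin", {
  sys0 <- particle_system()
  set.seed(401)
  expect_identical(nrow(produce_rna(sys0, 0)), 0L)
  sys1 <- produce_rna(sys0, 1, origin_position = c(2, -1))
  expect_identical(nrow(sys1), 1L)
  expect_identical(sys1$species, "R")
  expect_equal(c(sys1$x, sys1$y), c(2, -1))

  # binomial expectation over many steps
  n_steps <- 1e4
  p <- 0.01
  events <- sum(replicate(n_steps, nrow(produce_rna(sys0, p)) > 0))
  expect_lt(abs(events - n_steps * p), 3 * sqrt(n_steps * p * (1 - p)))
})

test_that("RNA decay removes each R independently", {
  set.seed(402)
  sys <- particle_system(x = rnorm(20), y = rnorm(20),
                         species = rep(c("R", "E"), 10))
  gone <- decay_rna(sys, 1)
  expect_identical(sort(unique(gone$species)), "E")
  expect_identical(nrow(decay_rna(sys, 0)), nrow(sys))
})

test_that("complex formation obeys the matching rule and at-most-one reaction per particle", {
  # no E within reach: unchanged
  far <- particle_system(x = c(0, 10), y = c(0, 0), species = c("R", "E"))
  expect_identical(form_complexes(far, 1, 1)$species, far$species)

  # forced reaction: one pair in contact
  set.seed(403)
  pair <- particle_system(x = c(0, 0.5), y = c(0, 0), species = c("R", "E"))
  out <- form_complexes(pair, 1, 1)
  expect_identical(out$species, "C")
  expect_equal(out$x, 0.5)  # C inherits the enzyme position

  # two R equidistant from one E: exactly one reacts
  tri <- particle_system(x = c(-0.5, 0.5, 0), y = c(0, 0, 0),
                         species = c("R", "R", "E"))
  out2 <- form_complexes(tri, 1, 1)
  expect_identical(sort(out2$species), c("C", "R"))

  # enzyme conservation across the full reaction set
  set.seed(404)
  sys <- particle_system(x = runif(40, -2, 2), y = runif(40, -2, 2),
                         species = sample(c("E", "R", "C"), 40, TRUE))
  ne0 <- sum(sys$species %in% c("E", "C"))
  for (i in 1:20) {
    sys <- sys |> decay_rna(0.1) |> produce_rna(0.5) |>
      form_complexes(1, 1) |> decay_complexes(0.2)
    expect_identical(sum(sys$species %in% c("E", "C")), ne0)
  }
})

test_that("complex decay converts C to E in place", {
  sys <- particle_system(x = c(1, 2), y = c(0, 0), species = c("C", "C"))
  out <- decay_complexes(sys, 1)
  expect_identical(out$species, c("E", "E"))
  expect_equal(out$x, c(1, 2))
  expect_identical(decay_complexes(sys, 0)$species, c("C", "C"))
})

test_that("stationary RNA count approaches p_rp / p_rd in an enzyme-free run", {
  p <- rd_params(n_nucleosomes = 11, radius = 8, n_enzymes = 0,
                 p_rp = 0.05, p_rd = 0.01, n_steps = 4e4, burn_in = 2e4,
                 sample_interval = 50, seed = 405)
  run <- run_rd_simulation(p, keep_samples = FALSE)
  expect_equal(mean(run$counts$n_r), 0.05 / 0.01, tolerance = 0.2)
})
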