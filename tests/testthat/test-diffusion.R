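test_that("zero mobility leaves positions unchanged and variance matches 2*D per axis", {
  pts <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  expect_identical(langevin_step(pts, 0)$x, pts$x)
  expect_error(langevin_step(pts, -1), "d_tilde")

  set.seed(301)
  d_tilde <- 2e-4
  one <- langevin_step(tibble::tibble(x = numeric(2e5), y = numeric(2e5)),
                       d_tilde)
  v <- var(one$x)
  # chi-square CI for a variance estimate from 2e5 draws is ~ +-0.7%
  expect_lt(abs(v - 2 * d_tilde) / (2 * d_tilde), 0.02)
})

test_that("radial mirroring maps outside points in, fixes inside points, and is idempotent", {
  r <- 5
  inside <- tibble::tibble(x = 0.3 * r, y = 0)
  expect_equal(reflect_into_disc(inside, r), inside)
  boundary <- tibble::tibble(x = r, y = 0)
  expect_equal(reflect_into_disc(boundary, r), boundary)
  eps <- 0.01
  out <- reflect_into_disc(tibble::tibble(x = r + eps, y = 0), r)
  expect_equal(out$x, r - eps)
  # far outside: folds iteratively and lands inside
  far <- reflect_into_disc(tibble::tibble(x = 3.7 * r, y = 0.2), r)
  expect_lte(sqrt(far$x^2 + far$y^2), r)
  expect_error(reflect_into_disc(tibble::tibble(x = NaN, y = 0), r),
               "non-finite")

  set.seed(302)
  pts <- tibble::tibble(x = runif(500, -3 * r, 3 * r),
                        y = runif(500, -3 * r, 3 * r))
  once <- reflect_into_disc(pts, r)
  expect_true(all(sqrt(once$x^2 + once$y^2) <= r + 1e-12))
  expect_equal(reflect_into_disc(once, r), once)
})

test_that("confined non-reacting walkers equilibrate to the uniform disc measure", {
  set.seed(303)
  r <- 5
  n_walkers <- 2000
  # small steps (0.45 sigma against a 5 sigma disc) keep the radial-mirror
  # boundary scheme accurate; 400 steps is several times the disc mixing
  # time r^2 / (4 D), so the walkers' final positions are independent
  # draws from the stationary law
  pos <- tibble::tibble(x = numeric(n_walkers), y = numeric(n_walkers))
  for (i in 1:400) pos <- reflect_into_disc(langevin_step(pos, 0.1), r)
  rad <- sqrt(pos$x^2 + pos$y^2)
  edges <- seq(0, r, length.out = 6)
  obs <- table(cut(rad, edges, include.lowest = TRUE))
  p_area <- diff(edges^2) / r^2
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p_area))
  expect_gt(chi$p.value, 1e-4)
})

test_that("unconfined mean squared displacement follows the 2D diffusion law", {
  set.seed(304)
  d_tilde <- 2e-4
  n_walkers <- 2000
  n_steps <- 300
  pts <- tibble::tibble(x = numeric(n_walkers), y = numeric(n_walkers))
  for (i in seq_len(n_steps)) pts <- langevin_step(pts, d_tilde)
  msd <- mean(pts$x^2 + pts$y^2)
  expected <- 4 * d_tilde * n_steps
  # per-walker R^2 is 2*D*chi^2_{2n}; 3-sigma band for the ensemble mean
  se <- sd(pts$x^2 + pts$y^2) / sqrt(n_walkers)
  expect_lt(abs(msd - expected), 3 * se + 0.02 * expected)
})
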