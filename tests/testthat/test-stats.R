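test_that("profile width follows the literal second-moment formula", {
  point <- tibble::tibble(site = -2:2, p_m = c(0, 0, 1, 0, 0))
  expect_identical(profile_sd(point), 0)
  two <- tibble::tibble(site = -1:1, p_m = c(0.5, 0, 0.5))
  expect_identical(profile_sd(two), 1)

  # literal and normalized modes coincide on unit-mass profiles
  set.seed(801)
  for (i in 1:20) {
    p <- runif(11)
    prof <- tibble::tibble(site = -5:5, p_m = p / sum(p))
    expect_equal(profile_sd(prof), profile_sd(prof, normalize = TRUE))
  }

  # asymmetric super-unit mass: the literal radicand goes negative and the
  # failure must be loud
  bad <- tibble::tibble(site = 0:2, p_m = c(0, 1, 1))
  expect_error(profile_sd(bad), "negative radicand")
  expect_equal(profile_sd(bad, normalize = TRUE), 0.5)
})

test_that("profile kurtosis matches its limiting shapes", {
  two <- tibble::tibble(site = c(-1, 1), p_m = c(0.5, 0.5))
  expect_identical(profile_kurtosis(two), 1)

  # fine discretized Gaussian -> 3
  x <- -300:300
  gauss <- tibble::tibble(site = x, p_m = exp(-x^2 / (2 * 50^2)))
  expect_equal(profile_kurtosis(gauss), 3, tolerance = 1e-3)

  # broad uniform -> 9/5
  unif <- tibble::tibble(site = -300:300, p_m = rep(1, 601))
  expect_equal(profile_kurtosis(unif), 1.8, tolerance = 1e-4)

  flat0 <- tibble::tibble(site = 0, p_m = 1)
  expect_error(profile_kurtosis(flat0), "variance")
})

test_that("widening a profile by symmetric convolution cannot shrink its width", {
  set.seed(802)
  kernel <- c(0.25, 0.5, 0.25)
  for (i in 1:10) {
    p <- runif(21)
    p <- p / sum(p)
    # convolve on a padded lattice so no kernel mass falls off the ends
    padded <- c(0, p, 0)
    smooth <- sapply(seq_along(padded), function(j) {
      lo <- max(1, j - 1); hi <- min(length(padded), j + 1)
      sum(padded[lo:hi] * kernel[(lo:hi) - j + 2])
    })
    prof <- tibble::tibble(site = -10:10, p_m = p)
    prof2 <- tibble::tibble(site = -11:11, p_m = smooth / sum(smooth))
    expect_gte(profile_sd(prof2, normalize = TRUE) + 1e-9,
               profile_sd(prof, normalize = TRUE))
  }
})

test_that("shell densities implement the annulus formula", {
  empty <- rna_shell_density(tibble::tibble(x = numeric(), y = numeric()),
                             dr = 1, r_max = 3)
  expect_identical(empty$density, rep(0, 3))

  one <- rna_shell_density(tibble::tibble(x = 0.5, y = 0), dr = 1, r_max = 3)
  expect_equal(one$density[1], 1 / pi)
  expect_identical(one$count, c(1L, 0L, 0L))
  expect_identical(sum(one$count), 1L)

  # uniform points on a disc give constant density across shells
  set.seed(803)
  n <- 2e4; r <- 10
  rad <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  sh <- rna_shell_density(tibble::tibble(x = rad * cos(th),
                                         y = rad * sin(th)),
                          dr = 2, r_max = 10)
  expected <- n / (pi * r^2)
  expect_true(all(abs(sh$density - expected) / expected < 0.15))
})

test_that("complex proximity counts average over snapshots", {
  sites <- tibble::tibble(site = 1:3, x = c(0, 5, 10), y = 0)
  none <- tibble::tibble(sample = 1, x = numeric(), y = numeric(),
                         species = character())
  expect_identical(complex_proximity_profile(none, sites)$c_p, rep(0, 3))
  snaps <- tibble::tibble(sample = rep(1:2, each = 1), x = c(5, 5),
                          y = c(0, 0), species = "C")
  out <- complex_proximity_profile(snaps, sites, d_prox = 1)
  expect_identical(out$c_p, c(0, 1, 0))
})

test_that("the RNA length scale is a diffusion-decay balance", {
  expect_equal(rna_length_scale(2e-4, 1e-3), sqrt(0.2), tolerance = 1e-12)
  expect_equal(rna_length_scale(8e-4, 1e-3), 2 * rna_length_scale(2e-4, 1e-3))
  expect_identical(rna_length_scale(2e-4, 0), Inf)

  # empirical: almost no stationary RNA lives beyond 5 * l_r
  p <- rd_params(n_nucleosomes = 5, radius = 10, n_enzymes = 0,
                 p_rp = 0.2, p_rd = 0.01, n_steps = 4e4, burn_in = 1e4,
                 sample_interval = 100, seed = 804)
  run <- run_rd_simulation(p, shell_dr = 0.2)
  lr <- rna_length_scale(p$d_tilde, p$p_rd)
  frac_beyond <- sum(run$shells$mean_count[run$shells$r_lo >= 5 * lr]) /
    sum(run$shells$mean_count)
  expect_lt(frac_beyond, 0.05)
})

test_that("quadratic trends are recovered by least squares", {
  x <- seq(0, 2, length.out = 9)
  exact <- fit_quadratic_trend(x, 3 * x^2 - x + 0.5)
  expect_equal(c(exact$a, exact$b, exact$c), c(3, -1, 0.5), tolerance = 1e-10)

  lin <- fit_quadratic_trend(x, 2 * x + 3)
  expect_equal(c(lin$a, lin$b, lin$c), c(0, 2, 3), tolerance = 1e-10)

  set.seed(805)
  noisy <- fit_quadratic_trend(x, 54 * x^2 + 2 * x + 3 + rnorm(9, 0, 0.5))
  td <- tidy(noisy)
  expect_lt(abs(td$estimate[td$term == "a"] - 54),
            3 * td$std.error[td$term == "a"])

  expect_error(fit_quadratic_trend(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_quadratic_trend(1:2, 1:2), ">= 3")
})

test_that("bedGraph export writes half-open 0-based intervals", {
  prof <- tibble::tibble(site = -1:1, p_m = c(0.25, 1, 0.5))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  export_bedgraph(prof, path, chrom = "chrT", bin_bp = 200)
  lines <- readLines(path)
  body <- lines[!grepl("^track|^#", lines)]
  fields <- do.call(rbind, strsplit(body, "\t"))
  expect_identical(fields[, 1], rep("chrT", 3))
  expect_identical(as.integer(fields[1, 2:3]), c(0L, 200L))
  expect_identical(as.integer(fields[3, 2:3]), c(400L, 600L))
})
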