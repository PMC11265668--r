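test_that("the spatial rate reduces correctly at its landmarks", {
  expect_identical(spatial_rate(0, 2, 5), 2)
  expect_equal(spatial_rate(5, 2, 5), 2 / exp(1))
  expect_equal(spatial_rate(-5, 2, 5), 2 / exp(1))
  expect_identical(spatial_rate(c(0, 3, 9), 2, Inf), c(2, 2, 2))
  expect_error(spatial_rate(0, 1, 0), "l_d")
})

test_that("zero spreading rate freezes the delta profile at the nucleation point", {
  run <- gillespie_run(kmc_params(n_sites = 5, k_plus = 0, k_minus = 1,
                                  n_events = 100, seed = 701))
  expect_true(run$absorbed)
  expect_identical(run$profile$p_m, as.numeric(run$profile$site == 0))
})

test_that("the master equation solves the two-site truncation in closed form", {
  for (K in c(0.5, 0.9, 1.3)) {
    me <- master_equation_profile(3, k_plus = K, k_minus = 1)
    expect_equal(me$p_m[me$site == 1], K / (1 + K), tolerance = 1e-12)
    # symmetry of the generator (up to solver round-off)
    expect_equal(me$p_m[me$site == 1], me$p_m[me$site == -1],
                 tolerance = 1e-12)
  }
  # removal negligible -> everything modified
  me_inf <- master_equation_profile(3, k_plus = 1e8, k_minus = 1)
  expect_equal(me_inf$p_m, rep(1, 3), tolerance = 1e-6)
  expect_error(master_equation_profile(15, 1, 1), "capped")
})

test_that("Gillespie sampling agrees with the exact master equation on small lattices", {
  for (K in c(0.5, 1.3)) {
    me <- master_equation_profile(5, k_plus = K, k_minus = 1)
    mc <- gillespie_run(kmc_params(n_sites = 5, k_plus = K, k_minus = 1,
                                   n_events = 4e5, seed = 702))
    off_np <- mc$profile$site != 0
    dev <- abs(mc$profile$p_m - me$p_m)[off_np]
    tol <- 3 * mc$profile$se[off_np] + 1e-3
    expect_true(all(dev < tol))
  }
})

test_that("the binary-propensity switch matches its own master equation", {
  me <- master_equation_profile(5, k_plus = 1.1, k_minus = 1,
                                binary_propensity = TRUE)
  mc <- gillespie_run(kmc_params(n_sites = 5, k_plus = 1.1, k_minus = 1,
                                 n_events = 3e5, binary_propensity = TRUE,
                                 seed = 703))
  expect_true(all(abs(mc$profile$p_m - me$p_m) < 3 * mc$profile$se + 1e-3))
})

test_that("profile width grows with K and l_d = Inf reproduces the basic model", {
  sms <- sapply(c(0.5, 1.0), function(K)
    profile_sd(gillespie_run(kmc_params(n_sites = 21, k_plus = K,
                                        k_minus = 1, n_events = 2e5,
                                        seed = 704))))
  expect_lt(sms[1], sms[2])

  basic <- gillespie_run(kmc_params(n_sites = 21, k_plus = 0.9, k_minus = 1,
                                    n_events = 1e5, seed = 705))
  spatial <- gillespie_run(kmc_params(n_sites = 21, k0 = 0.9, l_d = Inf,
                                      k_minus = 1, n_events = 1e5,
                                      seed = 705))
  expect_identical(basic$profile$p_m, spatial$profile$p_m)
})
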