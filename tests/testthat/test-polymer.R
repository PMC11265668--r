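test_that("random walks take unit square-lattice steps and are seed-deterministic", {
  set.seed(901)
  two <- generate_rw_2d(2)
  expect_equal(end_to_end_sq(two), 1)
  walk <- generate_rw_2d(50)
  bond <- sqrt(diff(walk$beads$x)^2 + diff(walk$beads$y)^2)
  expect_identical(unname(bond), rep(1, 49))
  # nucleation bead at the origin
  expect_identical(walk$beads$x[walk$np_bead], 0)

  set.seed(902); a <- generate_rw_2d(30)
  set.seed(902); b <- generate_rw_2d(30)
  expect_identical(a$beads, b$beads)
  expect_error(generate_rw_2d(1), ">= 2")
})

test_that("random-walk mean squared end-to-end distance equals n - 1", {
  set.seed(903)
  n <- 60
  r2 <- replicate(3000, end_to_end_sq(generate_rw_2d(n)))
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - (n - 1)), 3 * se)
})

test_that("self-avoiding walks are self-avoiding and visit both 3-bead shapes", {
  set.seed(904)
  cfgs <- saw_ensemble(3, 300, burn_accepts = 30, decorrelate = 5)
  keys <- sapply(cfgs, function(cf) paste(cf$beads$x, cf$beads$y,
                                          collapse = ";"))
  r2 <- sapply(cfgs, end_to_end_sq)
  # straight (R2 = 4) and bent (R2 = 2) both occur; immediate reversal
  # (R2 = 0) never occurs
  expect_setequal(sort(unique(r2)), c(2, 4))

  big <- saw_ensemble(40, 5)
  for (cf in big)
    expect_identical(anyDuplicated(paste(cf$beads$x, cf$beads$y)), 0L)
})

test_that("the pivot sampler reproduces exact enumeration at n = 10", {
  oracle <- enumerate_saw_r2(9)
  expect_identical(oracle$count, 16268)   # frozen from the enumeration oracle
  set.seed(905)
  r2 <- sapply(saw_ensemble(10, 1500, decorrelate = 60), end_to_end_sq)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - oracle$mean_r2), 3.5 * se)
})

test_that("SAW end-to-end scaling is consistent with the 2D Flory exponent", {
  set.seed(906)
  ns <- c(20, 50, 100)
  mean_r2 <- sapply(ns, function(n)
    mean(sapply(saw_ensemble(n, 150), end_to_end_sq)))
  slope <- coef(lm(log(mean_r2) ~ log(ns - 1)))[2]
  expect_equal(unname(slope), 1.5, tolerance = 0.1)
})

test_that("contact neighbourhoods include backbone, coincidence and spatial contacts", {
  rod <- rod_config(5)
  nb <- contact_neighbors(rod, 1.0)$neighbors
  expect_identical(nb, linear_neighbors(5))

  # U-shaped 6-bead walk: ends at distance 1 become contact neighbours
  u <- structure(list(beads = tibble::tibble(
    bead = 1:6, x = c(0, 1, 2, 2, 1, 0), y = c(0, 0, 0, 1, 1, 1)),
    walk_type = "SAW", contact_cutoff = NULL, neighbors = NULL,
    np_bead = 3L), class = "polymer_config")
  nb_u <- contact_neighbors(u, 1.0)$neighbors
  expect_true(6 %in% nb_u[[1]] && 1 %in% nb_u[[6]])

  # coincident beads in a revisiting RW are neighbours
  rw <- structure(list(beads = tibble::tibble(
    bead = 1:3, x = c(0, 1, 0), y = c(0, 0, 0)),
    walk_type = "RW", contact_cutoff = NULL, neighbors = NULL,
    np_bead = 2L), class = "polymer_config")
  nb_rw <- contact_neighbors(rw, 1.0)$neighbors
  expect_true(3 %in% nb_rw[[1]])

  # symmetry
  set.seed(907)
  cfg <- contact_neighbors(generate_rw_2d(30), 1.5)
  for (i in seq_along(cfg$neighbors))
    for (j in cfg$neighbors[[i]])
      expect_true(i %in% cfg$neighbors[[j]])

  expect_error(contact_neighbors(rod, 0.5), "contact_cutoff")
})

test_that("polymer files round-trip and invariants are enforced on read", {
  set.seed(908)
  cfg <- generate_saw_2d(15)
  path <- withr::local_tempfile(fileext = ".txt")
  write_polymer(cfg, path)
  back <- read_polymer(path, walk_type = "SAW")
  expect_equal(back$beads$x, cfg$beads$x)
  expect_equal(back$beads$y, cfg$beads$y)

  writeLines(c("1 0 0", "2 2 0"), path)   # broken bond
  expect_error(read_polymer(path), "bond")
  writeLines(c("1 0 0", "2 1 0", "3 0"), path)
  expect_error(read_polymer(path), "line 3")
})

test_that("a one-config rod ensemble reduces to the linear-lattice run", {
  p <- fast_params()
  ens <- run_polymer_ensemble(p, 1, configs = list(rod_config(11)))
  linear <- run_rd_simulation(p)
  expect_equal(ens$profile$p_m, linear$profile$p_m)
})

test_that("frozen configurations stay frozen and the ensemble peaks at the nucleation bead", {
  p <- fast_params(n_nucleosomes = 21, radius = 25, n_steps = 6000,
                   burn_in = 2000, sample_interval = 100, p_rp = 0.05,
                   p_cd = 1e-4)
  ens <- run_polymer_ensemble(p, 4, walk_type = "RW")
  for (cf in ens$configs) {
    bond <- sqrt(diff(cf$beads$x)^2 + diff(cf$beads$y)^2)
    expect_identical(unname(bond), rep(1, 20))
  }
  # the pinned nucleation bead attains the ensemble maximum (P = 1 there;
  # neighbouring beads may tie at small sample sizes)
  p_np <- ens$profile$p_m[ens$profile$site == 0]
  expect_identical(p_np, 1)
  expect_identical(p_np, max(ens$profile$p_m))
  g <- glance(ens)
  expect_identical(g$walk_type, "RW")
  expect_identical(g$n_configs, 4L)
})
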