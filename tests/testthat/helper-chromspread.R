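# small, fast parameter sets used across the unit tests
fast_params <- function(...) {
  defaults <- list(n_nucleosomes = 11, radius = 8, n_enzymes = 30,
                   p_rp = 0.02, p_rd = 0.01, p_cd = 1e-4, p_dm = 0.005,
                   n_steps = 3000, burn_in = 1000, sample_interval = 50,
                   seed = 42)
  do.call(rd_params, utils::modifyList(defaults, list(...)))
}

# build a straight-rod polymer configuration (site i at (i - np, 0))
rod_config <- function(n_beads) {
  np <- (n_beads + 1L) %/% 2L
  beads <- tibble::tibble(bead = seq_len(n_beads),
                          x = as.numeric(seq_len(n_beads) - np), y = 0)
  cfg <- structure(list(beads = beads, walk_type = "ROD",
                        contact_cutoff = NULL, neighbors = NULL,
                        np_bead = np),
                   class = "polymer_config")
  contact_neighbors(cfg, 1.5)
}

# exact mean squared end-to-end distance over every square-lattice SAW of
# n_steps steps, by depth-first enumeration (independent of the pivot code)
enumerate_saw_r2 <- function(n_steps) {
  count <- 0
  sum_r2 <- 0
  xs <- integer(n_steps + 1)
  ys <- integer(n_steps + 1)
  rec <- function(k) {
    if (k == n_steps + 1) {
      count <<- count + 1
      sum_r2 <<- sum_r2 + (xs[k] - xs[1])^2 + (ys[k] - ys[1])^2
      return()
    }
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nx <- xs[k] + d[1]; ny <- ys[k] + d[2]
      clash <- FALSE
      for (j in seq_len(k))
        if (xs[j] == nx && ys[j] == ny) { clash <- TRUE; break }
      if (!clash) {
        xs[k + 1] <<- nx; ys[k + 1] <<- ny
        rec(k + 1)
      }
    }
  }
  rec(1L)
  list(count = count, mean_r2 = sum_r2 / count)
}
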