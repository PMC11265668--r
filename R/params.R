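#' Parameters for one reaction-diffusion run
#'
#' Collects every probability, count and length that governs a single
#' particle-based reaction-diffusion simulation.  Lengths are in units of the
#' particle diameter \eqn{\sigma}; one lattice spacing between neighbouring
#' nucleosomes is \eqn{1\sigma}.  All reaction parameters are probabilities
#' per timestep (Bernoulli trials), not rates.
#'
#' The dimensionless diffusion constant `d_tilde` absorbs the physical
#' constants: \eqn{\tilde D = \mu k_B T \Delta t / \sigma^2}.  With a particle
#' of 5--10 nm diffusing at \eqn{10^{-3}\,\mu m^2/s} in the crowded
#' nucleoplasm, \eqn{\tilde D = 2\times10^{-4}} per step is a realistic
#' coarse-grained value and is the default used throughout.
#'
#' @param n_nucleosomes Number of lattice sites (odd, so sites are indexed
#'   `-(n-1)/2 ... (n-1)/2` around the nucleation point at 0).  The odd
#'   constraint applies to the linear lattice; polymer runs take their site
#'   count from the bead configuration.
#' @param radius Disc radius of the simulation space, in sigma.  Must be at
#'   least `(n_nucleosomes - 1) / 2` so the lattice fits inside the disc.
#' @param n_enzymes Number of enzyme particles, uniformly distributed at the
#'   start; enzymes are conserved (E -> C -> E), so `count(E) + count(C)`
#'   stays at `n_enzymes` forever.
#' @param d_tilde Dimensionless per-step diffusion constant (default `2e-4`).
#' @param p_rp RNA production probability per step (source at the nucleation
#'   point only).
#' @param p_rd RNA decay probability per step, anywhere in space.
#' @param p_cp Complex-formation probability when an E and an R are within
#'   `d_prox` (default 1: diffusion-limited binding).
#' @param p_cd Complex decay probability per step (C -> E, the RNA component
#'   is destroyed).
#' @param p_w "Writer" probability: a proximal complex deposits the mark even
#'   without a modified neighbour.  Zero except in the no-nucleation variant.
#' @param p_m "Reader-writer" boost: a proximal complex deposits the mark on
#'   a site with at least one modified neighbour with probability
#'   `min(1, p_w + p_m)`.
#' @param p_dm Demethylation probability per step for each modified site
#'   (the pinned nucleation point is exempt).
#' @param d_prox Proximity radius in sigma for every contact test
#'   (E--R encounters and complex--nucleosome proximity).  Default 1 sigma,
#'   one particle diameter.
#' @param nucleation If `TRUE` (default) the site at the origin is pinned in
#'   the modified state and excluded from demethylation.
#' @param n_steps,burn_in,sample_interval Run length, number of initial steps
#'   discarded, and the spacing of retained snapshots (`burn_in < n_steps`,
#'   `sample_interval >= 1`).
#' @param particle_cap Soft cap on the total particle count; RNA production is
#'   unbounded, so a run that exceeds the cap raises a warning.
#' @param seed RNG seed for the run.
#' @param geometry `"linear"` (default) for the 1D nucleosome lattice, or
#'   `"polymer"` when the run will use a frozen polymer configuration; the
#'   linear-lattice constraints (odd site count, lattice-in-disc radius) do
#'   not apply to polymer runs, whose containment is checked against the
#'   bead coordinates at run time.
#'
#' @return An object of class `rd_params` (a validated named list).
#' @examples
#' p <- rd_params(n_steps = 2000, burn_in = 500, sample_interval = 50)
#' p$p_rd
#' @export
rd_params <- function(n_nucleosomes = 61, radius = 40, n_enzymes = 500,
                      d_tilde = 2e-4, p_rp = 1e-3, p_rd = 1e-3, p_cp = 1,
                      p_cd = 1e-6, p_w = 0, p_m = 1, p_dm = 1e-3,
                      d_prox = 1, nucleation = TRUE,
                      n_steps = 2e5, burn_in = 1e5, sample_interval = 500,
                      particle_cap = 1e5, seed = 1L,
                      geometry = c("linear", "polymer")) {
  geometry <- match.arg(geometry)
  p <- list(n_nucleosomes = as.integer(n_nucleosomes), radius = radius,
            n_enzymes = as.integer(n_enzymes), d_tilde = d_tilde,
            p_rp = p_rp, p_rd = p_rd, p_cp = p_cp, p_cd = p_cd,
            p_w = p_w, p_m = p_m, p_dm = p_dm, d_prox = d_prox,
            nucleation = isTRUE(nucleation),
            n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
            sample_interval = as.integer(sample_interval),
            particle_cap = particle_cap, seed = as.integer(seed),
            geometry = geometry)
  class(p) <- "rd_params"
  validate_rd_params(p)
  p
}

#' Validate reaction-diffusion parameters
#'
#' Checks every invariant of [rd_params()]; errors name the violated
#' invariant.  Called automatically by the constructor and by the run
#' orchestrator.
#'
#' @param p An `rd_params` object (or a compatible named list).
#' @param polymer Optional polymer configuration; when supplied the linear
#'   lattice constraints (odd site count, lattice-in-disc radius) are replaced
#'   by the polymer containment check.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_rd_params <- function(p, polymer = NULL) {
  bad <- function(msg) abort(paste0("invalid rd_params: ", msg),
                             class = "chromspread_config_error")
  probs <- c("p_rp", "p_rd", "p_cp", "p_cd", "p_w", "p_m", "p_dm")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      bad(sprintf("probability `%s` must lie in [0, 1] (got %s)", nm,
                  format(v)))
  }
  if (!is.numeric(p$d_tilde) || is.na(p$d_tilde) || p$d_tilde < 0)
    bad("`d_tilde` must be >= 0")
  if (!is.numeric(p$d_prox) || is.na(p$d_prox) || p$d_prox <= 0)
    bad("`d_prox` must be > 0")
  if (is.na(p$n_enzymes) || p$n_enzymes < 0)
    bad("`n_enzymes` must be a non-negative integer")
  if (!is.numeric(p$radius) || is.na(p$radius) || p$radius <= 0)
    bad("`radius` must be > 0")
  if (is.null(polymer)) {
    n <- p$n_nucleosomes
    if (is.na(n) || n < 1)
      bad("`n_nucleosomes` must be a positive integer")
    if (identical(p$geometry %||% "linear", "linear")) {
      if (n %% 2 != 1)
        bad("`n_nucleosomes` must be an odd positive integer on the linear lattice")
      if (p$radius < (n - 1) / 2)
        bad(sprintf(
          "`radius` (%s) must be >= (n_nucleosomes - 1)/2 = %s so the lattice fits inside the disc",
          format(p$radius), (n - 1) / 2))
    }
  } else {
    max_r <- max(sqrt(polymer$beads$x^2 + polymer$beads$y^2))
    if (p$radius < max_r + 2)
      bad(sprintf(
        "`radius` (%s) must be >= max polymer bead radius + 2 sigma (= %.2f)",
        format(p$radius), max_r + 2))
  }
  if (is.na(p$n_steps) || p$n_steps < 1) bad("`n_steps` must be >= 1")
  if (is.na(p$burn_in) || p$burn_in < 0 || p$burn_in >= p$n_steps)
    bad("`burn_in` must satisfy 0 <= burn_in < n_steps")
  if (is.na(p$sample_interval) || p$sample_interval < 1)
    bad("`sample_interval` must be >= 1")
  invisible(p)
}

#' @export
print.rd_params <- function(x, ...) {
  cat("<rd_params>\n")
  cat(sprintf("  lattice: %d sites, disc radius %g sigma, %d enzymes\n",
              x$n_nucleosomes, x$radius, x$n_enzymes))
  cat(sprintf("  d_tilde = %g, d_prox = %g, nucleation = %s\n",
              x$d_tilde, x$d_prox, x$nucleation))
  cat(sprintf("  p_rp = %g, p_rd = %g, p_cp = %g, p_cd = %g\n",
              x$p_rp, x$p_rd, x$p_cp, x$p_cd))
  cat(sprintf("  p_w = %g, p_m = %g, p_dm = %g\n", x$p_w, x$p_m, x$p_dm))
  cat(sprintf("  %d steps (burn-in %d, sample every %d), seed %d\n",
              x$n_steps, x$burn_in, x$sample_interval, x$seed))
  invisible(x)
}

#' Parameters for the reaction-only Gillespie model
#'
#' The kinetic comparator is a contact process on an odd lattice pinned at
#' the nucleation point: a U site with `m` modified neighbours gains the mark
#' at rate `m * k_plus` (additive propensity per modified neighbour), a
#' modified site other than the NP loses it at rate `k_minus`.  The
#' behaviour is governed by `K = k_plus / k_minus`.  The space-dependent
#' variant replaces `k_plus` by `k0 * exp(-|i| / l_d)`; `l_d = Inf` recovers
#' the basic model with `k_plus = k0`.
#'
#' @param n_sites Odd number of lattice sites (default 61, sites -30..30).
#' @param k_plus Spreading rate per modified neighbour.
#' @param k_minus Removal rate.
#' @param k0,l_d Amplitude and decay length of the space-dependent spreading
#'   rate; leave `k0 = NULL` for the basic model.
#' @param n_events Number of Gillespie events to simulate.
#' @param burn_frac Fraction of events discarded before time-averaging.
#' @param n_batches Number of contiguous batches used for batch-mean
#'   standard errors.
#' @param binary_propensity If `TRUE`, a U site with any modified neighbour
#'   gains at rate `k_plus` regardless of how many neighbours are modified
#'   (sensitivity switch; default `FALSE`, additive).
#' @param seed RNG seed.
#' @return An object of class `kmc_params`.
#' @examples
#' kmc_params(k_plus = 0.9, k_minus = 1)
#' @export
kmc_params <- function(n_sites = 61, k_plus = 1, k_minus = 1, k0 = NULL,
                       l_d = NULL, n_events = 1e6, burn_frac = 0.2,
                       n_batches = 20, binary_propensity = FALSE, seed = 1L) {
  bad <- function(msg) abort(paste0("invalid kmc_params: ", msg),
                             class = "chromspread_config_error")
  if (n_sites < 3 || n_sites %% 2 != 1)
    bad("`n_sites` must be an odd integer >= 3")
  if (k_minus < 0 || k_plus < 0) bad("rates must be >= 0")
  if (!is.null(k0) && (is.null(l_d) || l_d <= 0))
    bad("`l_d` must be > 0 (use Inf for the uniform-rate limit)")
  if (burn_frac < 0 || burn_frac >= 1) bad("`burn_frac` must lie in [0, 1)")
  p <- list(n_sites = as.integer(n_sites), k_plus = k_plus, k_minus = k_minus,
            k0 = k0, l_d = l_d, n_events = n_events, burn_frac = burn_frac,
            n_batches = as.integer(n_batches),
            binary_propensity = isTRUE(binary_propensity),
            seed = as.integer(seed))
  class(p) <- "kmc_params"
  p
}

#' @export
print.kmc_params <- function(x, ...) {
  cat("<kmc_params>\n")
  if (is.null(x$k0)) {
    cat(sprintf("  %d sites, k_plus = %g, k_minus = %g (K = %g)\n",
                x$n_sites, x$k_plus, x$k_minus, x$k_plus / x$k_minus))
  } else {
    cat(sprintf("  %d sites, k+(i) = %g * exp(-|i|/%g), k_minus = %g\n",
                x$n_sites, x$k0, x$l_d, x$k_minus))
  }
  cat(sprintf("  %g events (burn-in fraction %g), seed %d\n",
              x$n_events, x$burn_frac, x$seed))
  invisible(x)
}

# run a callback with the RNG seeded, restoring the caller's RNG state
with_run_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
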