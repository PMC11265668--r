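#' Run one reaction-diffusion simulation
#'
#' Executes `n_steps` timesteps of the particle-based model.  Each timestep
#' applies, in this fixed order: (1) Brownian displacement of every particle
#' followed by reflection into the disc, (2) RNA decay, (3) RNA production at
#' the nucleation-point position, (4) complex formation, (5) complex decay,
#' (6) a synchronous methylation sweep, (7) a demethylation sweep, and
#' (8) re-assertion of the pinned nucleation point.  After `burn_in` steps
#' the lattice is snapshotted every `sample_interval` steps; the methylation
#' profile, RNA shell densities and complex-proximity profile are averaged
#' over those snapshots.
#'
#' With a polymer configuration the nucleosomes sit at the frozen bead
#' coordinates and the spreading topology is the polymer's contact adjacency;
#' a straight-rod configuration reproduces the linear lattice exactly
#' (bit-identical given the same seed).
#'
#' @param params An [rd_params()] object.
#' @param polymer Optional `polymer_config` (frozen bead coordinates plus
#'   contact adjacency); its bead count must equal `params$n_nucleosomes`.
#' @param shell_dr Width in sigma of the concentric shells used for the RNA
#'   number-density profile (default 1).
#' @param keep_samples Keep the per-sample lattice snapshot matrix in the
#'   result (default `TRUE`; ensembles switch it off to save memory).
#' @param .reseed Seed the RNG from `params$seed` before running (default
#'   `TRUE`).  Ensemble drivers pass `FALSE` to draw all runs from one
#'   already-seeded stream.
#' @return An object of class `rd_run` with components `profile` (tibble:
#'   `site`, `p_m`, `n_samples`), `shells` (tibble: `r_lo`, `r_hi`,
#'   `mean_count`, `density`), `cprox` (tibble: `site`, `c_p`), `counts`
#'   (per-sample particle counts), `samples` (snapshot matrix), `particles`
#'   (final particle system), `conservation_ok`, `max_radius`, and a full
#'   parameter echo.
#' @examples
#' p <- rd_params(n_nucleosomes = 11, radius = 8, n_enzymes = 30,
#'                n_steps = 2000, burn_in = 500, sample_interval = 50)
#' run <- run_rd_simulation(p)
#' glance(run)
#' @export
run_rd_simulation <- function(params, polymer = NULL, shell_dr = 1,
                              keep_samples = TRUE, .reseed = TRUE) {
  stopifnot(inherits(params, "rd_params"))
  validate_rd_params(params, polymer = polymer)

  if (is.null(polymer)) {
    if (identical(params$geometry, "polymer"))
      abort("params declare polymer geometry but no polymer configuration was supplied",
            class = "chromspread_config_error")
    m <- (params$n_nucleosomes - 1L) %/% 2L
    site_x <- as.numeric(-m:m)
    site_y <- rep(0, params$n_nucleosomes)
    nbrs <- linear_neighbors(params$n_nucleosomes)
    np <- m + 1L
    site_index <- -m:m
  } else {
    if (nrow(polymer$beads) != params$n_nucleosomes)
      abort(sprintf(
        "polymer bead count (%d) must equal params$n_nucleosomes (%d)",
        nrow(polymer$beads), params$n_nucleosomes),
        class = "chromspread_config_error")
    site_x <- polymer$beads$x
    site_y <- polymer$beads$y
    nbrs <- polymer$neighbors
    if (is.null(nbrs))
      nbrs <- contact_neighbors(polymer)$neighbors
    np <- polymer$np_bead
    site_index <- seq_len(nrow(polymer$beads)) - np
  }

  run_engine <- function() {
    cpp_rd_engine(site_x, site_y, lapply(nbrs, function(v) as.integer(v - 1L)),
                  np - 1L, params$nucleation, params$radius,
                  params$n_enzymes, params$d_tilde, params$p_rp, params$p_rd,
                  params$p_cp, params$p_cd, params$p_w, params$p_m,
                  params$p_dm, params$d_prox, params$n_steps, params$burn_in,
                  params$sample_interval, shell_dr, params$particle_cap)
  }
  res <- if (.reseed) with_run_seed(params$seed, run_engine()) else run_engine()

  if (isTRUE(res$cap_hit))
    warn(sprintf("particle count exceeded particle_cap (%g) during the run",
                 params$particle_cap))

  ns <- res$n_samples
  profile <- tibble::tibble(site = site_index,
                            p_m = if (ns > 0) res$m_count / ns else
                              rep(NA_real_, length(site_index)),
                            n_samples = ns)
  n_shells <- length(res$shell_sum)
  r_lo <- (seq_len(n_shells) - 1) * shell_dr
  r_hi <- r_lo + shell_dr
  shells <- tibble::tibble(
    r_lo = r_lo, r_hi = r_hi,
    mean_count = if (ns > 0) res$shell_sum / ns else rep(NA_real_, n_shells),
    density = if (ns > 0) (res$shell_sum / ns) / (pi * (r_hi^2 - r_lo^2)) else
      rep(NA_real_, n_shells))
  cprox <- tibble::tibble(site = site_index,
                          c_p = if (ns > 0) res$cprox_sum / ns else
                            rep(NA_real_, length(site_index)))
  counts <- tibble::tibble(sample = seq_len(ns),
                           n_e = res$counts[seq_len(ns), 1],
                           n_r = res$counts[seq_len(ns), 2],
                           n_c = res$counts[seq_len(ns), 3])
  samples <- NULL
  if (keep_samples) {
    samples <- res$samples
    colnames(samples) <- as.character(site_index)
  }
  particles <- particle_system(res$final_x, res$final_y,
                               c("E", "R", "C")[res$final_species + 1L])

  structure(
    list(profile = profile, shells = shells, cprox = cprox, counts = counts,
         samples = samples, particles = particles,
         conservation_ok = res$conservation_ok, max_radius = res$max_radius,
         n_samples = ns, params = params,
         mode = if (is.null(polymer)) "linear" else polymer$walk_type,
         site_index = site_index, seed = params$seed,
         version = as.character(packageVersion("chromspread"))),
    class = "rd_run")
}

#' @export
print.rd_run <- function(x, ...) {
  cat(sprintf("<rd_run> %s lattice, %d sites, %d samples\n",
              x$mode, nrow(x$profile), x$n_samples))
  g <- glance(x)
  cat(sprintf("  S_m = %.3f, kurtosis = %.3f, mean complexes = %.1f\n",
              g$s_m, g$kurtosis, g$mean_n_c))
  cat(sprintf("  enzyme conservation: %s, max |p| = %.4f (r = %g)\n",
              x$conservation_ok, x$max_radius, x$params$radius))
  invisible(x)
}

#' Tidy a reaction-diffusion run into its methylation profile
#'
#' @param x An `rd_run` object.
#' @param ... Unused.
#' @return A tibble with columns `site`, `p_m`, `n_samples`.
#' @export
tidy.rd_run <- function(x, ...) x$profile

#' One-row summary of a reaction-diffusion run
#'
#' @param x An `rd_run` object.
#' @param ... Unused.
#' @return A tibble with the profile width `s_m` (literal mode), normalized
#'   kurtosis, sample count, mean particle counts and run diagnostics.
#' @export
glance.rd_run <- function(x, ...) {
  kur <- tryCatch(profile_kurtosis(x$profile), error = function(e) NA_real_)
  sm <- tryCatch(profile_sd(x$profile), error = function(e) NA_real_)
  tibble::tibble(
    s_m = sm, kurtosis = kur, n_samples = x$n_samples,
    mean_n_e = mean(x$counts$n_e), mean_n_r = mean(x$counts$n_r),
    mean_n_c = mean(x$counts$n_c),
    conservation_ok = x$conservation_ok, max_radius = x$max_radius)
}

#' Plot the methylation profile of a run
#'
#' @param object An `rd_run` object.
#' @param ... Unused.
#' @return A ggplot object: per-site modification probability against the
#'   genomic site index.
#' @export
autoplot.rd_run <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$site, .data$p_m)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "nucleosome position i",
                  y = "P(M)", title = "Methylation profile") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the RNA radial shell-density profile of a run
#'
#' @param run An `rd_run` object.
#' @return A ggplot object of shell density against shell radius.
#' @export
plot_shell_density <- function(run) {
  stopifnot(inherits(run, "rd_run"))
  df <- dplyr::mutate(run$shells, r_mid = (.data$r_lo + .data$r_hi) / 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_mid, .data$density)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "shell radius (sigma)",
                  y = expression(rho[i]),
                  title = "RNA number density by concentric shell") +
    ggplot2::theme_minimal()
}
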