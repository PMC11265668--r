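#' Space-dependent spreading rate
#'
#' The exponential-rate variant of the kinetic model:
#' \eqn{k^+(i) = k_0\, e^{-|i|/l_d}}, where `i` is the target site's distance
#' (in lattice units) from the nucleation point and `l_d` is the length scale
#' of complex spread that, in the reaction-diffusion model, emerges from the
#' microscopic reaction parameters.  `l_d = Inf` reduces to the uniform rate
#' `k0`.
#'
#' @param i Site index (distance from the NP; sign is ignored).
#' @param k0 Rate amplitude at the nucleation point.
#' @param l_d Decay length (> 0, `Inf` allowed).
#' @return The spreading rate at site `i`.
#' @examples
#' spatial_rate(0, 2, 5)           # 2
#' spatial_rate(5, 2, 5)           # 2 / e
#' spatial_rate(7, 2, Inf)         # 2
#' @export
spatial_rate <- function(i, k0, l_d) {
  if (any(l_d <= 0)) abort("`l_d` must be > 0",
                           class = "chromspread_config_error")
  if (is.infinite(l_d)) return(rep(k0, length(i)))
  k0 * exp(-abs(i) / l_d)
}

kmc_site_rates <- function(params) {
  m <- (params$n_sites - 1L) %/% 2L
  idx <- -m:m
  if (!is.null(params$k0)) spatial_rate(idx, params$k0, params$l_d)
  else rep(params$k_plus, params$n_sites)
}

#' Gillespie simulation of the reaction-only spreading model
#'
#' Simulates the contact-process comparator with the standard Gillespie
#' algorithm: site 0 starts modified and is held modified permanently; a U
#' site with `m` modified neighbours gains the mark at rate
#' `m * k_plus(site)`, a modified site other than the NP loses it at rate
#' `k_minus`.  Waiting times are exponential and the per-site stationary
#' `P(M)` is accumulated time-weighted (not event-weighted) after the
#' burn-in fraction of events, in contiguous batches that provide batch-mean
#' standard errors.
#'
#' @param params A [kmc_params()] object.
#' @param .reseed Seed the RNG from `params$seed` first (default `TRUE`).
#' @return An object of class `kmc_run` with `profile` (tibble: `site`,
#'   `p_m`, `se`), `t_total`, `absorbed` and the parameter echo.
#' @examples
#' run <- gillespie_run(kmc_params(n_sites = 5, k_plus = 0.9, k_minus = 1,
#'                                 n_events = 1e4))
#' tidy(run)
#' @export
gillespie_run <- function(params, .reseed = TRUE) {
  stopifnot(inherits(params, "kmc_params"))
  rates <- kmc_site_rates(params)
  run_engine <- function() {
    cpp_kmc_engine(params$n_sites, rates, params$k_minus, params$n_events,
                   params$burn_frac, params$n_batches,
                   params$binary_propensity)
  }
  res <- if (.reseed) with_run_seed(params$seed, run_engine()) else
    run_engine()

  m <- (params$n_sites - 1L) %/% 2L
  idx <- -m:m
  tb <- res$batch_t
  used <- tb > 0
  if (res$absorbed && sum(used) == 0) {
    # frozen trajectory (e.g. k_plus = 0): the stationary profile is the
    # absorbing state itself
    profile <- tibble::tibble(site = idx, p_m = as.numeric(res$final_state),
                              se = 0)
  } else {
    occ <- res$batch_occ[used, , drop = FALSE]
    tb <- tb[used]
    batch_p <- sweep(occ, 1, tb, "/")
    p_m <- colSums(occ) / sum(tb)
    se <- if (nrow(batch_p) > 1)
      apply(batch_p, 2, sd) / sqrt(nrow(batch_p)) else rep(NA_real_,
                                                           params$n_sites)
    profile <- tibble::tibble(site = idx, p_m = p_m, se = se)
  }
  structure(list(profile = profile, t_total = res$t_total,
                 absorbed = res$absorbed, params = params,
                 model = "kmc", seed = params$seed),
            class = "kmc_run")
}

#' @export
print.kmc_run <- function(x, ...) {
  cat(sprintf("<kmc_run> %d sites, %g events, simulated time %.1f\n",
              x$params$n_sites, x$params$n_events, x$t_total))
  cat(sprintf("  S_m = %.3f%s\n", profile_sd(x),
              if (x$absorbed) " (trajectory absorbed)" else ""))
  invisible(x)
}

#' @export
tidy.kmc_run <- function(x, ...) x$profile

#' @export
glance.kmc_run <- function(x, ...) {
  tibble::tibble(
    s_m = profile_sd(x),
    kurtosis = tryCatch(profile_kurtosis(x), error = function(e) NA_real_),
    t_total = x$t_total, absorbed = x$absorbed,
    K = if (is.null(x$params$k0)) x$params$k_plus / x$params$k_minus
        else x$params$k0 / x$params$k_minus)
}

#' @export
autoplot.kmc_run <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$site, .data$p_m)) +
    ggplot2::geom_line(colour = "#d95f0e") +
    ggplot2::labs(x = "lattice position j", y = "P(M)",
                  title = "Stationary profile (reaction-only model)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Exact stationary profile from the master equation
#'
#' Builds the full continuous-time Markov chain over the `2^(n_sites - 1)`
#' U/M configurations of the non-pinned sites (site 0 held modified), solves
#' the stationary distribution of its generator with a sparse linear solve,
#' and marginalizes the per-site modification probability.  This is the
#' independent validation oracle for [gillespie_run()]; it is exact but only
#' tractable for small lattices.
#'
#' @param n_sites Odd number of sites, at most 13 (8192 states).
#' @param k_plus Spreading rate (scalar), or use `k0`/`l_d`.
#' @param k_minus Removal rate.
#' @param k0,l_d Optional space-dependent rate parameters, as in
#'   [kmc_params()].
#' @param binary_propensity Match the sensitivity switch of the simulator.
#' @return A tibble `site`, `p_m` with the exact stationary probabilities.
#' @examples
#' master_equation_profile(3, k_plus = 0.9, k_minus = 1)  # P = K/(1+K) at +-1
#' @export
master_equation_profile <- function(n_sites, k_plus = 1, k_minus = 1,
                                    k0 = NULL, l_d = NULL,
                                    binary_propensity = FALSE) {
  if (n_sites %% 2 != 1 || n_sites < 3)
    abort("`n_sites` must be odd and >= 3",
          class = "chromspread_config_error")
  if (n_sites > 13)
    abort(sprintf(
      "n_sites = %d gives 2^%d states; the exact solver is capped at 13 sites",
      n_sites, n_sites - 1), class = "chromspread_config_error")
  m <- (n_sites - 1L) %/% 2L
  idx <- -m:m
  rates <- if (!is.null(k0)) spatial_rate(idx, k0, l_d) else
    rep(k_plus, n_sites)
  np <- m + 1L                      # 1-based pinned site
  free <- setdiff(seq_len(n_sites), np)
  nf <- length(free)
  n_states <- 2L^nf

  state_of <- function(s) {         # s in 0..n_states-1 -> full lattice
    lat <- integer(n_sites)
    lat[np] <- 1L
    lat[free] <- bitwAnd(bitwShiftR(s, seq_len(nf) - 1L), 1L)
    lat
  }

  max_tr <- n_states * nf
  ii <- integer(max_tr); jj <- integer(max_tr); xx <- numeric(max_tr)
  n_tr <- 0L
  diag_out <- numeric(n_states)
  for (s in 0:(n_states - 1L)) {
    lat <- state_of(s)
    for (f in seq_len(nf)) {
      site <- free[f]
      if (lat[site] == 0L) {
        mn <- 0L
        if (site > 1 && lat[site - 1] == 1L) mn <- mn + 1L
        if (site < n_sites && lat[site + 1] == 1L) mn <- mn + 1L
        if (binary_propensity && mn > 1L) mn <- 1L
        r <- mn * rates[site]
      } else {
        r <- k_minus
      }
      if (r > 0) {
        s2 <- bitwXor(s, bitwShiftL(1L, f - 1L))
        n_tr <- n_tr + 1L
        ii[n_tr] <- s + 1L; jj[n_tr] <- s2 + 1L; xx[n_tr] <- r
        diag_out[s + 1L] <- diag_out[s + 1L] + r
      }
    }
  }
  ii <- ii[seq_len(n_tr)]; jj <- jj[seq_len(n_tr)]; xx <- xx[seq_len(n_tr)]
  Q <- Matrix::sparseMatrix(i = c(ii, seq_len(n_states)),
                            j = c(jj, seq_len(n_states)),
                            x = c(xx, -diag_out),
                            dims = c(n_states, n_states))
  A <- Matrix::t(Q)
  A[1, ] <- 1                       # replace one balance row by normalization
  b <- c(1, rep(0, n_states - 1))
  pi_vec <- as.numeric(Matrix::solve(A, b))
  pi_vec[pi_vec < 0] <- 0
  pi_vec <- pi_vec / sum(pi_vec)

  p_m <- numeric(n_sites)
  for (s in 0:(n_states - 1L)) {
    lat <- state_of(s)
    p_m <- p_m + pi_vec[s + 1L] * lat
  }
  tibble::tibble(site = idx, p_m = p_m)
}
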