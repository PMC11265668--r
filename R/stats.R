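profile_frame <- function(profile) {
  if (inherits(profile, "rd_run") || inherits(profile, "kmc_run"))
    profile <- profile$profile
  if (!is.data.frame(profile) || !all(c("site", "p_m") %in% names(profile)))
    abort("`profile` must be a data frame with columns `site` and `p_m`",
          class = "chromspread_config_error")
  if (nrow(profile) == 0)
    abort("`profile` is empty", class = "chromspread_config_error")
  profile
}

#' Width of a methylation profile (S_m)
#'
#' Computes the second-moment width of the per-site modification profile,
#' \deqn{S_m = \Big(\sum_i i^2 P_i - \big(\sum_i i P_i\big)^2\Big)^{1/2},}
#' taken literally over the raw probabilities `P_i` (no normalization by
#' `sum(P_i)`) -- the statistic's defining form and the default here.  Because the raw profile
#' is not a probability distribution over sites, the radicand can be negative
#' for strongly asymmetric profiles with total mass above 1; in that case the
#' literal mode fails loudly.  `normalize = TRUE` first rescales the weights
#' to unit mass, giving an ordinary standard deviation; the two modes agree
#' whenever `sum(P_i) = 1`.
#'
#' @param profile A profile tibble (`site`, `p_m`) or an `rd_run` /
#'   `kmc_run` object.
#' @param normalize Use unit-mass weights instead of the literal formula.
#' @return The width `S_m` (a non-negative number, in lattice units).
#' @examples
#' profile_sd(tibble::tibble(site = -1:1, p_m = c(0.5, 0, 0.5)))  # 1
#' @export
profile_sd <- function(profile, normalize = FALSE) {
  pf <- profile_frame(profile)
  i <- pf$site
  p <- pf$p_m
  if (normalize) {
    tot <- sum(p)
    if (tot <= 0) abort("profile has zero total mass; cannot normalize",
                        class = "chromspread_config_error")
    p <- p / tot
  }
  s2 <- sum(i^2 * p) - sum(i * p)^2
  if (s2 < 0) {
    if (s2 > -1e-9) return(0)
    abort(sprintf(
      "negative radicand (%.4g) in literal-mode S_m: the raw profile has total mass %.3f; use normalize = TRUE",
      s2, sum(pf$p_m)), class = "chromspread_stat_error")
  }
  sqrt(s2)
}

#' Kurtosis of a methylation profile
#'
#' Pearson kurtosis \eqn{m_4 / m_2^2} of the site index under the normalized
#' weights \eqn{w_i = P_i / \sum_j P_j}.  Kurtosis requires normalization,
#' so unlike [profile_sd()] there is no literal mode.  A Gaussian-shaped
#' profile gives 3, a two-point profile 1, a broad uniform profile 9/5;
#' trends between profiles are the same under the excess convention
#' (Pearson minus 3).
#'
#' @param profile A profile tibble (`site`, `p_m`) or an `rd_run` /
#'   `kmc_run` object.
#' @return The Pearson kurtosis.
#' @examples
#' profile_kurtosis(tibble::tibble(site = c(-1, 1), p_m = c(0.5, 0.5)))  # 1
#' @export
profile_kurtosis <- function(profile) {
  pf <- profile_frame(profile)
  tot <- sum(pf$p_m)
  if (tot <= 0) abort("profile has zero total mass",
                      class = "chromspread_stat_error")
  w <- pf$p_m / tot
  mu <- sum(pf$site * w)
  m2 <- sum((pf$site - mu)^2 * w)
  if (m2 <= 0) abort("profile has zero variance; kurtosis undefined",
                     class = "chromspread_stat_error")
  m4 <- sum((pf$site - mu)^4 * w)
  m4 / m2^2
}

#' Summary moments of a profile
#'
#' Reports both width modes side by side: the literal second-moment width is
#' `NA` where its radicand is negative (strongly asymmetric raw profiles),
#' while the normalized width and kurtosis are always defined for profiles
#' with positive variance.
#'
#' @param profile A profile tibble or run object.
#' @return A tibble with `s_m` (literal), `s_m_normalized`, `kurtosis` and
#'   the mean position.
#' @export
profile_moments <- function(profile) {
  pf <- profile_frame(profile)
  tot <- sum(pf$p_m)
  mean_pos <- if (tot > 0) sum(pf$site * pf$p_m) / tot else NA_real_
  tibble::tibble(
    s_m = tryCatch(profile_sd(pf), error = function(e) NA_real_),
    s_m_normalized = tryCatch(profile_sd(pf, normalize = TRUE),
                              error = function(e) NA_real_),
    kurtosis = tryCatch(profile_kurtosis(pf), error = function(e) NA_real_),
    mean_position = mean_pos)
}

#' RNA number density in concentric shells
#'
#' Bins particle radial distances into shells `[r_i, r_i + dr)` and applies
#' \deqn{\rho_i = N_{R_i} / \big(\pi (r_{i+1}^2 - r_i^2)\big).}
#'
#' @param positions Data frame with columns `x`, `y` (or a single numeric
#'   vector of radial distances).
#' @param dr Shell width in sigma (> 0).
#' @param r_max Outer radius; particles beyond it fall in the last shell.
#' @return A `shell_density` tibble: `r_lo`, `r_hi`, `count`, `density`.
#' @examples
#' rna_shell_density(tibble::tibble(x = c(0.2, 3), y = c(0, 0)),
#'                   dr = 1, r_max = 5)
#' @export
rna_shell_density <- function(positions, dr = 1, r_max = NULL) {
  if (!is.numeric(dr) || dr <= 0)
    abort("`dr` must be > 0", class = "chromspread_config_error")
  r <- if (is.data.frame(positions)) sqrt(positions$x^2 + positions$y^2)
       else as.numeric(positions)
  if (is.null(r_max)) r_max <- if (length(r)) max(r, dr) else dr
  n_shells <- max(1L, as.integer(ceiling(r_max / dr)))
  b <- pmin(floor(r / dr), n_shells - 1)
  counts <- tabulate(b + 1L, nbins = n_shells)
  r_lo <- (seq_len(n_shells) - 1) * dr
  r_hi <- r_lo + dr
  out <- tibble::tibble(r_lo = r_lo, r_hi = r_hi, count = counts,
                        density = counts / (pi * (r_hi^2 - r_lo^2)))
  class(out) <- c("shell_density", class(out))
  out
}

#' Average complex proximity per nucleosome
#'
#' For each site, the mean over samples of the number of C particles within
#' `d_prox` of the site's spatial position -- the \eqn{\langle C^p \rangle}
#' profile.  [run_rd_simulation()] accumulates the same quantity online; this
#' standalone version operates on stored particle snapshots.
#'
#' @param samples Data frame of particle snapshots with columns `sample`
#'   (snapshot id), `x`, `y`, `species`.
#' @param site_positions Data frame with columns `site`, `x`, `y`.
#' @param d_prox Proximity radius in sigma.
#' @return A tibble `site`, `c_p`.
#' @export
complex_proximity_profile <- function(samples, site_positions, d_prox = 1) {
  n_samp <- length(unique(samples$sample))
  if (n_samp == 0)
    return(tibble::tibble(site = site_positions$site, c_p = 0))
  cc <- samples[samples$species == "C", , drop = FALSE]
  d2max <- d_prox^2
  c_p <- vapply(seq_len(nrow(site_positions)), function(s) {
    d2 <- (cc$x - site_positions$x[s])^2 + (cc$y - site_positions$y[s])^2
    sum(d2 <= d2max) / n_samp
  }, numeric(1))
  tibble::tibble(site = site_positions$site, c_p = c_p)
}

#' Diffusion-decay length scale of the RNA cloud
#'
#' The stationary RNA cloud around the source extends over
#' \eqn{l_r = \sqrt{\tilde D_r / P_{rd}}}, the length scale of diffusion
#' balanced against first-order decay.  (The estimator is quoted without the
#' root in some displays; dimensional consistency of a diffusion-decay
#' length forces the square root, which is what this function returns.)
#'
#' @param d_tilde_r Dimensionless diffusion constant of the RNA particles.
#' @param p_rd RNA decay probability per step.
#' @return The length `l_r` in sigma; `Inf` when `p_rd = 0`.
#' @examples
#' rna_length_scale(2e-4, 1e-3)  # ~0.447
#' @export
rna_length_scale <- function(d_tilde_r, p_rd) {
  if (p_rd < 0 || d_tilde_r < 0)
    abort("`d_tilde_r` and `p_rd` must be >= 0",
          class = "chromspread_config_error")
  if (p_rd == 0) return(Inf)
  sqrt(d_tilde_r / p_rd)
}

#' Least-squares quadratic trend
#'
#' Fits `y = a x^2 + b x + c` by ordinary least squares, as used for the
#' profile-width versus enzyme-concentration trend.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points).
#' @return An object of class `quad_trend` with elements `a`, `b`, `c` and
#'   the underlying `lm` fit; has [tidy()] and [glance()] methods.
#' @examples
#' fit <- fit_quadratic_trend(0:4, (0:4)^2)
#' fit$a
#' @export
fit_quadratic_trend <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("need >= 3 (x, y) points for a quadratic fit",
          class = "chromspread_config_error")
  if (length(unique(x)) < 3)
    abort("degenerate design: need >= 3 distinct x values",
          class = "chromspread_config_error")
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  structure(list(a = unname(cf[["I(x^2)"]]), b = unname(cf[["x"]]),
                 c = unname(cf[["(Intercept)"]]), fit = fit),
            class = "quad_trend")
}

#' @export
print.quad_trend <- function(x, ...) {
  cat(sprintf("<quad_trend> y = %.4g x^2 + %.4g x + %.4g\n", x$a, x$b, x$c))
  invisible(x)
}

#' @export
tidy.quad_trend <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("c", "b", "a"),
                 estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

#' @export
glance.quad_trend <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, sigma = sm$sigma,
                 df.residual = x$fit$df.residual)
}

#' Export a methylation profile as bedGraph
#'
#' Maps lattice site `i` to the half-open, 0-based genomic interval
#' `[(i + offset) * bin_bp, (i + offset + 1) * bin_bp)` so the profile can be
#' viewed in a genome browser next to a ChIP-seq track.  Uses rtracklayer
#' when available, otherwise writes the four-column text format directly.
#'
#' @param profile A profile tibble or run object.
#' @param path Output file path.
#' @param chrom Chromosome name for the track.
#' @param bin_bp Genomic width per lattice site (default 200 bp, about one
#'   nucleosome repeat).
#' @param offset Added to the site index so coordinates are non-negative
#'   (default shifts the most negative site to 0).
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, path, chrom = "chrSim", bin_bp = 200,
                            offset = NULL) {
  pf <- profile_frame(profile)
  if (is.null(offset)) offset <- -min(pf$site)
  start <- (pf$site + offset) * bin_bp
  if (any(start < 0))
    abort("negative genomic coordinates; increase `offset`",
          class = "chromspread_config_error")
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      requireNamespace("GenomicRanges", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start + 1, width = bin_bp),
      score = pf$p_m)
    rtracklayer::export.bedGraph(gr, path)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", chrom, as.integer(start),
                     as.integer(start + bin_bp), format(pf$p_m, digits = 10))
    writeLines(lines, path)
  }
  invisible(path)
}
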