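#' Brownian displacement of particles
#'
#' Applies one Langevin (overdamped Brownian) step to a set of particle
#' positions: each coordinate is displaced by
#' \eqn{\sqrt{2\tilde D}\, g} with `g` a standard Gaussian, independent
#' across particles, axes and steps.  No boundary handling is done here; see
#' [reflect_into_disc()].
#'
#' @param positions A data frame with numeric columns `x` and `y` (sigma
#'   units), one row per particle.
#' @param d_tilde Dimensionless per-step diffusion constant (>= 0).
#' @return A tibble with the displaced `x`, `y` (other columns preserved).
#' @examples
#' pts <- tibble::tibble(x = c(0, 1), y = c(0, -1))
#' langevin_step(pts, d_tilde = 2e-4)
#' @export
langevin_step <- function(positions, d_tilde) {
  if (!is.numeric(d_tilde) || length(d_tilde) != 1 || is.na(d_tilde) ||
      d_tilde < 0)
    abort("`d_tilde` must be a single non-negative number",
          class = "chromspread_config_error")
  n <- nrow(positions)
  out <- tibble::as_tibble(positions)
  if (n == 0 || d_tilde == 0) return(out)
  s <- sqrt(2 * d_tilde)
  out$x <- out$x + s * rnorm(n)
  out$y <- out$y + s * rnorm(n)
  out
}

#' Reflect positions back into the disc
#'
#' Radial mirroring for the reflecting boundary of the circular simulation
#' space: a point at radial distance `|p| > r` is mapped to `2r - |p|` at the
#' same angle, iterating (and folding at the origin) until the point lies
#' inside.  Interior points are returned unchanged, so the map is idempotent.
#' For the step sizes used here (about `0.02` sigma against radii of tens of
#' sigma) a single mirror always suffices; the iteration only guards
#' pathological inputs.
#'
#' @param positions A data frame with numeric columns `x`, `y`.
#' @param radius Disc radius (> 0).
#' @return A tibble of positions, all satisfying `x^2 + y^2 <= radius^2`.
#' @examples
#' reflect_into_disc(tibble::tibble(x = 5.5, y = 0), radius = 5)
#' @export
reflect_into_disc <- function(positions, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) ||
      radius <= 0)
    abort("`radius` must be a single positive number",
          class = "chromspread_config_error")
  out <- tibble::as_tibble(positions)
  if (nrow(out) == 0) return(out)
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    abort("non-finite particle position passed to reflect_into_disc()",
          class = "chromspread_config_error")
  rr <- sqrt(out$x^2 + out$y^2)
  outside <- which(rr > radius)
  if (length(outside)) {
    rn <- rr[outside]
    for (k in seq_len(64)) {
      over <- rn > radius
      if (!any(over)) break
      rn[over] <- abs(2 * radius - rn[over])
    }
    rn <- pmin(rn, radius)
    scale <- rn / rr[outside]
    out$x[outside] <- out$x[outside] * scale
    out$y[outside] <- out$y[outside] * scale
  }
  out
}
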