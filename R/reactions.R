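#' Construct a particle system
#'
#' A particle system is a tibble with one row per diffusing particle:
#' position (`x`, `y` in sigma units) and `species`, one of `"E"` (enzyme),
#' `"R"` (RNA) or `"C"` (enzyme-RNA complex).
#'
#' @param x,y Numeric coordinates.
#' @param species Character vector of species codes.
#' @return A tibble of class `particle_system`.
#' @examples
#' particle_system(x = c(0, 1), y = c(0, 0), species = c("E", "R"))
#' @export
particle_system <- function(x = numeric(), y = numeric(),
                            species = character()) {
  species <- as.character(species)
  if (!all(species %in% c("E", "R", "C")))
    abort("`species` must be one of \"E\", \"R\", \"C\"",
          class = "chromspread_config_error")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        species = species)
  class(out) <- c("particle_system", class(out))
  out
}

as_particle_system <- function(df) {
  particle_system(df$x, df$y, df$species)
}

#' RNA production at the nucleation point
#'
#' With probability `p_rp` this timestep, appends one R particle at the
#' origin position (the spatial position of the nucleation-point nucleosome);
#' otherwise the system is returned unchanged.  Production is a single
#' Bernoulli source, not a per-site draw.
#'
#' @param system A [particle_system()].
#' @param p_rp Production probability per step.
#' @param origin_position Length-2 numeric `(x, y)` of the RNA source.
#' @return The updated particle system.
#' @export
produce_rna <- function(system, p_rp, origin_position = c(0, 0)) {
  if (p_rp > 0 && runif(1) < p_rp) {
    system <- dplyr::bind_rows(
      system,
      tibble::tibble(x = origin_position[[1]], y = origin_position[[2]],
                     species = "R"))
    system <- as_particle_system(system)
  }
  system
}

#' RNA decay
#'
#' Each R particle is removed independently with probability `p_rd`,
#' anywhere in space.
#'
#' @param system A [particle_system()].
#' @param p_rd Decay probability per step.
#' @return The updated particle system.
#' @export
decay_rna <- function(system, p_rd) {
  is_r <- system$species == "R"
  if (!any(is_r) || p_rd == 0) return(system)
  gone <- is_r & runif(nrow(system)) < p_rd
  as_particle_system(system[!gone, , drop = FALSE])
}

#' Complex formation E + R -> C
#'
#' R particles are visited in index order; each takes its nearest free E
#' within `d_prox` (ties broken towards the lower index).  A matched pair
#' reacts with probability `p_cp`: the E becomes a C at its own position (the
#' enzyme is the persistent entity) and the R is removed.  Each particle
#' participates in at most one reaction per step; if the Bernoulli trial
#' fails, neither partner is consumed but the R does not retry another E
#' this step.
#'
#' @param system A [particle_system()].
#' @param p_cp Reaction probability per matched pair.
#' @param d_prox Contact radius in sigma.
#' @return The updated particle system.
#' @export
form_complexes <- function(system, p_cp, d_prox) {
  r_idx <- which(system$species == "R")
  e_free <- system$species == "E"
  if (length(r_idx) == 0 || !any(e_free) || p_cp == 0) return(system)
  d2max <- d_prox^2
  remove_r <- integer()
  for (i in r_idx) {
    cand <- which(e_free)
    if (length(cand) == 0) break
    d2 <- (system$x[cand] - system$x[i])^2 + (system$y[cand] - system$y[i])^2
    ok <- d2 <= d2max
    if (!any(ok)) next
    cand <- cand[ok]
    d2 <- d2[ok]
    best <- cand[order(d2, cand)[1]]
    if (runif(1) < p_cp) {
      system$species[best] <- "C"
      e_free[best] <- FALSE
      remove_r <- c(remove_r, i)
    }
  }
  if (length(remove_r))
    system <- system[-remove_r, , drop = FALSE]
  as_particle_system(system)
}

#' Complex decay C -> E
#'
#' Each C particle is converted back to an E at the same position,
#' independently with probability `p_cd`; the bound RNA component is
#' destroyed (it does not reappear as an R particle).
#'
#' @param system A [particle_system()].
#' @param p_cd Decay probability per step.
#' @return The updated particle system.
#' @export
decay_complexes <- function(system, p_cd) {
  is_c <- system$species == "C"
  if (!any(is_c) || p_cd == 0) return(system)
  flip <- is_c & runif(nrow(system)) < p_cd
  system$species[flip] <- "E"
  system
}
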