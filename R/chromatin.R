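#' Neighbour system of a nucleosome lattice
#'
#' The neighbour system lists, for every site, the sites whose modified
#' state boosts its methylation probability.  On the linear lattice these
#' are the backbone neighbours `i - 1`, `i + 1`; on a folded polymer they
#' are the contact neighbours of the frozen configuration (see
#' [contact_neighbors()]).  The relation is symmetric.
#'
#' @param n_sites Number of lattice sites.
#' @return A list of integer vectors (1-based site indices), one per site.
#' @examples
#' linear_neighbors(5)
#' @export
linear_neighbors <- function(n_sites) {
  lapply(seq_len(n_sites), function(i) {
    v <- c(i - 1L, i + 1L)
    v[v >= 1L & v <= n_sites]
  })
}

#' Effective methylation probability of one site
#'
#' Implements the proximity-gated rule
#' \eqn{P_m^{eff} = \delta_{C,1}\,\min(1,\; P_w + P_m\,\delta_{nbr,M})}:
#' zero unless a complex is within the proximity radius of the site; with a
#' complex proximal, the writer probability `p_w` plus the reader-writer
#' boost `p_m` if any neighbour is modified.  The neighbour term is binary
#' (the Kronecker delta is 1 if *either* neighbour is modified), never
#' additive, and multiple proximal complexes count the same as one.
#'
#' @param site Site index (1-based) -- must currently be unmodified.
#' @param lattice Integer/logical vector of site states (1/TRUE = modified).
#' @param neighbor_system Neighbour list as from [linear_neighbors()] or
#'   [contact_neighbors()].
#' @param c_proximal Logical: is at least one complex within `d_prox` of the
#'   site's spatial position?
#' @param p_w,p_m Writer and reader-writer probabilities.
#' @return The per-step methylation probability (a number in `[0, 1]`).
#' @export
effective_methylation_prob <- function(site, lattice, neighbor_system,
                                       c_proximal, p_w, p_m) {
  if (lattice[site] == 1)
    abort("effective_methylation_prob() called on an already-modified site",
          class = "chromspread_contract_error")
  if (!isTRUE(c_proximal)) return(0)
  nbr_m <- any(lattice[neighbor_system[[site]]] == 1)
  min(1, p_w + if (nbr_m) p_m else 0)
}

#' One synchronous methylation sweep
#'
#' For every unmodified site, determines whether any complex lies within
#' `d_prox` of the site's spatial position and draws a Bernoulli trial at
#' [effective_methylation_prob()].  All neighbour states are read from the
#' pre-sweep lattice (synchronous update), so a site modified during the
#' sweep cannot boost its neighbour in the same sweep.
#'
#' @param lattice Integer vector of site states (1 = modified).
#' @param system A [particle_system()] (only C particles are consulted).
#' @param neighbor_system Neighbour list.
#' @param site_positions Data frame with columns `x`, `y`: the spatial
#'   position of each site (linear mode places site i at `(i, 0)`).
#' @param d_prox Proximity radius in sigma.
#' @param p_w,p_m Writer and reader-writer probabilities.
#' @return The updated lattice vector.
#' @export
methylation_sweep <- function(lattice, system, neighbor_system,
                              site_positions, d_prox, p_w, p_m) {
  cx <- system$x[system$species == "C"]
  cy <- system$y[system$species == "C"]
  if (length(cx) == 0) return(lattice)
  d2max <- d_prox^2
  new_lattice <- lattice
  for (s in seq_along(lattice)) {
    if (lattice[s] == 1) next
    d2 <- (cx - site_positions$x[s])^2 + (cy - site_positions$y[s])^2
    if (!any(d2 <= d2max)) next
    peff <- effective_methylation_prob(s, lattice, neighbor_system,
                                       c_proximal = TRUE, p_w = p_w,
                                       p_m = p_m)
    if (peff > 0 && runif(1) < peff) new_lattice[s] <- 1L
  }
  new_lattice
}

#' One demethylation sweep
#'
#' Each modified site flips back to the unmodified state independently with
#' probability `p_dm`.  While nucleation is enabled the nucleation point is
#' excluded from the draw (it is pinned in the modified state).
#'
#' @param lattice Integer vector of site states.
#' @param p_dm Demethylation probability per step.
#' @param nucleation_enabled Logical; if `TRUE`, `np_site` is exempt.
#' @param np_site 1-based index of the nucleation point.
#' @return The updated lattice vector.
#' @export
demethylation_sweep <- function(lattice, p_dm, nucleation_enabled = TRUE,
                                np_site = (length(lattice) + 1L) %/% 2L) {
  if (p_dm == 0) return(lattice)
  m_sites <- which(lattice == 1)
  if (nucleation_enabled) m_sites <- setdiff(m_sites, np_site)
  if (length(m_sites) == 0) return(lattice)
  flip <- m_sites[runif(length(m_sites)) < p_dm]
  lattice[flip] <- 0L
  lattice
}
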