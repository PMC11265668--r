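new_polymer_config <- function(beads, walk_type, contact_cutoff = NULL,
                               neighbors = NULL) {
  np <- (nrow(beads) + 1L) %/% 2L
  structure(list(beads = tibble::as_tibble(beads), walk_type = walk_type,
                 contact_cutoff = contact_cutoff, neighbors = neighbors,
                 np_bead = np),
            class = "polymer_config")
}

#' @export
print.polymer_config <- function(x, ...) {
  cat(sprintf("<polymer_config> %s, %d beads, NP bead %d%s\n",
              x$walk_type, nrow(x$beads), x$np_bead,
              if (is.null(x$neighbors)) "" else
                sprintf(", contact cutoff %g sigma", x$contact_cutoff)))
  invisible(x)
}

#' Generate a 2D lattice random-walk polymer
#'
#' A square-lattice random walk of `n_beads` beads with unit bond length;
#' each step is uniform over the four lattice directions and revisits are
#' allowed (the compact-chromatin limit).  The configuration is translated so
#' the nucleation bead (the middle bead, `(n_beads + 1) %/% 2`) sits at the
#' origin.
#'
#' @param n_beads Number of beads (>= 2); one bead per nucleosome.
#' @return A `polymer_config` with the bead coordinates (columns `bead`,
#'   `x`, `y`); contacts are added by [contact_neighbors()].
#' @examples
#' set.seed(1); generate_rw_2d(10)
#' @export
generate_rw_2d <- function(n_beads) {
  if (n_beads < 2) abort("`n_beads` must be >= 2",
                         class = "chromspread_config_error")
  dirs <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)
  steps <- dirs[sample.int(4, n_beads - 1, replace = TRUE), , drop = FALSE]
  x <- c(0, cumsum(steps[, 1]))
  y <- c(0, cumsum(steps[, 2]))
  np <- (n_beads + 1L) %/% 2L
  beads <- tibble::tibble(bead = seq_len(n_beads),
                          x = x - x[np], y = y - y[np])
  new_polymer_config(beads, "RW")
}

# one pivot-chain sampler; returns a list of n_configs coordinate matrices.
# burn_accepts accepted pivots are discarded, then one configuration is
# emitted every `decorrelate` attempts (rejections advance the chain clock).
saw_pivot_chain <- function(n_beads, n_configs, burn_accepts = 10 * n_beads,
                            decorrelate = 3 * n_beads,
                            max_attempts = 2000 * (burn_accepts +
                                                     n_configs * decorrelate)) {
  # 7 non-identity symmetries of the square lattice as 2x2 matrices
  syms <- list(matrix(c(0, -1, 1, 0), 2),   # rot 90
               matrix(c(-1, 0, 0, -1), 2),  # rot 180
               matrix(c(0, 1, -1, 0), 2),   # rot 270
               matrix(c(-1, 0, 0, 1), 2),   # reflect x
               matrix(c(1, 0, 0, -1), 2),   # reflect y
               matrix(c(0, 1, 1, 0), 2),    # reflect diagonal
               matrix(c(0, -1, -1, 0), 2))  # reflect anti-diagonal
  key_base <- 4L * n_beads + 1L
  coords <- cbind(0:(n_beads - 1), rep(0L, n_beads))  # rod start
  accepted <- 0L
  attempts <- 0L
  post_burn_attempts <- 0L
  next_emit <- decorrelate
  out <- vector("list", n_configs)
  got <- 0L
  while (got < n_configs) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      abort("pivot sampler exceeded its attempt cap without accepting enough moves",
            class = "chromspread_polymer_error")
    k <- sample.int(n_beads - 2L, 1L) + 1L   # pivot bead in 2..n-1
    s <- syms[[sample.int(7L, 1L)]]
    piv <- coords[k, ]
    tail_idx <- (k + 1L):n_beads
    d <- sweep(coords[tail_idx, , drop = FALSE], 2, piv)
    newtail <- sweep(d %*% s, 2, piv, "+")
    prop <- coords
    prop[tail_idx, ] <- newtail
    keys <- (prop[, 1] + 2L * n_beads) * key_base + (prop[, 2] + 2L * n_beads)
    accept <- !anyDuplicated(keys)
    if (accept) {
      coords <- prop
      accepted <- accepted + 1L
    }
    # a rejected proposal repeats the current state: it advances the chain
    # clock, otherwise compact (low-acceptance) configurations would be
    # under-sampled.  Burn-in is counted in accepted pivots so the rod start
    # is fully decorrelated before emission begins.
    if (accepted >= burn_accepts) {
      post_burn_attempts <- post_burn_attempts + 1L
      if (post_burn_attempts >= next_emit) {
        got <- got + 1L
        out[[got]] <- coords
        next_emit <- next_emit + decorrelate
      }
    }
  }
  out
}

#' Generate a 2D self-avoiding-walk polymer
#'
#' Samples a square-lattice self-avoiding walk (the swollen-chromatin limit)
#' with the pivot algorithm: starting from a straight rod, random lattice
#' symmetries are applied about random pivot beads and proposals that
#' self-intersect are rejected; at least `10 * n_beads` accepted pivots are
#' discarded as burn-in before the configuration is returned.  The walk is
#' translated so the nucleation bead is at the origin.
#'
#' @param n_beads Number of beads (>= 2).
#' @param burn_accepts Accepted pivots discarded before emitting (default
#'   `10 * n_beads`).
#' @return A `polymer_config`; all bead coordinates are distinct.
#' @examples
#' set.seed(1); generate_saw_2d(20)
#' @export
generate_saw_2d <- function(n_beads, burn_accepts = 10 * n_beads) {
  cfgs <- saw_ensemble(n_beads, 1, burn_accepts = burn_accepts)
  cfgs[[1]]
}

#' Sample an ensemble of self-avoiding walks
#'
#' Runs one pivot chain and emits the current configuration every
#' `decorrelate` attempted pivots after burn-in (rejected proposals repeat
#' the state, as Metropolis sampling requires); successive emissions are
#' effectively independent because the pivot algorithm decorrelates global
#' observables in O(n) moves.
#'
#' @param n_beads Number of beads.
#' @param n_configs Number of configurations to return.
#' @param burn_accepts,decorrelate Pivot-chain tuning (defaults
#'   `10 * n_beads` accepted pivots and `3 * n_beads` attempts).
#' @return A list of `polymer_config` objects.
#' @export
saw_ensemble <- function(n_beads, n_configs, burn_accepts = 10 * n_beads,
                         decorrelate = 3 * n_beads) {
  if (n_beads < 2) abort("`n_beads` must be >= 2",
                         class = "chromspread_config_error")
  if (n_beads == 2) {
    # trivial chain: the rod is the only SAW up to symmetry; sample direction
    return(lapply(seq_len(n_configs), function(i) {
      th <- sample.int(4L, 1L)
      d <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[[th]]
      beads <- tibble::tibble(bead = 1:2, x = c(0, d[1]), y = c(0, d[2]))
      new_polymer_config(beads, "SAW")
    }))
  }
  mats <- saw_pivot_chain(n_beads, n_configs, burn_accepts, decorrelate)
  np <- (n_beads + 1L) %/% 2L
  lapply(mats, function(m) {
    beads <- tibble::tibble(bead = seq_len(n_beads),
                            x = m[, 1] - m[np, 1], y = m[, 2] - m[np, 2])
    new_polymer_config(beads, "SAW")
  })
}

#' Contact neighbourhood of a frozen polymer
#'
#' Beads `i`, `j` are neighbours iff they are backbone neighbours
#' (`|i - j| = 1`) or their Euclidean distance is at most `contact_cutoff`.
#' The default cutoff of 1.5 sigma captures diagonal and coincident
#' contacts while excluding the next-nearest lattice shell (distance 2).
#' The adjacency is symmetric and always contains the backbone.
#'
#' @param config A `polymer_config`.
#' @param contact_cutoff Contact distance in sigma (>= 1).
#' @return The `polymer_config` with its `neighbors` field set (a list of
#'   integer vectors, one per bead).
#' @examples
#' rod <- generate_rw_2d(4)  # any config; contacts recomputed here
#' contact_neighbors(rod, 1.5)$neighbors
#' @export
contact_neighbors <- function(config, contact_cutoff = 1.5) {
  stopifnot(inherits(config, "polymer_config"))
  if (contact_cutoff < 1)
    abort("`contact_cutoff` must be >= 1 (backbone bonds have unit length)",
          class = "chromspread_config_error")
  n <- nrow(config$beads)
  x <- config$beads$x; y <- config$beads$y
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  cut2 <- contact_cutoff^2
  nbrs <- lapply(seq_len(n), function(i) {
    v <- which(d2[i, ] <= cut2 | abs(seq_len(n) - i) == 1L)
    sort(setdiff(v, i))
  })
  config$neighbors <- nbrs
  config$contact_cutoff <- contact_cutoff
  config
}

#' Read / write a polymer configuration file
#'
#' Plain-text format: one `index x y` row per bead (whitespace-separated,
#' `#` comments allowed).  The reader validates the polymer invariants:
#' consecutive beads at unit distance, and distinct coordinates when
#' `walk_type = "SAW"`.
#'
#' @param path File path.
#' @param walk_type `"SAW"` or `"RW"`; controls which invariants are
#'   enforced on read.
#' @return `read_polymer()`: a `polymer_config`. `write_polymer()`: `path`,
#'   invisibly.
#' @export
read_polymer <- function(path, walk_type = "SAW") {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    abort(sprintf("polymer file '%s' has fewer than 2 beads", path),
          class = "chromspread_parse_error")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad))
    abort(sprintf("polymer file '%s': line %d does not have 3 fields",
                  path, bad[1]), class = "chromspread_parse_error")
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (any(!is.finite(m)))
    abort(sprintf("polymer file '%s' contains non-numeric fields", path),
          class = "chromspread_parse_error")
  m <- m[order(m[, 1]), , drop = FALSE]
  beads <- tibble::tibble(bead = as.integer(m[, 1]), x = m[, 2], y = m[, 3])
  bond <- sqrt(diff(beads$x)^2 + diff(beads$y)^2)
  if (any(abs(bond - 1) > 1e-6))
    abort(sprintf(
      "polymer invariant violated: bond %d has length %.4f (expected 1)",
      which(abs(bond - 1) > 1e-6)[1], bond[abs(bond - 1) > 1e-6][1]),
      class = "chromspread_config_error")
  if (walk_type == "SAW" &&
      anyDuplicated(paste(beads$x, beads$y)) > 0)
    abort("polymer invariant violated: SAW has coincident beads",
          class = "chromspread_config_error")
  cfg <- new_polymer_config(beads, walk_type)
  cfg$beads$x <- cfg$beads$x - beads$x[cfg$np_bead]
  cfg$beads$y <- cfg$beads$y - beads$y[cfg$np_bead]
  cfg
}

#' @rdname read_polymer
#' @param config A `polymer_config` to write.
#' @export
write_polymer <- function(config, path) {
  stopifnot(inherits(config, "polymer_config"))
  writeLines(sprintf("%d %.10g %.10g", config$beads$bead, config$beads$x,
                     config$beads$y), path)
  invisible(path)
}

#' Squared end-to-end distance of a polymer
#'
#' @param config A `polymer_config`.
#' @return The squared Euclidean distance between the first and last bead.
#' @export
end_to_end_sq <- function(config) {
  b <- config$beads
  n <- nrow(b)
  (b$x[n] - b$x[1])^2 + (b$y[n] - b$y[1])^2
}

#' Spreading on an ensemble of frozen polymer configurations
#'
#' For each of `n_configs` independently sampled frozen configurations
#' (coordinates held fixed for the whole run), runs the full
#' reaction-diffusion simulation with the beads as nucleosome positions and
#' the contact adjacency as the spreading topology, then averages the
#' per-bead methylation profiles over the ensemble.  Profiles are indexed by
#' genomic position relative to the nucleation bead.
#'
#' @param params An [rd_params()]; `n_nucleosomes` must equal `n_beads`.
#' @param n_configs Number of frozen configurations.
#' @param walk_type `"SAW"` or `"RW"`.
#' @param contact_cutoff Contact distance passed to [contact_neighbors()].
#' @param configs Optional pre-built list of `polymer_config`s (overrides
#'   `n_configs`/`walk_type`); user-supplied configurations that do not fit
#'   the disc are an error.
#' @param max_resample Generated configurations whose maximal bead radius
#'   exceeds `radius - 2` are redrawn, at most this many times in total
#'   (the ensemble is conditioned on fitting the disc; the exceedance is a
#'   far tail for the default radius).
#' @return An object of class `polymer_ensemble`: per-config profiles and
#'   widths, the ensemble-average `profile`, and the parameter echo.
#' @export
run_polymer_ensemble <- function(params, n_configs, walk_type = c("SAW", "RW"),
                                 contact_cutoff = 1.5, configs = NULL,
                                 max_resample = 100) {
  walk_type <- match.arg(walk_type)
  stopifnot(inherits(params, "rd_params"))
  n_beads <- params$n_nucleosomes
  user_supplied <- !is.null(configs)

  with_run_seed(params$seed, {
    if (is.null(configs)) {
      draw <- function(k) {
        if (walk_type == "SAW") saw_ensemble(n_beads, k)
        else lapply(seq_len(k), function(i) generate_rw_2d(n_beads))
      }
      configs <- draw(n_configs)
      fits <- function(cf)
        max(sqrt(cf$beads$x^2 + cf$beads$y^2)) <= params$radius - 2
      tries <- 0
      for (i in seq_along(configs)) {
        while (!fits(configs[[i]])) {
          tries <- tries + 1
          if (tries > max_resample)
            abort("too many polymer configurations exceed the disc; increase `radius`",
                  class = "chromspread_polymer_error")
          configs[[i]] <- draw(1)[[1]]
        }
      }
    }
    configs <- lapply(configs, contact_neighbors,
                      contact_cutoff = contact_cutoff)
    runs <- lapply(configs, function(cf) {
      if (user_supplied) validate_rd_params(params, polymer = cf)
      run_rd_simulation(params, polymer = cf, keep_samples = FALSE,
                        .reseed = FALSE)
    })
    profiles <- purrr::imap_dfr(runs, function(r, i)
      dplyr::mutate(r$profile, config = i))
    ensemble <- profiles |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(p_m = mean(.data$p_m), .groups = "drop")
    structure(list(profile = ensemble, config_profiles = profiles,
                   configs = configs, walk_type = walk_type,
                   n_configs = length(configs), params = params,
                   contact_cutoff = contact_cutoff, seed = params$seed),
              class = "polymer_ensemble")
  })
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  cat(sprintf("<polymer_ensemble> %s, %d configs of %d beads\n",
              x$walk_type, x$n_configs, x$params$n_nucleosomes))
  cat(sprintf("  ensemble S_m = %.3f, peak at site %d\n",
              profile_sd(x$profile, normalize = TRUE),
              x$profile$site[which.max(x$profile$p_m)]))
  invisible(x)
}

#' @export
tidy.polymer_ensemble <- function(x, ...) x$profile

#' @export
glance.polymer_ensemble <- function(x, ...) {
  tibble::tibble(
    walk_type = x$walk_type, n_configs = x$n_configs,
    s_m = profile_sd(x$profile),
    s_m_normalized = profile_sd(x$profile, normalize = TRUE),
    peak_site = x$profile$site[which.max(x$profile$p_m)])
}

#' @export
autoplot.polymer_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$config_profiles,
                  ggplot2::aes(.data$site, .data$p_m,
                               group = .data$config)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::geom_line(data = object$profile,
                       ggplot2::aes(.data$site, .data$p_m),
                       inherit.aes = FALSE, colour = "#e31a1c",
                       linewidth = 1) +
    ggplot2::labs(x = "genomic position (beads from NP)", y = "P(M)",
                  title = sprintf("Ensemble-averaged profile (%s, %d configs)",
                                  object$walk_type, object$n_configs)) +
    ggplot2::theme_minimal()
}
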