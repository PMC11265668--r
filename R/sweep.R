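#' Parameter sweep over a grid of reaction parameters
#'
#' Runs the reaction-diffusion simulation over the Cartesian grid of two
#' parameters (any fields of [rd_params()]), optionally replicated over
#' several seeds, and collects the phase-diagram table of profile widths
#' with the full profiles nested alongside.
#'
#' @param params Base [rd_params()].
#' @param param1,param2 Names of the swept fields (e.g. `"p_rd"`, `"p_cd"`).
#' @param values1,values2 Numeric vectors of grid values.
#' @param seeds Integer vector of seeds; each grid cell is run once per seed.
#' @return A tibble of class `rd_sweep`: one row per (value1, value2, seed)
#'   with columns `s_m`, `kurtosis` and a list-column `profile`.
#' @examples
#' \donttest{
#' p <- rd_params(n_nucleosomes = 11, radius = 8, n_enzymes = 30,
#'                n_steps = 4000, burn_in = 1000, sample_interval = 100)
#' sw <- param_sweep(p, "p_rd", c(1e-3, 1e-2), "p_cd", c(1e-4, 1e-2))
#' }
#' @export
param_sweep <- function(params, param1, values1, param2, values2,
                        seeds = params$seed) {
  stopifnot(inherits(params, "rd_params"))
  for (nm in c(param1, param2))
    if (!nm %in% names(params))
      abort(sprintf("unknown parameter `%s` in sweep", nm),
            class = "chromspread_config_error")
  grid <- tidyr::expand_grid(v1 = values1, v2 = values2, seed = seeds)
  rows <- purrr::pmap(grid, function(v1, v2, seed) {
    p <- params
    p[[param1]] <- v1
    p[[param2]] <- v2
    p$seed <- as.integer(seed)
    validate_rd_params(p)
    run <- run_rd_simulation(p, keep_samples = FALSE)
    g <- glance(run)
    tibble::tibble(!!param1 := v1, !!param2 := v2, seed = seed,
                   s_m = g$s_m, kurtosis = g$kurtosis,
                   profile = list(run$profile))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rd_sweep", class(out))
  attr(out, "swept") <- c(param1, param2)
  out
}

#' @importFrom rlang `:=`
NULL

#' Phase-diagram plot of a parameter sweep
#'
#' @param object An `rd_sweep` tibble from [param_sweep()].
#' @param ... Unused.
#' @return A ggplot tile plot of mean `S_m` over the swept grid.
#' @export
autoplot.rd_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  df <- object |>
    dplyr::group_by(dplyr::across(dplyr::all_of(swept))) |>
    dplyr::summarise(s_m = mean(.data$s_m), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data[[swept[1]]]),
                                   factor(.data[[swept[2]]]),
                                   fill = .data$s_m)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(S[m])) +
    ggplot2::labs(x = swept[1], y = swept[2],
                  title = "Profile width across the parameter grid") +
    ggplot2::theme_minimal()
}
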