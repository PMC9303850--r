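#' Configuration for fitting the Collective Investment game
#'
#' Defines the parameter grids searched by [fit_investment_game()] and
#' [fit_transdifferentiation()], and the options shared by the fitting and
#' bootstrap machinery. Defaults: 20 values per game parameter, spanning
#' `b` in `[2, 15]`, `c` in `[1, 2)`, `e` in `[0, 1)` and `t` in `(0, 1]`;
#' the enforcement parameter `D` is searched on `[0, 0.25]` in steps of 0.01.
#'
#' @param b_grid,c_grid,e_grid,t_grid Numeric grids for the benefit, cost,
#'   error SD and error-exponent parameters (sorted internally).
#' @param D_grid Grid for the transdifferentiation pressure.
#' @param n_boot Bootstrap iterations for [bootstrap_ci()].
#' @param delta_p Parameter-count difference used by [model_compare_F()]
#'   (2: the perfect-information model drops both `e` and `t`).
#' @param map Empirical-scale map for predictions, `"linear"` or `"exact"`;
#'   see [model_to_empirical()].
#' @param tails Handling of perception-error mass outside `[0, 1]`; see
#'   [expected_investment()].
#' @param n_grid Trapezoid quadrature nodes for the error integral.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(b_grid = seq(2, 15, length.out = 20),
                       c_grid = seq(1, 1.95, by = 0.05),
                       e_grid = seq(0, 0.95, by = 0.05),
                       t_grid = seq(0.05, 1, by = 0.05),
                       D_grid = seq(0, 0.25, by = 0.01),
                       n_boot = 100,
                       delta_p = 2,
                       map = c("linear", "exact"),
                       tails = c("truncate", "reflect"),
                       n_grid = quad_grid_n) {
  map <- match.arg(map)
  tails <- match.arg(tails)
  for (g in list(b_grid, c_grid, e_grid, t_grid, D_grid)) {
    if (!length(g) || any(!is.finite(g))) {
      abort("all parameter grids must be non-empty and finite.",
            class = "cigame_config_error")
    }
  }
  if (any(b_grid <= 0) || any(c_grid <= 0) || any(e_grid < 0) ||
      any(t_grid < 0) || any(D_grid < 0 | D_grid > 1)) {
    abort("grid values violate parameter domains.",
          class = "cigame_config_error")
  }
  if (n_boot < 1) abort("`n_boot` must be >= 1.", class = "cigame_config_error")
  structure(list(
    b_grid = sort(unique(b_grid)), c_grid = sort(unique(c_grid)),
    e_grid = sort(unique(e_grid)), t_grid = sort(unique(t_grid)),
    D_grid = sort(unique(D_grid)), n_boot = n_boot, delta_p = delta_p,
    map = map, tails = tails, n_grid = n_grid
  ), class = "fit_config")
}

#' @exportS3Method base::print
print.fit_config <- function(x, ...) {
  cat(sprintf(
    paste0("fit_config: b [%g, %g] x%d; c [%g, %g] x%d; e [%g, %g] x%d; ",
           "t [%g, %g] x%d; D [%g, %g] x%d\n  map = %s, tails = %s, ",
           "n_boot = %d\n"),
    min(x$b_grid), max(x$b_grid), length(x$b_grid),
    min(x$c_grid), max(x$c_grid), length(x$c_grid),
    min(x$e_grid), max(x$e_grid), length(x$e_grid),
    min(x$t_grid), max(x$t_grid), length(x$t_grid),
    min(x$D_grid), max(x$D_grid), length(x$D_grid),
    x$map, x$tails, x$n_boot))
  invisible(x)
}
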