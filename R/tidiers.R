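# broom-style tidiers for fitted objects

#' Tidy a Collective Investment game fit
#'
#' @param x A `cig_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`),
#'   including the derived optimum `theta`.
#' @export
tidy.cig_fit <- function(x, ...) {
  p <- x$params
  keep <- !vapply(p, is.na, logical(1))
  tibble(term = c(names(p)[keep], "theta"),
         estimate = c(unlist(p[keep]), x$theta))
}

#' Glance at a Collective Investment game fit
#'
#' @param x A `cig_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the RSS, variance explained, the
#'   prediction--observation Pearson correlation, the number of compositions
#'   and the empirical-scale map used.
#' @export
glance.cig_fit <- function(x, ...) {
  gof <- goodness_of_fit(x)
  tibble(rss = x$rss, r_squared = gof$r_squared,
         pearson_r = gof$pearson_r, n = x$n, map = x$map,
         n_ties = nrow(x$ties))
}

#' Tidy bootstrap confidence intervals
#'
#' @param x A `cig_boot` from [bootstrap_ci()].
#' @param ... Unused.
#' @return The per-parameter interval tibble (`parameter`, `estimate`,
#'   `lower`, `upper`).
#' @export
tidy.cig_boot <- function(x, ...) x$ci
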