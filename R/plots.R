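# ggplot2 figure helpers

#' Investment as a function of relatedness
#'
#' Plots the model's investment curve over relatedness, optionally with
#' perception error and/or the enforcement term, on the proportion-of-theta
#' scale.
#'
#' @param params A [game_params()] object.
#' @param err Optional [error_model()].
#' @param with_transdiff Show realised investment in equal-frequency groups
#'   of size `1/r` under enforcement (uses `params$D`)?
#' @param n Number of relatedness values to evaluate.
#' @return A ggplot object.
#' @export
plot_investment_curve <- function(params, err = NULL, with_transdiff = FALSE,
                                  n = 201) {
  rs <- seq(0.005, 1, length.out = n)
  th <- theta(params)
  x <- if (with_transdiff) {
    vapply(rs, function(r) {
      n_strains <- max(2, round(1 / r))
      comp <- tibble(strain_id = as.character(seq_len(n_strains)),
                     frequency = rep(1 / n_strains, n_strains))
      predict_collective(comp, params, err, with_transdiff = TRUE)
    }, numeric(1))
  } else {
    expected_investment(rs, params, err)
  }
  ggplot2::ggplot(tibble(relatedness = rs, y = x / th),
                  ggplot2::aes(x = .data$relatedness, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relatedness to group",
                  y = "investment (proportion of optimum)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cig_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "predicted relative spore production",
      y = "observed relative spore production",
      title = sprintf("Collective Investment game fit (RSS = %.3g)",
                      object$rss)) +
    ggplot2::theme_minimal()
}

#' Ranked pspA-index plot of classified cells
#'
#' Cells are ranked by their pspA index within each condition; the shaded
#' bands mark the prestalk (low index) and prespore (high index) regions, and
#' the interior band carries the mixed transdifferentiation signature.
#'
#' @param cells Output of [classify_cells()].
#' @param prestalk_max,prespore_min Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_pspa_index <- function(cells, prestalk_max = 0.3, prespore_min = 0.7) {
  kept <- cells[cells$fate != "censored", ] |>
    dplyr::group_by(.data$condition) |>
    dplyr::arrange(.data$pspA_index, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$rank, y = .data$pspA_index,
                                     colour = .data$fate)) +
    ggplot2::geom_hline(yintercept = c(prestalk_max, prespore_min),
                        linetype = 3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~condition, scales = "free_x") +
    ggplot2::labs(x = "cell rank", y = "pspA index", colour = "fate") +
    ggplot2::theme_minimal()
}

#' Collapse proportion against relatedness
#'
#' Scatter of collapse records with the cubic-relatedness trend from
#' [collapse_trend_cubic()] overlaid.
#'
#' @param records Collapse records (columns `relatedness`,
#'   `prop_collapsed`).
#' @return A ggplot object.
#' @export
plot_collapse <- function(records) {
  fit <- collapse_trend_cubic(records)
  grid <- tibble(relatedness = seq(min(records$relatedness),
                                   max(records$relatedness),
                                   length.out = 101))
  grid$prop_collapsed <- stats::predict(fit, newdata = grid)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$relatedness,
                                        y = .data$prop_collapsed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "relatedness (1/N)",
                  y = "proportion of fruiting bodies collapsed") +
    ggplot2::theme_minimal()
}
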