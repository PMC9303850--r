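# Spore-count scale: converting measured spore totals to inferred stalk
# investment, and model predictions onto the empirical scale.

#' Expected clonal spore production of a chimeric group
#'
#' The spore total a chimera would produce if every strain behaved as it does
#' clonally: the frequency-weighted mean of the constituent strains' clonal
#' totals, `E_G = sum(r_i * T_i)`.
#'
#' @param frequency Strain frequencies (summing to 1).
#' @param clonal_spores Per-strain clonal spore totals `T_i` (>= 0), aligned
#'   with `frequency`.
#' @param strain_id Optional strain ids (used for error messages and the
#'   uniqueness check).
#' @return A single number `E_G`.
#' @export
expected_clonal_production <- function(frequency, clonal_spores,
                                       strain_id = NULL) {
  check_composition(frequency, strain_id)
  if (length(clonal_spores) != length(frequency) ||
      any(!is.finite(clonal_spores)) || any(clonal_spores < 0)) {
    missing_id <- if (!is.null(strain_id)) {
      strain_id[!is.finite(clonal_spores) | clonal_spores < 0][1]
    } else "?"
    abort(sprintf(
      "every strain needs a nonnegative clonal spore total (first offender: %s).",
      missing_id), class = "cigame_data_error")
  }
  sum(frequency * clonal_spores)
}

#' Relative spore production of a chimera
#'
#' `S_G = E_G / T_G`: the clonal expectation divided by the measured chimeric
#' total. `S_G = 1` means the chimera behaves like its clones; values below 1
#' mean the chimera overproduced spores, i.e. under-invested in stalk.
#'
#' @param e_g Expected clonal production `E_G` (> 0).
#' @param t_g Measured chimeric spore total `T_G` (> 0).
#' @return `S_G` (vectorised over both arguments).
#' @export
relative_production <- function(e_g, t_g) {
  if (any(!is.finite(t_g)) || any(t_g <= 0)) {
    abort("measured chimeric total `t_g` must be > 0.",
          class = "cigame_data_error")
  }
  e_g / t_g
}

#' Inferred collective investment from relative spore production
#'
#' Maps `S_G` onto the model's investment scale:
#' `I_G = 1 - (1 - theta) / S_G`. `S_G = 1` is read as the optimal investment
#' `theta`; `S_G = 1 - theta` is the zero-investment limit. Values of `S_G`
#' below `1 - theta` give negative inferred investment; these are returned
#' as-is (with a warning) because clipping them would bias least squares --
#' they flag noise or model misfit.
#'
#' @param s_g Relative spore production (> 0), vectorised.
#' @param theta The optimal investment level, in (0, 1).
#' @return Inferred investments `I_G`.
#' @export
infer_investment <- function(s_g, theta) {
  stop_if_not_number(theta, "theta", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(!is.finite(s_g)) || any(s_g <= 0)) {
    abort("`s_g` must be > 0.", class = "cigame_data_error")
  }
  out <- 1 - (1 - theta) / s_g
  if (any(out < 0)) {
    warn(sprintf(
      "%d inferred investment(s) are negative (S_G < 1 - theta); reported as-is.",
      sum(out < 0)))
  }
  out
}

#' Model prediction on the empirical (relative-production) scale
#'
#' Converts a model-predicted collective investment, expressed as a proportion
#' of `theta`, to the relative-spore-production scale. The default is the
#' linear map `X_G = 1 - theta * (1 - y)` used for fitting; the exact
#' hyperbolic inverse of [infer_investment()], `X_G = (1 - theta)/(1 - y
#' theta)`, is available via `map = "exact"`. The two agree at both endpoints
#' and differ by up to ~0.07 mid-scale for `theta` near 0.46; see the methods
#' vignette.
#'
#' @param y Predicted investment as a proportion of `theta`, in `[0, 1]`
#'   (vectorised).
#' @param theta The optimal investment level, in (0, 1).
#' @param map `"linear"` (default) or `"exact"`.
#' @return Predicted relative production `X_G`.
#' @export
model_to_empirical <- function(y, theta, map = c("linear", "exact")) {
  map <- match.arg(map)
  stop_if_not_number(theta, "theta", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    abort("`y` must lie in [0, 1].", class = "cigame_domain_error")
  }
  switch(map,
    linear = 1 - theta * (1 - y),
    exact = (1 - theta) / (1 - y * theta)
  )
}

#' Estimate stalk investment from a spore-count assay table
#'
#' The tabular front end to the empirical scale: takes the long assay schema
#' (one row per strain per group replicate) and returns one row per group
#' replicate with the expected clonal production `e_g`, relative production
#' `s_g`, inferred investment `i_g` and its proportion-of-theta version `y`.
#'
#' @param data A data frame with columns `strain_set_id`, `replicate_id`,
#'   `strain_id`, `frequency`, `clonal_spores`, `chimeric_spores` (the chimeric
#'   total repeated on each strain row of a group).
#' @param theta The optimal investment level used as the clonal reference.
#' @return A tibble with one row per (`strain_set_id`, `replicate_id`).
#' @examples
#' sim <- simulate_assay(design_nstrain(c(4, 10)), simulation_spec(seed = 1))
#' estimate_investment(sim, theta = theta(game_params(12, 1)))
#' @export
estimate_investment <- function(data, theta) {
  required <- c("strain_set_id", "replicate_id", "strain_id", "frequency",
                "clonal_spores", "chimeric_spores")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  data |>
    dplyr::group_by(.data$strain_set_id, .data$replicate_id) |>
    dplyr::group_modify(function(d, key) {
      check_composition(d$frequency, d$strain_id,
                        call_name = paste0("group ", key$strain_set_id))
      t_g <- unique(d$chimeric_spores)
      if (length(t_g) != 1L) {
        abort(sprintf("group %s: chimeric total differs across strain rows.",
                      key$strain_set_id), class = "cigame_data_error")
      }
      e_g <- expected_clonal_production(d$frequency, d$clonal_spores,
                                        d$strain_id)
      s_g <- relative_production(e_g, t_g)
      i_g <- infer_investment(s_g, theta)
      tibble(n_strains = nrow(d), e_g = e_g, s_g = s_g, i_g = i_g,
             y = i_g / theta)
    }) |>
    dplyr::ungroup()
}

#' Summarise investment estimates per composition
#'
#' Averages replicate-level investment estimates within each strain set,
#' returning the per-composition mean and standard error used by the fitting
#' functions.
#'
#' @param estimates Output of [estimate_investment()].
#' @return A tibble with columns `strain_set_id`, `n`, `s_mean`, `s_se`,
#'   `i_mean`, `y_mean`.
#' @export
summarize_investment <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$strain_set_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      s_mean = mean(.data$s_g),
      s_se = if (dplyr::n() > 1) sd(.data$s_g) / sqrt(dplyr::n()) else 0,
      i_mean = mean(.data$i_g),
      y_mean = mean(.data$y),
      .groups = "drop"
    )
}
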