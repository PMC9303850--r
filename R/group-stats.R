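# Fruiting-body collapse statistics, the collapse--investment correlation,
# and the two-strain vs twenty-strain enforcement comparison.

#' Regression of fruiting-body collapse on relatedness
#'
#' The headline statistic is the simple OLS of the proportion of collapsed
#' fruiting bodies on within-group relatedness, reported as `F(1, n - 2)`.
#' Alongside it (when `mixed = TRUE`) a maximum-likelihood mixed model adds a
#' random intercept for the strain combination, controlling for
#' combination-specific collapse behaviour.
#'
#' @param records A data frame with columns `relatedness`,
#'   `prop_collapsed` and (for the mixed model) `composition_id`.
#' @param mixed Also fit the mixed model? (Skipping it is useful in
#'   permutation loops.)
#' @return A tibble with one row per method (`ols`, and `mixed` if requested):
#'   slope `estimate`, `statistic` (OLS `F`; mixed-model `t`), `df1`, `df2`
#'   and `p_value`. A perfect linear fit is reported as an infinite F with
#'   p-value 0.
#' @export
collapse_regression <- function(records, mixed = TRUE) {
  required <- c("relatedness", "prop_collapsed")
  if (!all(required %in% names(records))) {
    abort("need columns relatedness and prop_collapsed.",
          class = "cigame_data_error")
  }
  n <- nrow(records)
  if (n < 3 || dplyr::n_distinct(records$relatedness) < 2) {
    abort("need >= 3 records with >= 2 distinct relatedness values.",
          class = "cigame_data_error")
  }
  fit <- lm(prop_collapsed ~ relatedness, data = records)
  rss <- sum(fit$residuals^2)
  slope <- coef(fit)[["relatedness"]]
  if (rss < 1e-25) {
    ols_row <- tibble(method = "ols", estimate = slope, statistic = Inf,
                      df1 = 1, df2 = n - 2, p_value = 0)
  } else {
    fstat <- summary(fit)$fstatistic
    ols_row <- tibble(method = "ols", estimate = slope,
                      statistic = unname(fstat[1]), df1 = unname(fstat[2]),
                      df2 = unname(fstat[3]),
                      p_value = pf(fstat[1], fstat[2], fstat[3],
                                   lower.tail = FALSE))
  }
  if (!mixed) return(ols_row)
  if (!"composition_id" %in% names(records)) {
    abort("the mixed model needs a composition_id column.",
          class = "cigame_data_error")
  }
  mm <- suppressWarnings(suppressMessages(
    lme4::lmer(prop_collapsed ~ relatedness + (1 | composition_id),
               data = records, REML = FALSE)
  ))
  est <- lme4::fixef(mm)[["relatedness"]]
  se <- sqrt(diag(as.matrix(vcov(mm))))[[2]]
  tval <- est / se
  df2 <- n - 2
  dplyr::bind_rows(
    ols_row,
    tibble(method = "mixed", estimate = est, statistic = tval,
           df1 = 1, df2 = df2,
           p_value = 2 * pt(-abs(tval), df2))
  )
}

#' Cubic-relatedness trend of collapse
#'
#' Visualisation aid: OLS of the collapse proportion on relatedness cubed.
#'
#' @inheritParams collapse_regression
#' @return The fitted `lm` object (`prop_collapsed ~ I(relatedness^3)`).
#' @export
collapse_trend_cubic <- function(records) {
  if (nrow(records) < 3 || dplyr::n_distinct(records$relatedness) < 2) {
    abort("need >= 3 records with >= 2 distinct relatedness values.",
          class = "cigame_data_error")
  }
  lm(prop_collapsed ~ I(relatedness^3), data = records)
}

#' Correlation between collapse and collective investment
#'
#' Pearson correlation of per-group-size mean collapse proportion against
#' per-group-size mean collective investment.
#'
#' @param collapse_means Data frame with columns `group_size` and
#'   `prop_collapsed` (one row per group size).
#' @param investment_means Data frame with columns `group_size` and
#'   `investment` (one row per group size).
#' @return A one-row tibble with `r`, `p_value`, `n`.
#' @export
correlate_collapse_investment <- function(collapse_means, investment_means) {
  joined <- dplyr::inner_join(collapse_means, investment_means,
                              by = "group_size")
  missing_sizes <- c(
    setdiff(collapse_means$group_size, investment_means$group_size),
    setdiff(investment_means$group_size, collapse_means$group_size)
  )
  if (length(missing_sizes)) {
    abort(paste0("group sizes present in only one table: ",
                 paste(sort(unique(missing_sizes)), collapse = ", ")),
          class = "cigame_data_error")
  }
  if (nrow(joined) < 3) {
    abort("need at least 3 matched group sizes.", class = "cigame_data_error")
  }
  ct <- cor.test(joined$prop_collapsed, joined$investment)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined))
}

#' Adjust nominal pair frequencies for representation bias
#'
#' Two-strain mixes are prepared at nominal frequencies, but strains differ
#' systematically in how many spores they contribute, which is visible in
#' 50:50 control mixes. If the focal strain's observed share in the 50:50 mix
#' is `s`, its representation is biased by the odds factor `beta = s / (1 -
#' s)`, and a nominal focal frequency `f` corresponds to an adjusted frequency
#' `f * beta / (f * beta + 1 - f)`. `s = 0.5` leaves frequencies unchanged;
#' the adjustment is monotone in `s` and preserves the pair's frequency sum.
#'
#' @param f Nominal focal frequencies in (0, 1) (vectorised).
#' @param s Observed focal share(s) in the 50:50 mix, in (0, 1).
#' @param method `"odds"` (default, the odds-scaling rule above) or
#'   `"linear"` (the focal share is simply rescaled by its relative
#'   representation, `f * 2 s`, clipped below 1; this variant does not
#'   preserve the pair sum and is provided for sensitivity analysis).
#' @return Adjusted focal frequencies.
#' @examples
#' adjust_pair_frequencies(0.05, s = 0.6)
#' @export
adjust_pair_frequencies <- function(f, s, method = c("odds", "linear")) {
  method <- match.arg(method)
  if (any(!is.finite(s)) || any(s <= 0 | s >= 1)) {
    abort("50:50 share `s` must lie strictly inside (0, 1).",
          class = "cigame_data_error")
  }
  if (any(!is.finite(f)) || any(f <= 0 | f >= 1)) {
    abort("nominal frequency `f` must lie strictly inside (0, 1).",
          class = "cigame_data_error")
  }
  if (method == "linear") {
    return(pmin(1 - 1e-12, f * 2 * s))
  }
  beta <- s / (1 - s)
  f * beta / (f * beta + (1 - f))
}

#' Compare low-frequency investment in two-strain vs twenty-strain groups
#'
#' Tests whether strains at ~5% frequency invest more in stalk when every
#' other group member is also rare (20-strain groups, strong enforcement
#' pressure) than when paired with one common strain (two-strain groups, weak
#' pressure). Fits a maximum-likelihood mixed model with group type as the
#' fixed effect and the replicate group (strain identity for pairs, `N` for
#' the 20-strain groups) as a random intercept; the minimal degrees of
#' freedom, the number of replicate groups minus one, are enforced on the
#' two-sided t test.
#'
#' @param records A data frame with columns `group_type` (`"two_strain"` or
#'   `"twenty_strain"`), `replicate_group` and `investment`.
#' @return A one-row tibble: fixed-effect `estimate` (twenty minus two),
#'   `se`, `statistic`, `df`, `p_value`, `n_groups`.
#' @export
compare_two_vs_twenty <- function(records) {
  required <- c("group_type", "replicate_group", "investment")
  if (!all(required %in% names(records))) {
    abort("need columns group_type, replicate_group, investment.",
          class = "cigame_data_error")
  }
  types <- unique(records$group_type)
  if (!all(c("two_strain", "twenty_strain") %in% types)) {
    abort("both group types must be present.", class = "cigame_data_error")
  }
  n_groups <- dplyr::n_distinct(records$replicate_group)
  if (n_groups < 2) {
    abort("need more than one replicate group for the enforced df.",
          class = "cigame_df_error")
  }
  records$group_type <- factor(records$group_type,
                               levels = c("two_strain", "twenty_strain"))
  mm <- suppressWarnings(suppressMessages(
    lme4::lmer(investment ~ group_type + (1 | replicate_group),
               data = records, REML = FALSE)
  ))
  est <- lme4::fixef(mm)[["group_typetwenty_strain"]]
  se <- sqrt(diag(as.matrix(vcov(mm))))[[2]]
  tval <- est / se
  df <- n_groups - 1
  tibble(estimate = est, se = se, statistic = tval, df = df,
         p_value = 2 * pt(-abs(tval), df), n_groups = n_groups)
}
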