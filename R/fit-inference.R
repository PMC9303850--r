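# Uncertainty and model comparison for Collective Investment game fits.

#' Parametric-bootstrap confidence intervals for a game fit
#'
#' Resamples each composition mean from a Gaussian centred on the observed
#' mean with its standard error (the sampling distribution of the mean),
#' refits the grid search to every resampled dataset, and summarises each
#' parameter by the 5th--95th percentile range of the deviations from the
#' point estimate. Refitting reuses the prediction matrix computed by the
#' original fit, so each iteration is an exact re-minimisation, not an
#' approximation. A nonparametric alternative resamples replicate-level
#' estimates within compositions (`method = "resample"`).
#'
#' In addition to per-parameter intervals, a conservative prediction band is
#' built from the corner combination of parameter bounds that maximises the
#' deviation of predicted investment from the point fit.
#'
#' @param fit A `cig_fit` from [fit_investment_game()] or
#'   [fit_transdifferentiation()].
#' @param n_boot Iterations (default from the fit's [fit_config()]).
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @param method `"parametric"` (Gaussian around the mean, default) or
#'   `"resample"` (resample replicate estimates; requires `replicates`).
#' @param replicates For `method = "resample"`: a data frame with columns
#'   `strain_set_id` and `s_g` holding replicate-level relative production.
#' @return An object of class `cig_boot`; `tidy()` returns the parameter
#'   intervals.
#' @export
bootstrap_ci <- function(fit, n_boot = NULL, seed = NULL,
                         method = c("parametric", "resample"),
                         replicates = NULL) {
  stopifnot(inherits(fit, "cig_fit"))
  method <- match.arg(method)
  n_boot <- n_boot %||% fit$config$n_boot
  if (n_boot < 20) {
    warn("fewer than 20 bootstrap iterations: percentile bounds are unstable.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (method == "resample") {
    if (is.null(replicates) ||
        !all(c("strain_set_id", "s_g") %in% names(replicates))) {
      abort("`replicates` with columns strain_set_id, s_g is required.",
            class = "cigame_data_error")
    }
    rep_split <- split(replicates$s_g, replicates$strain_set_id)
    rep_split <- rep_split[fit$data$strain_set_id]
    if (anyNA(names(rep_split))) {
      abort("`replicates` is missing some compositions of the fit.",
            class = "cigame_data_error")
    }
  }

  P <- fit$P
  csP2 <- colSums(P^2)
  mu <- fit$data$s_mean
  se <- fit$data$s_se
  n_comp <- length(mu)
  par_names <- names(fit$grid)

  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(par_names),
                  dimnames = list(NULL, par_names))
  for (iter in seq_len(n_boot)) {
    o <- if (method == "parametric") {
      rnorm(n_comp, mean = mu, sd = se)
    } else {
      vapply(rep_split, function(v) mean(sample(v, replace = TRUE)),
             numeric(1))
    }
    rssv <- sum(o^2) - 2 * drop(crossprod(P, o)) + csP2
    idx <- pick_best(rssv, fit$grid)$idx
    draws[iter, ] <- as.numeric(fit$grid[idx, ])
  }

  est <- unlist(fit$params[par_names])
  ci <- purrr::map_dfr(par_names, function(nm) {
    dev <- draws[, nm] - est[[nm]]
    q <- quantile(dev, c(0.05, 0.95), names = FALSE)
    tibble(parameter = nm, estimate = est[[nm]],
           lower = est[[nm]] + q[1], upper = est[[nm]] + q[2])
  })

  band <- conservative_band(fit, ci)

  structure(list(ci = ci, draws = as_tibble(draws), band = band$band,
                 worst_corner = band$worst, method = method,
                 n_boot = n_boot, fit = fit),
            class = "cig_boot")
}

# prediction band from the CI corner that deviates most from the point fit
conservative_band <- function(fit, ci) {
  bounds <- lapply(seq_len(nrow(ci)), function(i) {
    unique(c(ci$lower[i], ci$upper[i]))
  })
  names(bounds) <- ci$parameter
  corners <- do.call(tidyr::expand_grid, bounds)
  fixed <- fit$params
  preds <- purrr::map(seq_len(nrow(corners)), function(i) {
    p <- as.list(corners[i, ])
    b <- p$b %||% fixed$b; cc <- p$c %||% fixed$c
    e <- p$e %||% fixed$e; tt <- p$t %||% fixed$t
    D <- p$D %||% fixed$D
    with_td <- fit$type == "D"
    gp <- game_params(max(b, 1e-9), max(cc, 1e-9),
                      D = if (with_td) clip01(D) else 0)
    err <- if (e > 1e-12) error_model(max(e, 0), max(tt, 0)) else NULL
    predict_compositions(fit$compositions, gp, err, with_td, fit$map,
                         fit$config$tails)
  })
  pm <- do.call(cbind, preds)
  dev <- colSums(abs(pm - fit$predictions$predicted))
  worst_i <- which.max(dev)
  list(
    band = tibble(
      strain_set_id = fit$predictions$strain_set_id,
      fit = fit$predictions$predicted,
      lower = apply(pm, 1, min),
      upper = apply(pm, 1, max)
    ),
    worst = as.list(corners[worst_i, ])
  )
}

#' @exportS3Method base::print
print.cig_boot <- function(x, ...) {
  cat(sprintf("Bootstrap CIs (%s, %d iterations)\n", x$method, x$n_boot))
  print(x$ci)
  invisible(x)
}

#' Nested-model F test: perfect versus imperfect information
#'
#' Compares the residual sums of squares of a restricted fit (perfect
#' information, `e` fixed at 0, which also removes `t`) and the full fit via
#' `F = ((RSS0 - RSS1) / delta_p) / (RSS1 / (n - p_full))`.
#'
#' @param fit_restricted,fit_full `cig_fit` objects on the same data, with the
#'   restricted model nested in the full one.
#' @param n Number of observations (defaults to the full fit's composition
#'   count).
#' @param delta_p Parameters dropped by the restriction (default 2: `e` and
#'   `t`).
#' @param p_full Parameters of the full model (default 4).
#' @return A one-row tibble with the statistic, degrees of freedom, p-value
#'   and both RSS values. A perfectly fitting full model (`RSS1 = 0`) is
#'   reported as an infinite statistic with `perfect_fit = TRUE`.
#' @export
model_compare_F <- function(fit_restricted, fit_full, n = NULL, delta_p = 2,
                            p_full = 4) {
  stopifnot(inherits(fit_restricted, "cig_fit"), inherits(fit_full, "cig_fit"))
  n <- n %||% fit_full$n
  if (n <= p_full) {
    abort("need more observations than full-model parameters for the F test.",
          class = "cigame_df_error")
  }
  rss0 <- fit_restricted$rss
  rss1 <- fit_full$rss
  if (rss1 == 0) {
    return(tibble(statistic = Inf, df1 = delta_p, df2 = n - p_full,
                  p_value = 0, rss_restricted = rss0, rss_full = rss1,
                  perfect_fit = TRUE))
  }
  f <- ((rss0 - rss1) / delta_p) / (rss1 / (n - p_full))
  tibble(statistic = f, df1 = delta_p, df2 = n - p_full,
         p_value = pf(f, delta_p, n - p_full, lower.tail = FALSE),
         rss_restricted = rss0, rss_full = rss1, perfect_fit = FALSE)
}

#' Goodness of fit between observations and model predictions
#'
#' Computes the variance explained (`R^2 = 1 - RSS/TSS`, with TSS about the
#' observed mean), the Pearson correlation between predictions and
#' observations, and a two-sided paired t test of the observation--prediction
#' pairs.
#'
#' @param observed Either a numeric vector or a `cig_fit` (in which case its
#'   stored predictions are used and `predicted` is ignored).
#' @param predicted Numeric vector paired with `observed`.
#' @return A one-row tibble: `r_squared`, `pearson_r`, `pearson_p`,
#'   `t_statistic`, `t_df`, `t_p`, `n`.
#' @export
goodness_of_fit <- function(observed, predicted = NULL) {
  if (inherits(observed, "cig_fit")) {
    predicted <- observed$predictions$predicted
    observed <- observed$predictions$observed
  }
  if (length(observed) != length(predicted) || length(observed) < 3) {
    abort("need paired vectors of equal length with n >= 3.",
          class = "cigame_data_error")
  }
  if (var(observed) == 0) {
    abort("observations have zero variance: R^2 is undefined.",
          class = "cigame_data_error")
  }
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  identical_pairs <- isTRUE(all.equal(observed, predicted, tolerance = 1e-12))
  ct <- if (identical_pairs) NULL else cor.test(observed, predicted)
  tt <- if (identical_pairs) NULL else t.test(observed, predicted,
                                              paired = TRUE)
  tibble(
    r_squared = 1 - rss / tss,
    pearson_r = if (identical_pairs) 1 else unname(ct$estimate),
    pearson_p = if (identical_pairs) 0 else ct$p.value,
    t_statistic = if (identical_pairs) 0 else unname(tt$statistic),
    t_df = length(observed) - 1,
    t_p = if (identical_pairs) 1 else tt$p.value,
    n = length(observed)
  )
}
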