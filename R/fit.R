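# Grid-search fitting of the Collective Investment game to per-composition
# mean investment data (observed on the relative-spore-production scale).

# ---- input plumbing --------------------------------------------------------

# data: long tibble with one row per strain per composition:
#   strain_set_id, strain_id, frequency, s_mean [, s_se]
# returns list(comps = list of frequency vectors, ids, obs, se)
prepare_fit_data <- function(data) {
  required <- c("strain_set_id", "strain_id", "frequency", "s_mean")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  if (any(!is.finite(data$s_mean))) {
    abort("`s_mean` contains missing or non-finite values.",
          class = "cigame_data_error")
  }
  split_d <- split(data, data$strain_set_id)
  ids <- names(split_d)
  comps <- lapply(split_d, function(d) {
    check_composition(d$frequency, d$strain_id,
                      call_name = paste0("group ", d$strain_set_id[1]))
    d$frequency
  })
  obs <- vapply(split_d, function(d) {
    s <- unique(d$s_mean)
    if (length(s) != 1L) {
      abort(sprintf("group %s: `s_mean` differs across strain rows.",
                    d$strain_set_id[1]), class = "cigame_data_error")
    }
    s
  }, numeric(1))
  se <- if ("s_se" %in% names(data)) {
    vapply(split_d, function(d) unique(d$s_se)[1], numeric(1))
  } else {
    rep(0, length(ids))
  }
  if (length(ids) < 2L) {
    abort("need at least 2 distinct compositions to fit.",
          class = "cigame_data_error")
  }
  list(ids = ids, comps = comps, obs = unname(obs), se = unname(se))
}

# composition weight matrix over the unique relatedness values
composition_matrix <- function(comps, r_u) {
  C <- matrix(0, nrow = length(comps), ncol = length(r_u))
  key <- as.character(signif(r_u, 12))
  for (i in seq_along(comps)) {
    k <- as.character(signif(comps[[i]], 12))
    for (j in seq_along(k)) {
      col <- match(k[j], key)
      C[i, col] <- C[i, col] + comps[[i]][j]
    }
  }
  C
}

# ---- the grid search -------------------------------------------------------

#' Fit the Collective Investment game by grid search
#'
#' Minimises the sum of squared differences between observed per-composition
#' mean relative spore production and the game's predictions over a grid of
#' `(b, c, e, t)` values. Predictions compose the perfect-information optimum,
#' the perception-error quadrature, frequency-weighted aggregation and the
#' empirical-scale map. The search is exhaustive and deterministic; exact ties
#' are broken towards the smallest `(b, c, e, t)` in lexicographic order and
#' all tied grid points are reported.
#'
#' @param data A long data frame with one row per strain per composition:
#'   columns `strain_set_id`, `strain_id`, `frequency`, `s_mean` (the observed
#'   composition mean on the relative-production scale, repeated on each
#'   strain row) and optionally `s_se` (its standard error, used by
#'   [bootstrap_ci()]).
#' @param config A [fit_config()].
#' @return An object of class `cig_fit` with the best-fit parameters, the
#'   residual sum of squares, per-composition predictions, the searched grid
#'   and everything [bootstrap_ci()] needs to resample cheaply.
#' @seealso [fit_transdifferentiation()], [model_compare_F()],
#'   [goodness_of_fit()]
#' @export
fit_investment_game <- function(data, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  fd <- prepare_fit_data(data)
  n_comp <- length(fd$comps)

  r_u <- sort(unique(unlist(lapply(fd$comps, function(x) signif(x, 12)))))
  C <- composition_matrix(fd$comps, r_u)

  bg <- config$b_grid; cg <- config$c_grid
  eg <- config$e_grid; tg <- config$t_grid
  n_b <- length(bg); n_c <- length(cg); n_e <- length(eg); n_t <- length(tg)
  n_bc <- n_b * n_c
  n_combo <- n_bc * n_e * n_t

  g <- seq(0, 1, length.out = config$n_grid)
  wq <- trapezoid_weights(config$n_grid)

  # strategy curves per (b, c): columns ordered b-outer, c-inner
  bc <- tidyr::expand_grid(b = bg, c = cg)
  X <- matrix(0, nrow = config$n_grid, ncol = n_bc)
  theta_bc <- numeric(n_bc)
  xhat_ru <- matrix(0, nrow = length(r_u), ncol = n_bc) # closed form at r_u
  for (j in seq_len(n_bc)) {
    p <- game_params(bc$b[j], bc$c[j])
    X[, j] <- optimal_investment(g, p)
    theta_bc[j] <- theta(p)
    xhat_ru[, j] <- optimal_investment(r_u, p)
  }

  P <- matrix(NA_real_, nrow = n_comp, ncol = n_combo)
  col0 <- 0L
  for (ie in seq_len(n_e)) {
    for (it in seq_len(n_t)) {
      err <- error_model(eg[ie], tg[it])
      sds <- perceived_sd(r_u, err)
      live <- sds >= 1e-12
      E <- xhat_ru
      if (any(live)) {
        W <- matrix(0, nrow = sum(live), ncol = config$n_grid)
        rl <- r_u[live]; sl <- sds[live]
        for (i in seq_along(rl)) {
          dens <- dnorm(g, mean = rl[i], sd = sl[i])
          if (config$tails == "reflect") {
            dens <- dens + dnorm(-g, mean = rl[i], sd = sl[i]) +
              dnorm(2 - g, mean = rl[i], sd = sl[i])
          }
          W[i, ] <- dens * wq
        }
        E[live, ] <- (W %*% X) / rowSums(W)
      }
      xg <- C %*% E                       # n_comp x n_bc
      pred <- if (config$map == "linear") {
        sweep(xg, 2, 1 - theta_bc, "+")
      } else {
        sweep(1 - xg, 2, 1 - theta_bc, FUN = function(a, b) b / a)
      }
      P[, (col0 + 1L):(col0 + n_bc)] <- pred
      col0 <- col0 + n_bc
    }
  }

  # grid_df columns align with P: e slowest, then t, then (b, c)
  grid_df <- tidyr::expand_grid(e = eg, t = tg, b = bg, c = cg) |>
    dplyr::select("b", "c", "e", "t")

  rss <- colSums((fd$obs - P)^2)
  best <- pick_best(rss, grid_df)

  params <- as.list(grid_df[best$idx, ])
  pred_best <- P[, best$idx]
  th <- theta(game_params(params$b, params$c))

  structure(list(
    type = "grid",
    params = list(b = params$b, c = params$c, e = params$e, t = params$t,
                  D = NA_real_),
    theta = th,
    rss = rss[best$idx],
    n = n_comp,
    map = config$map,
    predictions = tibble(strain_set_id = fd$ids, observed = fd$obs,
                         predicted = pred_best),
    data = tibble(strain_set_id = fd$ids, s_mean = fd$obs, s_se = fd$se),
    compositions = fd$comps,
    ties = grid_df[best$tied, , drop = FALSE],
    grid = grid_df,
    P = P,
    config = config
  ), class = "cig_fit")
}

# deterministic argmin with lexicographic tie-breaking on (b, c, e, t[, D])
pick_best <- function(rss, grid_df, tol = 1e-12) {
  m <- min(rss)
  tied <- which(rss <= m + tol)
  ord <- tied[do.call(order, as.list(grid_df[tied, , drop = FALSE]))]
  list(idx = ord[1], tied = tied)
}

#' @exportS3Method base::print
print.cig_fit <- function(x, ...) {
  p <- x$params
  if (x$type == "grid") {
    cat(sprintf(
      "Collective Investment game fit (grid search, %d compositions)\n",
      x$n))
    cat(sprintf("  b = %g, c = %g, e = %g, t = %g  (theta = %.4f)\n",
                p$b, p$c, p$e, p$t, x$theta))
  } else {
    cat(sprintf(
      "Transdifferentiation fit (D search, %d compositions)\n", x$n))
    cat(sprintf("  D = %g with fixed b = %g, c = %g, e = %g, t = %g\n",
                p$D, p$b, p$c, p$e, p$t))
  }
  cat(sprintf("  RSS = %.6g on the %s empirical scale\n", x$rss, x$map))
  if (nrow(x$ties) > 1) {
    cat(sprintf("  note: %d grid points tie at the minimum\n", nrow(x$ties)))
  }
  invisible(x)
}

# ---- D search --------------------------------------------------------------

#' Fit the transdifferentiation pressure D
#'
#' One-dimensional search for the enforcement parameter `D` on the configured
#' grid (default `[0, 0.25]` in steps of 0.01), holding the remaining game and
#' error parameters fixed (typically at the best fit from the three-strain
#' data). Predictions use the enforcement-aware inherent allocation, the
#' perception-error quadrature, and the negative-feedback map to realised
#' investment.
#'
#' @inheritParams fit_investment_game
#' @param fixed Either a `cig_fit` from [fit_investment_game()] or a named
#'   list with elements `b`, `c`, `e`, `t`.
#' @return A `cig_fit` of type `"D"`.
#' @export
fit_transdifferentiation <- function(data, fixed, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (inherits(fixed, "cig_fit")) fixed <- fixed$params
  for (nm in c("b", "c", "e", "t")) {
    if (is.null(fixed[[nm]])) {
      abort(sprintf("`fixed` must supply `%s`.", nm),
            class = "cigame_config_error")
    }
  }
  fd <- prepare_fit_data(data)
  err <- if (fixed$e > 0) error_model(fixed$e, fixed$t) else NULL
  Dg <- config$D_grid
  P <- matrix(NA_real_, nrow = length(fd$comps), ncol = length(Dg))
  th <- theta(game_params(fixed$b, fixed$c))
  for (k in seq_along(Dg)) {
    p_k <- game_params(fixed$b, fixed$c, D = Dg[k])
    xg <- vapply(fd$comps, function(freqs) {
      comp <- tibble(strain_id = as.character(seq_along(freqs)),
                     frequency = freqs)
      predict_collective(comp, p_k, err, with_transdiff = TRUE,
                         tails = config$tails)
    }, numeric(1))
    P[, k] <- model_to_empirical(clip01(xg / th), th, map = config$map)
  }
  rss <- colSums((fd$obs - P)^2)
  grid_df <- tibble(D = Dg)
  best <- pick_best(rss, grid_df)

  structure(list(
    type = "D",
    params = list(b = fixed$b, c = fixed$c, e = fixed$e, t = fixed$t,
                  D = Dg[best$idx]),
    theta = th,
    rss = rss[best$idx],
    n = length(fd$comps),
    map = config$map,
    predictions = tibble(strain_set_id = fd$ids, observed = fd$obs,
                         predicted = P[, best$idx]),
    data = tibble(strain_set_id = fd$ids, s_mean = fd$obs, s_se = fd$se),
    compositions = fd$comps,
    ties = grid_df[best$tied, , drop = FALSE],
    grid = grid_df,
    P = P,
    config = config
  ), class = "cig_fit")
}

# predictions at arbitrary (possibly off-grid) parameter values, used for the
# conservative bootstrap band
predict_compositions <- function(comps, params, err, with_transdiff, map,
                                 tails = "truncate") {
  th <- theta(params)
  vapply(comps, function(freqs) {
    comp <- tibble(strain_id = as.character(seq_along(freqs)),
                   frequency = freqs)
    xg <- predict_collective(comp, params, err,
                             with_transdiff = with_transdiff, tails = tails)
    model_to_empirical(clip01(xg / th), th, map = map)
  }, numeric(1))
}
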