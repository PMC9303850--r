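#' Optimal investment given perfect information
#'
#' The fitness-maximising fraction of a player's cell budget to invest in the
#' public good (stalk), as a function of its relatedness `r` to the group:
#' `x = (1/c - 1/(b r)) / 2` where positive, and 0 otherwise. Investment
#' drops to zero once `r < c / b` (Hamilton's rule threshold); at `r = 1` it
#' equals [theta()]. `r = 0` is handled as the limit, returning 0.
#'
#' @param r Relatedness values in `[0, 1]` (vectorised).
#' @param params A [game_params()] object (`D` is ignored here).
#' @return Investment fractions, same length as `r`.
#' @examples
#' p <- game_params(12, 1)
#' optimal_investment(c(0, 0.05, 0.5, 1), p)
#' @export
optimal_investment <- function(r, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    abort("relatedness `r` must lie in [0, 1].", class = "cigame_domain_error")
  }
  x <- numeric(length(r))
  pos <- r > 0
  x[pos] <- pmax(0, 0.5 * (1 / params$c - 1 / (params$b * r[pos])))
  x
}

#' Player fitness in the Collective Investment game
#'
#' Fitness is the product of a direct-cost component `C = 1 - c x` and a
#' shared-benefit component `B = 1 + r b x`, i.e. `omega = B * C`. Investing
#' nothing gives the baseline fitness 1.
#'
#' @param x Realised investment in `[0, 1]` (vectorised).
#' @inheritParams optimal_investment
#' @return Fitness values. If `c * x > 1` the (unbiological) negative survival
#'   is clipped to zero fitness with a warning.
#' @examples
#' player_fitness(theta(game_params(12, 1)), r = 1, game_params(12, 1))
#' @export
player_fitness <- function(x, r, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(x < 0 | x > 1)) {
    abort("investment `x` must lie in [0, 1].", class = "cigame_domain_error")
  }
  if (any(r < 0 | r > 1)) {
    abort("relatedness `r` must lie in [0, 1].", class = "cigame_domain_error")
  }
  w <- (1 + r * params$b * x) * (1 - params$c * x)
  if (any(params$c * x > 1)) {
    warn("cost exceeds the survival budget (c * x > 1); fitness clipped at 0.")
    w <- pmax(w, 0)
  }
  w
}

#' Optimal initial stalk allocation under transdifferentiation
#'
#' With enforcement, fitness depends on the realised investment
#' `x = A + D * (theta - A_G)`, so the optimal inherent allocation `A`
#' compensates for the enforcement a strain expects to receive. Under the
#' many-strain assumption (all non-focal strains allocate 0, so
#' `A_G = r * A`), the optimum is
#' `A = ((1 - D) / (c (1 - D r)) - 1 / (b r)) / 2` where positive, else 0.
#' At `D = 0` this reduces to [optimal_investment()]; at `r = 1` it equals
#' [theta()] for any valid `D`.
#'
#' @inheritParams optimal_investment
#' @param params A [game_params()] object whose `D` is used.
#' @return Inherent allocation fractions, same length as `r`.
#' @export
optimal_initial_allocation <- function(r, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    abort("relatedness `r` must lie in [0, 1].", class = "cigame_domain_error")
  }
  if (any(params$D * r >= 1)) {
    abort("D * r >= 1 leaves no feasible allocation (zero denominator).",
          class = "cigame_invalid_parameter")
  }
  a <- numeric(length(r))
  pos <- r > 0
  a[pos] <- pmax(0, 0.5 * ((1 - params$D) / (params$c * (1 - params$D * r[pos]))
                           - 1 / (params$b * r[pos])))
  a
}

#' Collective investment of a group
#'
#' Frequency-weighted sum of per-strain investments,
#' `x_G = sum(r_i * x_i)`. A strain's relatedness to the group equals its
#' frequency (all strains are assumed pairwise unrelated).
#'
#' @param composition A data frame with columns `strain_id` and `frequency`
#'   (frequencies > 0, summing to 1).
#' @param invest Either a numeric vector of per-strain investments aligned with
#'   the rows of `composition`, or a function of relatedness applied to each
#'   strain's frequency.
#' @return A single number, the collective investment `x_G`.
#' @examples
#' comp <- tibble::tibble(strain_id = c("a", "b"), frequency = c(0.5, 0.5))
#' collective_investment(comp, function(r) optimal_investment(r, game_params(12, 1)))
#' @export
collective_investment <- function(composition, invest) {
  check_composition(composition$frequency, composition$strain_id)
  x <- if (is.function(invest)) invest(composition$frequency) else invest
  if (length(x) != nrow(composition)) {
    abort("`invest` must give one investment per strain.",
          class = "cigame_invalid_parameter")
  }
  sum(composition$frequency * x)
}

# ---- perception-error quadrature ------------------------------------------
#
# Expected investment when the player's perceived relatedness is Gaussian
# around the truth: E[x] = \int strategy(rho) phi(rho; r, sd) drho. The
# Gaussian is restricted to [0, 1] (relatedness is only defined there) and
# renormalised; a reflected alternative is kept behind `tails`.
# Fixed 2001-point trapezoid grid: the strategy is piecewise smooth with a
# single kink, for which this density keeps the quadrature error well below
# the Monte-Carlo resolution used to validate it.

quad_grid_n <- 2001L

#' Expected investment under relatedness-perception error
#'
#' Averages a strategy over the distribution of perceived relatedness: a
#' Gaussian centred on the true relatedness `r` with SD [perceived_sd()],
#' truncated to `[0, 1]` and renormalised (or reflected at the boundaries via
#' `tails = "reflect"`). Zero SD returns `strategy(r)` exactly.
#'
#' @inheritParams optimal_investment
#' @param err An [error_model()] object, or `NULL` for perfect information.
#' @param strategy A vectorised function of perceived relatedness; defaults to
#'   the perfect-information optimum [optimal_investment()] under `params`.
#' @param tails How to handle probability mass outside `[0, 1]`: `"truncate"`
#'   (renormalise, default) or `"reflect"` (fold back at the boundaries).
#' @param n_grid Number of trapezoid quadrature nodes.
#' @return Expected investments, same length as `r`.
#' @examples
#' p <- game_params(12, 1)
#' expected_investment(0.2, p, error_model(e = 0.2, t = 1))
#' @export
expected_investment <- function(r, params, err = NULL, strategy = NULL,
                                tails = c("truncate", "reflect"),
                                n_grid = quad_grid_n) {
  stopifnot(inherits(params, "game_params"))
  tails <- match.arg(tails)
  if (is.null(strategy)) {
    strategy <- function(rho) optimal_investment(rho, params)
  }
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    abort("relatedness `r` must lie in [0, 1].", class = "cigame_domain_error")
  }
  sds <- if (is.null(err)) rep(0, length(r)) else perceived_sd(r, err)
  g <- seq(0, 1, length.out = n_grid)
  wq <- trapezoid_weights(n_grid)
  fx <- NULL # strategy evaluated on the grid, built lazily
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    if (sds[i] < 1e-12) {
      out[i] <- strategy(r[i])
      next
    }
    if (is.null(fx)) fx <- strategy(g)
    dens <- dnorm(g, mean = r[i], sd = sds[i])
    if (tails == "reflect") {
      dens <- dens + dnorm(-g, mean = r[i], sd = sds[i]) +
        dnorm(2 - g, mean = r[i], sd = sds[i])
    }
    w <- dens * wq
    out[i] <- sum(w * fx) / sum(w)
  }
  out
}

#' Realised investment after transdifferentiation feedback
#'
#' Given each strain's inherent stalk allocation `A_i`, the group allocation is
#' `A_G = sum(r_i A_i)` and the negative-feedback enforcement pushes every
#' strain's realised investment to `x_i = A_i + D * (theta - A_G)`, clipped to
#' `[0, 1]`. Whenever the group under-allocates (`A_G < theta`) every strain is
#' forced above its inherent allocation.
#'
#' @inheritParams collective_investment
#' @param allocation Numeric vector of inherent allocations `A_i` in `[0, 1]`,
#'   aligned with the rows of `composition`.
#' @param params A [game_params()] object whose `D` and [theta()] drive the
#'   feedback.
#' @return A tibble with columns `strain_id`, `frequency`, `allocation`,
#'   `investment`, and attributes `A_G` and `x_G` (also exposed as columns of
#'   the summary from [predict_collective()]).
#' @export
realized_investment <- function(composition, allocation, params) {
  stopifnot(inherits(params, "game_params"))
  check_composition(composition$frequency, composition$strain_id)
  if (length(allocation) != nrow(composition) ||
      any(allocation < 0 | allocation > 1)) {
    abort("`allocation` must give one value in [0, 1] per strain.",
          class = "cigame_invalid_parameter")
  }
  a_g <- sum(composition$frequency * allocation)
  x <- clip01(allocation + params$D * (theta(params) - a_g))
  out <- tibble(
    strain_id = composition$strain_id,
    frequency = composition$frequency,
    allocation = allocation,
    investment = x
  )
  attr(out, "A_G") <- a_g
  attr(out, "x_G") <- sum(out$frequency * out$investment)
  out
}

#' Predicted collective investment for a group composition
#'
#' Composes the pieces of the game into the model's prediction for one group:
#' each strain's strategy (perfect-information optimum, or the inherent
#' allocation that anticipates enforcement when `with_transdiff = TRUE`) is
#' averaged over perception error, then, with transdifferentiation, the
#' negative feedback converts inherent allocations into realised investments.
#'
#' @inheritParams collective_investment
#' @param params A [game_params()] object.
#' @param err An [error_model()] object or `NULL` (perfect information).
#' @param with_transdiff Apply the enforcement term? Uses `params$D`.
#' @param tails Passed to [expected_investment()].
#' @return The collective investment `x_G` (a single number).
#' @examples
#' p <- game_params(12, 1, D = 0.15)
#' comp <- tibble::tibble(strain_id = letters[1:20], frequency = rep(0.05, 20))
#' predict_collective(comp, p, with_transdiff = TRUE) # enforcement floor D * theta
#' @export
predict_collective <- function(composition, params, err = NULL,
                               with_transdiff = FALSE,
                               tails = c("truncate", "reflect")) {
  stopifnot(inherits(params, "game_params"))
  tails <- match.arg(tails)
  check_composition(composition$frequency, composition$strain_id)
  rs <- composition$frequency
  if (with_transdiff) {
    strat <- function(rho) optimal_initial_allocation(rho, params)
    a_i <- expected_investment(rs, params, err, strategy = strat, tails = tails)
    prof <- realized_investment(composition, a_i, params)
    attr(prof, "x_G")
  } else {
    x_i <- expected_investment(rs, params, err, tails = tails)
    sum(rs * x_i)
  }
}
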