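#' Parameters of the Collective Investment game
#'
#' Bundles the benefit rate `b`, the cost rate `c` and the transdifferentiation
#' pressure `D` of the Collective Investment game. Each unit of public-good
#' (stalk) investment by a player costs `c` units of direct fitness and adds
#' `r * b` units of group benefit to a player whose relatedness to the group is
#' `r`. `D` scales the negative-feedback enforcement that pushes realised stalk
#' allocation back towards the group optimum when the group under-allocates.
#'
#' @param b Benefit rate per unit investment (dimensionless, > 0).
#' @param c Cost rate per unit investment (dimensionless, > 0).
#' @param D Transdifferentiation pressure in `[0, 1]`. `D = 0` recovers the
#'   game without enforcement.
#'
#' @return An object of class `game_params`.
#' @examples
#' p <- game_params(b = 12, c = 1)
#' theta(p)
#' @export
game_params <- function(b, c, D = 0) {
  stop_if_not_number(b, "b", lower = 0, strict_lower = TRUE)
  stop_if_not_number(c, "c", lower = 0, strict_lower = TRUE)
  stop_if_not_number(D, "D", lower = 0, upper = 1)
  structure(list(b = b, c = c, D = D), class = "game_params")
}

#' @exportS3Method base::print
print.game_params <- function(x, ...) {
  cat(sprintf(
    "Collective Investment game: b = %g, c = %g, D = %g (theta = %.4f)\n",
    x$b, x$c, x$D, theta(x)))
  invisible(x)
}

#' Group-optimal investment level
#'
#' The investment level that maximises whole-group fitness,
#' `theta = (b - c) / (2 b c)`. This is the level a clonal group should adopt.
#' When `b <= c` no positive investment pays and the optimum is 0.
#'
#' @param params A [game_params()] object.
#' @return A single number in `[0, 1)` for the parameter ranges used here.
#' @examples
#' theta(game_params(12, 1)) # 11/24, prints as 0.46 at two decimals
#' @export
theta <- function(params) {
  stopifnot(inherits(params, "game_params"))
  if (params$b <= params$c) return(0)
  (params$b - params$c) / (2 * params$b * params$c)
}

#' Relatedness-perception error model
#'
#' Players estimate their relatedness to the group with Gaussian error. The
#' standard deviation of the perceived relatedness at true relatedness `r` is
#' `e * 4^t * (r * (1 - r))^t`: the baseline noise `e` applies at `r = 0.5`
#' for every `t`, and `t > 0` concentrates noise at intermediate relatedness
#' (signals are assumed more reliable near clonality or vanishing frequency).
#' `t = 0` gives frequency-independent noise.
#'
#' @param e Baseline SD of perceived relatedness (relatedness units, >= 0).
#' @param t Frequency-dependence exponent (dimensionless, >= 0).
#' @return An object of class `error_model`.
#' @examples
#' err <- error_model(e = 0.2, t = 1)
#' perceived_sd(c(0, 0.25, 0.5, 1), err)
#' @export
error_model <- function(e, t = 0) {
  stop_if_not_number(e, "e", lower = 0)
  stop_if_not_number(t, "t", lower = 0)
  structure(list(e = e, t = t), class = "error_model")
}

#' @exportS3Method base::print
print.error_model <- function(x, ...) {
  cat(sprintf("Perception error model: e = %g, t = %g\n", x$e, x$t))
  invisible(x)
}

#' @describeIn error_model SD of perceived relatedness at true relatedness `r`
#'   (vectorised over `r`).
#' @param r True relatedness values in `[0, 1]`.
#' @param err An `error_model` object.
#' @export
perceived_sd <- function(r, err) {
  stopifnot(inherits(err, "error_model"))
  if (any(r < 0 | r > 1)) {
    abort("relatedness `r` must lie in [0, 1].", class = "cigame_domain_error")
  }
  # 0^0 == 1 in R, so t = 0 gives a constant SD of e including at r = 0, 1
  err$e * 4^err$t * (r * (1 - r))^err$t
}
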