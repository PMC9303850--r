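# internal helpers shared across modules

clip01 <- function(x) pmin(1, pmax(0, x))

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "cigame_invalid_parameter")
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "cigame_invalid_parameter")
  }
  invisible(x)
}

# frequencies of a group must form a composition on the simplex
check_composition <- function(frequency, strain_id = NULL, tol = 1e-9,
                              call_name = "composition") {
  if (length(frequency) < 1L || any(!is.finite(frequency))) {
    abort(sprintf("%s: frequencies must be finite and non-empty.", call_name),
          class = "cigame_invalid_composition")
  }
  if (any(frequency <= 0)) {
    abort(sprintf("%s: all strain frequencies must be > 0.", call_name),
          class = "cigame_invalid_composition")
  }
  if (abs(sum(frequency) - 1) > tol) {
    abort(sprintf("%s: frequencies sum to %.10f, not 1.", call_name,
                  sum(frequency)),
          class = "cigame_invalid_composition")
  }
  if (!is.null(strain_id) && anyDuplicated(strain_id)) {
    abort(sprintf("%s: strain ids must be unique.", call_name),
          class = "cigame_invalid_composition")
  }
  invisible(TRUE)
}

# trapezoid weights for a uniform grid on [0, 1]
trapezoid_weights <- function(n) {
  h <- 1 / (n - 1)
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}
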