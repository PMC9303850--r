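test_that("theta matches its closed form and handles degenerate costs", {
  expect_equal(theta(game_params(12, 1)), 11 / 24)
  expect_equal(round(theta(game_params(12, 1)), 2), 0.46)
  expect_equal(theta(game_params(2, 1)), 0.25)
  expect_equal(theta(game_params(1.5, 1.5)), 0)  # b = c: no positive optimum
  expect_equal(theta(game_params(1, 2)), 0)      # b < c
  expect_error(game_params(0, 1), class = "cigame_invalid_parameter")
  expect_error(game_params(12, -1), class = "cigame_invalid_parameter")
})

test_that("theta maximises clonal-group fitness on a fine grid", {
  p <- game_params(12, 1)
  xs <- seq(0, 1, length.out = 2001)
  expect_true(all(player_fitness(theta(p), 1, p) >=
                    player_fitness(xs, 1, p) - 1e-12))
})

test_that("perfect-information optimum: clonal level, Hamilton threshold,
           interior value", {
  p <- game_params(12, 1)
  expect_equal(optimal_investment(1, p), theta(p))
  expect_equal(optimal_investment(0, p), 0)
  # below the Hamilton threshold c/b no investment pays
  expect_equal(optimal_investment(c(0.02, 1 / 12, 0.083), p), c(0, 0, 0))
  expect_equal(optimal_investment(0.5, p), 5 / 12)
  expect_error(optimal_investment(1.2, p), class = "cigame_domain_error")
})

test_that("closed-form optima agree with brute-force fitness maximisation", {
  set.seed(101)
  for (k in 1:250) {
    b <- runif(1, 1.2, 20)
    cc <- runif(1, 0.5, 2)
    r <- runif(1, 0.01, 1)
    D <- runif(1, 0, 0.25)
    p <- game_params(b, cc, D)
    # perfect information
    x_star <- quad_argmax(function(x) (1 + r * b * x) * (1 - cc * x))
    expect_equal(optimal_investment(r, p), x_star, tolerance = 1e-8)
    # with enforcement, many-strain assumption: A_G = r * A
    th <- theta(p)
    a_star <- quad_argmax(function(a) {
      x <- min(1, max(0, a + D * (th - r * a)))
      (1 + r * b * x) * (1 - cc * x)
    })
    a_hat <- optimal_initial_allocation(r, p)
    if (a_hat > 1e-6 && a_hat < 1 - 1e-6) {
      expect_equal(a_hat, a_star, tolerance = 1e-8)
    } else {
      # boundary optimum: fitness at the closed form must match the best found
      f <- function(a) {
        x <- min(1, max(0, a + D * (th - r * a)))
        (1 + r * b * x) * (1 - cc * x)
      }
      expect_gte(f(a_hat) + 1e-10, f(a_star))
    }
  }
})

test_that("investment is nondecreasing in relatedness and bounded by the
           clonal optimum", {
  set.seed(102)
  for (k in 1:50) {
    cc <- runif(1, 0.5, 2)
    b <- cc + runif(1, 0.1, 15)
    p <- game_params(b, cc)
    x <- optimal_investment(seq(0, 1, length.out = 200), p)
    expect_true(all(diff(x) >= -1e-12))
    expect_true(all(x >= 0 & x <= 0.5 * (1 / cc - 1 / b) + 1e-12))
  }
})

test_that("fitness is multiplicative benefit x cost with a warned floor", {
  p <- game_params(12, 1)
  expect_equal(player_fitness(0, 0.7, p), 1)
  expect_equal(player_fitness(theta(p), 1, p), 6.5 * 13 / 24)
  p_cost <- game_params(12, 1.5)
  expect_warning(w <- player_fitness(0.9, 0, p_cost))
  expect_equal(w, 0) # survival exhausted, clipped
})

test_that("enforcement-aware allocation reduces to Eq.-1 behaviour and stays
           consistent at the boundaries", {
  p0 <- game_params(12, 1, D = 0)
  rs <- seq(0.01, 1, length.out = 47)
  expect_equal(optimal_initial_allocation(rs, p0),
               optimal_investment(rs, p0))
  pD <- game_params(12, 1, D = 0.15)
  expect_equal(optimal_initial_allocation(1, pD), theta(pD))
  expect_error(optimal_initial_allocation(1, game_params(2, 1, D = 1)),
               class = "cigame_invalid_parameter")
})

test_that("strains with positive inherent allocation realise the
           perfect-information optimum (algebraic identity)", {
  set.seed(103)
  for (k in 1:50) {
    b <- runif(1, 3, 18); cc <- runif(1, 0.6, 1.9)
    D <- runif(1, 0.01, 0.25); r <- runif(1, 0.05, 1)
    p <- game_params(b, cc, D)
    a <- optimal_initial_allocation(r, p)
    if (a > 1e-9) {
      x <- a + D * (theta(p) - r * a) # many-strain A_G = r * a
      expect_equal(x, optimal_investment(r, p), tolerance = 1e-10)
    }
  }
})

test_that("perception-error SD has the stated shape", {
  err1 <- error_model(e = 0.2, t = 1)
  expect_equal(perceived_sd(0.5, err1), 0.2) # weight is 1 at r = 0.5
  expect_equal(perceived_sd(c(0, 1), err1), c(0, 0))
  err0 <- error_model(e = 0.3, t = 0)
  expect_equal(perceived_sd(c(0, 0.2, 0.5, 1), err0), rep(0.3, 4))
  expect_equal(perceived_sd(0.5, error_model(0.2, 3)), 0.2) # any t
})

test_that("expected investment collapses to the noiseless strategy and
           matches Monte-Carlo integration", {
  p <- game_params(12, 1)
  rs <- c(0.1, 0.3, 0.6, 0.9)
  expect_equal(expected_investment(rs, p, NULL), optimal_investment(rs, p))
  expect_equal(expected_investment(rs, p, error_model(0, 0.5)),
               optimal_investment(rs, p))
  # e -> 0 convergence in sup norm
  tiny <- expected_investment(rs, p, error_model(1e-6, 0))
  expect_lt(max(abs(tiny - optimal_investment(rs, p))), 1e-6)
  # Monte-Carlo cross-check on a handful of configurations
  set.seed(104)
  for (k in 1:3) {
    e <- runif(1, 0.1, 0.6); tt <- runif(1, 0, 1); r <- runif(1, 0.05, 0.95)
    err <- error_model(e, tt)
    sdv <- perceived_sd(r, err)
    draws <- optimal_investment(rtruncnorm01(2e5, r, sdv), p)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(expected_investment(r, p, err) - mean(draws)), 4 * se)
  }
  # reflected tails stay within the strategy's range
  refl <- expected_investment(rs, p, error_model(0.3, 0.5), tails = "reflect")
  expect_true(all(refl >= 0 & refl <= theta(p)))
})

test_that("transdifferentiation feedback pushes groups towards the optimum", {
  p <- game_params(12, 1, D = 0.15)
  comp <- tibble::tibble(strain_id = c("a", "b", "c"),
                         frequency = c(0.2, 0.3, 0.5))
  # equilibrium: group allocating theta is untouched
  at_theta <- realized_investment(comp, rep(theta(p), 3), p)
  expect_equal(at_theta$investment, rep(theta(p), 3))
  # pure enforcement floor
  floor <- realized_investment(comp, rep(0, 3), p)
  expect_equal(floor$investment, rep(p$D * theta(p), 3))
  expect_equal(attr(floor, "x_G"), p$D * theta(p))
  # realised collective investment never falls below D * theta
  set.seed(105)
  for (k in 1:100) {
    n <- sample(2:6, 1)
    w <- runif(n); w <- w / sum(w)
    cmp <- tibble::tibble(strain_id = as.character(seq_len(n)), frequency = w)
    a <- runif(n) * theta(p)
    prof <- realized_investment(cmp, a, p)
    expect_gte(attr(prof, "x_G"), p$D * theta(p) - 1e-12)
  }
})

test_that("collective investment aggregates frequency-weighted strategies", {
  p <- game_params(12, 1)
  one <- tibble::tibble(strain_id = "s", frequency = 1)
  expect_equal(collective_investment(one, function(r) optimal_investment(r, p)),
               theta(p))
  half <- tibble::tibble(strain_id = c("a", "b"), frequency = c(0.5, 0.5))
  expect_equal(collective_investment(half,
                                     function(r) optimal_investment(r, p)),
               5 / 12)
  twenty <- tibble::tibble(strain_id = sprintf("s%02d", 1:20),
                           frequency = rep(0.05, 20))
  expect_equal(collective_investment(twenty,
                                     function(r) optimal_investment(r, p)),
               0) # all below c/b = 1/12
  bad <- tibble::tibble(strain_id = c("a", "b"), frequency = c(0.5, 0.4))
  expect_error(collective_investment(bad, function(r) r),
               class = "cigame_invalid_composition")
})

test_that("predict_collective composes strategy, error and enforcement", {
  p <- game_params(12, 1)
  clonal <- tibble::tibble(strain_id = "s", frequency = 1)
  expect_equal(predict_collective(clonal, p), theta(p))
  # enforcement floor for groups entirely below the allocation threshold
  pD <- game_params(12, 1, D = 0.15)
  twenty <- tibble::tibble(strain_id = sprintf("s%02d", 1:20),
                           frequency = rep(0.05, 20))
  expect_equal(predict_collective(twenty, pD, with_transdiff = TRUE),
               pD$D * theta(pD))
  # hand-composed three-strain prediction, perfect information, no D
  comp <- tibble::tibble(strain_id = c("a", "b", "c"),
                         frequency = c(0.2, 0.3, 0.5))
  by_hand <- sum(comp$frequency * optimal_investment(comp$frequency, p))
  expect_equal(predict_collective(comp, p), by_hand)
})
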