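th_true <- theta(game_params(12, 1))

small_cfg <- fit_config(b_grid = c(8, 12, 15), c_grid = c(1, 1.4, 1.8),
                        e_grid = c(0, 0.2, 0.4), t_grid = c(0.25, 0.5, 0.75))

test_that("the grid search reproduces an independent brute-force objective", {
  d3 <- design_three_strain()
  spec <- simulation_spec(D = 0, noise_cv = 0.05, n_rep = 4, map = "linear",
                          seed = 31)
  data <- make_fit_data(d3, spec, th_true)
  fit <- fit_investment_game(data, small_cfg)

  # brute force over the same 3^4 grid using only exported primitives
  comps <- split(data, data$strain_set_id)
  obs <- vapply(comps, function(d) d$s_mean[1], numeric(1))
  grid <- tidyr::expand_grid(b = small_cfg$b_grid, c = small_cfg$c_grid,
                             e = small_cfg$e_grid, t = small_cfg$t_grid)
  rss_all <- vapply(seq_len(nrow(grid)), function(i) {
    p <- game_params(grid$b[i], grid$c[i])
    err <- if (grid$e[i] > 0) error_model(grid$e[i], grid$t[i]) else NULL
    pred <- vapply(comps, function(d) {
      x_i <- expected_investment(d$frequency, p, err)
      x_g <- sum(d$frequency * x_i)
      model_to_empirical(x_g / theta(p), theta(p))
    }, numeric(1))
    sum((obs - pred)^2)
  }, numeric(1))

  expect_equal(fit$rss, min(rss_all), tolerance = 1e-10)
  best <- grid[which.min(rss_all), ]
  expect_equal(fit$params$b, best$b)
  expect_equal(fit$params$c, best$c)
  expect_equal(fit$params$e, best$e)
  expect_equal(fit$params$t, best$t)
})

test_that("noiseless data generated at a grid point is recovered exactly", {
  d3 <- design_three_strain()
  spec <- simulation_spec(b = 12, c = 1, D = 0, e = 0.2, t = 0.5,
                          noise_cv = 0, n_rep = 1, map = "linear", seed = 32)
  data <- make_fit_data(d3, spec, th_true)
  fit <- fit_investment_game(data, small_cfg)
  expect_equal(fit$params$b, 12)
  expect_equal(fit$params$c, 1)
  expect_equal(fit$params$e, 0.2)
  expect_equal(fit$params$t, 0.5)
  expect_lt(fit$rss, 1e-16)
})

test_that("exact ties are reported and broken towards the smallest
           parameters", {
  d3 <- design_three_strain()
  spec <- simulation_spec(b = 12, c = 1, D = 0, e = 0, noise_cv = 0,
                          n_rep = 1, map = "linear", seed = 33)
  data <- make_fit_data(d3, spec, th_true)
  # with e = 0 the t grid is irrelevant: every t value ties
  cfg <- fit_config(b_grid = c(10, 12), c_grid = 1, e_grid = 0,
                    t_grid = c(0.3, 0.6))
  fit <- fit_investment_game(data, cfg)
  expect_equal(nrow(fit$ties), 2)
  expect_equal(fit$params$t, 0.3)
  expect_equal(fit$params$b, 12)
})

test_that("the D search recovers generating enforcement on noiseless
           N-strain data, including zero", {
  dn <- design_nstrain()
  fixed <- list(b = 12, c = 1, e = 0.2, t = 0.5)
  for (d_true in c(0, 0.15)) {
    spec <- simulation_spec(b = 12, c = 1, D = d_true, e = 0.2, t = 0.5,
                            noise_cv = 0, n_rep = 1, map = "linear",
                            seed = 34)
    data <- make_fit_data(dn, spec, th_true)
    fit_d <- fit_transdifferentiation(data, fixed, fit_config())
    expect_equal(fit_d$params$D, d_true)
    expect_lt(fit_d$rss, 1e-16)
  }
})

test_that("freeing D never increases the residual sum of squares", {
  dn <- design_nstrain()
  spec <- simulation_spec(D = 0.15, seed = 35)
  data <- make_fit_data(dn, spec, th_true)
  fixed <- list(b = 12, c = 1, e = 0.2, t = 0.5)
  free_d <- fit_transdifferentiation(data, fixed, fit_config())
  no_d <- fit_transdifferentiation(data, fixed,
                                   fit_config(D_grid = 0))
  expect_lte(free_d$rss, no_d$rss)
  expect_gte(glance(free_d)$r_squared, glance(no_d)$r_squared)
})

test_that("the nested-model F statistic follows its definition", {
  stub <- function(rss) structure(list(rss = rss, n = 60), class = "cig_fit")
  same <- model_compare_F(stub(1.3), stub(1.3), n = 60)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  hand <- model_compare_F(stub(2), stub(1), n = 60)
  expect_equal(hand$statistic, (1 / 2) / (1 / 56)) # = 28
  expect_equal(hand$df1, 2)
  expect_equal(hand$df2, 56)
  perfect <- model_compare_F(stub(2), stub(0), n = 60)
  expect_true(is.infinite(perfect$statistic))
  expect_true(perfect$perfect_fit)
  expect_error(model_compare_F(stub(2), stub(1), n = 4),
               class = "cigame_df_error")
})

test_that("goodness of fit covers the exact, anti-correlated and degenerate
           cases", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$pearson_r, 1)
  expect_equal(g$t_statistic, 0)
  g2 <- goodness_of_fit(c(1, 2, 3), c(3, 2, 1))
  expect_equal(g2$pearson_r, -1)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)),
               class = "cigame_data_error")
})

test_that("bootstrap intervals are deterministic, contain the estimate and
           degenerate with zero SEs", {
  d3 <- design_three_strain()
  spec <- simulation_spec(D = 0, noise_cv = 0.05, n_rep = 5, map = "linear",
                          seed = 36)
  data <- make_fit_data(d3, spec, th_true)
  fit <- fit_investment_game(data, small_cfg)
  boot1 <- bootstrap_ci(fit, n_boot = 30, seed = 1)
  boot2 <- bootstrap_ci(fit, n_boot = 30, seed = 1)
  expect_identical(boot1$ci, boot2$ci)
  expect_true(all(boot1$ci$lower <= boot1$ci$estimate + 1e-12))
  expect_true(all(boot1$ci$upper >= boot1$ci$estimate - 1e-12))
  # zero SEs: every resample is the data itself
  data0 <- data
  data0$s_se <- 0
  fit0 <- fit_investment_game(data0, small_cfg)
  boot0 <- bootstrap_ci(fit0, n_boot = 25, seed = 2)
  expect_equal(boot0$ci$lower, boot0$ci$estimate)
  expect_equal(boot0$ci$upper, boot0$ci$estimate)
  expect_warning(bootstrap_ci(fit, n_boot = 10, seed = 3), "20")
})

test_that("tidy and glance summarise fits in broom style", {
  d3 <- design_three_strain()
  spec <- simulation_spec(D = 0, noise_cv = 0, n_rep = 1, map = "linear",
                          seed = 37)
  data <- make_fit_data(d3, spec, th_true)
  fit <- fit_investment_game(data, small_cfg)
  td <- tidy(fit)
  expect_true(all(c("b", "c", "e", "t", "theta") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_true(gl$r_squared <= 1)
})
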