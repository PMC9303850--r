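base_cells <- function(ecma, pspa, replicate_id = "R1",
                       condition = "clonal") {
  tibble::tibble(
    cell_id = paste0("c", seq_along(ecma)),
    replicate_id = replicate_id,
    condition = condition,
    ecmA = ecma, pspA = pspa
  )
}

test_that("censoring keeps any cell clearing the threshold on one gene", {
  cells <- base_cells(c(16, 17, 100, 0), c(16, 0, 50, 40))
  cen <- censor_cells(cells)
  expect_equal(cen$retained, c(FALSE, TRUE, TRUE, TRUE))
  strict <- censor_cells(cells, rule = "either_below")
  expect_equal(strict$retained, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(censor_cells(base_cells(-1, 5)), class = "cigame_data_error")
})

test_that("pspA normalisation equalises gene means within each replicate", {
  cells <- base_cells(c(20, 40), c(40, 80))
  norm <- normalize_pspa(censor_cells(cells))
  expect_equal(norm$pspA_norm, c(20, 40)) # factor mean(ecmA)/mean(pspA) = 0.5
  expect_equal(mean(norm$pspA_norm), mean(norm$ecmA))
  # unit factor leaves counts unchanged; renormalising is idempotent
  cells_eq <- base_cells(c(30, 50), c(50, 30))
  norm_eq <- normalize_pspa(censor_cells(cells_eq))
  expect_equal(norm_eq$pspA_norm, cells_eq$pspA)
  # replicates are normalised independently
  two_rep <- dplyr::bind_rows(
    base_cells(c(20, 40), c(40, 80), replicate_id = "R1"),
    base_cells(c(20, 40), c(20, 40), replicate_id = "R2")
  )
  norm2 <- normalize_pspa(censor_cells(two_rep))
  expect_equal(norm2$pspA_norm[norm2$replicate_id == "R1"], c(20, 40))
  expect_equal(norm2$pspA_norm[norm2$replicate_id == "R2"], c(20, 40))
})

test_that("fate thresholds are inclusive at both boundaries", {
  expect_equal(as.character(classify_fate(c(0.30, 0.70, 0.5, 0, 1))),
               c("prestalk", "prespore", "transdifferentiated",
                 "prestalk", "prespore"))
})

test_that("classification partitions retained cells and respects censoring", {
  cells <- simulate_smfish(n_cells = c(clonal = 400, chimeric = 400),
                           seed = 5)
  cl <- classify_cells(cells)
  expect_equal(nrow(cl), 800)
  expect_true(all(cl$fate[!cl$retained] == "censored"))
  counts <- table(cl$fate[cl$retained])
  expect_equal(sum(counts[c("prestalk", "transdifferentiated", "prespore")]),
               sum(cl$retained))
})

test_that("a clonal population generated without transdifferentiation is
           classified as such", {
  cells <- simulate_smfish(
    n_cells = c(clonal = 2000),
    clonal_props = c(prestalk = 0.45, prespore = 0.55,
                     transdifferentiated = 0),
    seed = 6
  )
  cl <- classify_cells(cells)
  pr <- fate_proportions(cl)
  td <- pr$proportion[pr$fate == "transdifferentiated"]
  expect_lt(td, 0.02)
})

test_that("condition comparison matches the textbook 2x2 chi-square", {
  cells <- cells_from_counts(c(10, 0, 90), c(30, 0, 70))
  res <- compare_conditions(cells, "prestalk")
  expect_equal(res$statistic, chisq_2x2(10, 90, 30, 70))
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1)
  # doubling all counts doubles the statistic
  cells2 <- cells_from_counts(c(20, 0, 180), c(60, 0, 140))
  expect_equal(compare_conditions(cells2, "prestalk")$statistic, 25)
  # identical proportions give a null statistic
  same <- cells_from_counts(c(10, 5, 85), c(20, 10, 170))
  expect_equal(compare_conditions(same, "prestalk")$statistic, 0)
  only_clonal <- cells_from_counts(c(5, 5, 5), c(0, 0, 0))
  expect_error(compare_conditions(only_clonal, "prestalk"),
               class = "cigame_data_error")
})

test_that("replicate homogeneity matches the expected-count chi-square", {
  build <- function(counts, rep_id) tibble::tibble(
    cell_id = paste0(rep_id, seq_len(sum(counts))),
    replicate_id = rep_id, condition = "clonal",
    fate = factor(rep(c("prestalk", "transdifferentiated", "prespore"),
                      counts),
                  levels = c("prestalk", "transdifferentiated", "prespore",
                             "censored"))
  )
  cells <- dplyr::bind_rows(build(c(20, 10, 10), "R1"),
                            build(c(10, 10, 20), "R2"))
  res <- replicate_homogeneity(cells, "clonal")
  tab <- rbind(c(20, 10, 10), c(10, 10, 20))
  expect_equal(res$statistic, chisq_expected(tab))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 2)
  same <- dplyr::bind_rows(build(c(10, 10, 10), "R1"),
                           build(c(10, 10, 10), "R2"))
  res0 <- replicate_homogeneity(same, "clonal")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})
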