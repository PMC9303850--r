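# Independent oracles and fixtures built in code.

# Brute-force maximiser on [lo, hi]: dense grid plus one exact parabolic
# refinement step. For quadratic objectives (as the game's fitness is in the
# investment) the refinement is exact, so this reaches ~machine precision
# without using any closed form.
quad_argmax <- function(f, lo = 0, hi = 1, n = 4001) {
  g <- seq(lo, hi, length.out = n)
  fx <- vapply(g, f, numeric(1))
  i <- which.max(fx)
  if (i == 1L || i == n) return(g[i])
  h <- g[2] - g[1]
  denom <- fx[i + 1] - 2 * fx[i] + fx[i - 1]
  if (denom >= 0) return(g[i]) # flat or degenerate
  x <- g[i] - h / 2 * (fx[i + 1] - fx[i - 1]) / denom
  min(hi, max(lo, x))
}

# Textbook Pearson chi-square for a 2x2 table of counts (no correction)
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Pearson chi-square for any contingency table via expected counts
chisq_expected <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# simulate -> estimate -> summarise -> long fit table
make_fit_data <- function(design, spec, th) {
  sim <- simulate_assay(design, spec)
  summ <- suppressWarnings(
    summarize_investment(estimate_investment(sim, th))
  )
  dplyr::left_join(
    design[, c("strain_set_id", "strain_id", "frequency")],
    summ[, c("strain_set_id", "s_mean", "s_se")],
    by = "strain_set_id"
  )
}

# truncated-normal draws on [0, 1] by inverse-CDF
rtruncnorm01 <- function(n, mean, sd) {
  u <- runif(n, pnorm(0, mean, sd), pnorm(1, mean, sd))
  mean + sd * qnorm(u)
}

# a cells tibble with prescribed fate counts, for the categorical tests
cells_from_counts <- function(counts_clonal, counts_chimeric) {
  fates <- c("prestalk", "transdifferentiated", "prespore")
  build <- function(counts, cond) {
    tibble::tibble(
      cell_id = paste0(cond, seq_len(sum(counts))),
      replicate_id = "R1",
      condition = cond,
      fate = factor(rep(fates, counts),
                    levels = c(fates, "censored"))
    )
  }
  dplyr::bind_rows(build(counts_clonal, "clonal"),
                   build(counts_chimeric, "chimeric"))
}
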