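# Synthetic assay-shaped data with the statistical structure the analysis
# assumes: clonal and chimeric spore totals generated from the game model
# with multiplicative noise, smFISH dot counts for the three cell-fate
# classes, and collapse proportions tied to collective investment.

#' Specification for the spore-assay simulator
#'
#' The generator's defaults are the study conditions: best-fit game
#' parameters `b = 12`, `c = 1`, enforcement `D = 0.15`, moderate perception
#' error (`e = 0.2`, `t = 0.5`), 21 replicates per composition, clonal spore
#' totals around 10^6 with a between-strain CV of 0.3, and multiplicative
#' log-normal measurement noise with CV 0.03 (counting-dominated error for
#' hemocytometer totals of ~10^3 counted spores) on the relative-production
#' scale.
#'
#' @param b,c,D,e,t True game and error parameters (see [game_params()] and
#'   [error_model()]).
#' @param clonal_mean Mean clonal spore total per strain.
#' @param clonal_cv Between-strain coefficient of variation of clonal totals.
#' @param noise_cv CV of the multiplicative log-normal measurement noise on
#'   chimeric totals (0 for noiseless data).
#' @param n_rep Replicates per composition.
#' @param map Empirical-scale map used to convert model investment into
#'   chimeric spore totals: `"exact"` (the hyperbolic inverse of the
#'   investment scale, default) or `"linear"`.
#' @param strain_theta_sd SD of an optional per-strain perturbation of
#'   realised investment (off by default; set > 0 to emulate strains varying
#'   in their clonal investment level).
#' @param seed Integer seed recorded in the spec and used by
#'   [simulate_assay()].
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(b = 12, c = 1, D = 0.15, e = 0.2, t = 0.5,
                            clonal_mean = 1e6, clonal_cv = 0.3,
                            noise_cv = 0.03, n_rep = 21,
                            map = c("exact", "linear"),
                            strain_theta_sd = 0, seed = 1) {
  map <- match.arg(map)
  stop_if_not_number(clonal_mean, "clonal_mean", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(clonal_cv, "clonal_cv", lower = 0)
  stop_if_not_number(noise_cv, "noise_cv", lower = 0)
  stop_if_not_number(strain_theta_sd, "strain_theta_sd", lower = 0)
  if (n_rep < 1) abort("`n_rep` must be >= 1.", class = "cigame_config_error")
  structure(list(
    params = game_params(b, c, D),
    err = if (e > 0) error_model(e, t) else NULL,
    clonal_mean = clonal_mean, clonal_cv = clonal_cv, noise_cv = noise_cv,
    n_rep = as.integer(n_rep), map = map,
    strain_theta_sd = strain_theta_sd, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# log-normal draws with a given mean and CV (CV 0 gives the mean exactly)
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Three-strain transect design
#'
#' Enumerates the composition transects used for three-strain groups: each
#' strain in turn is held at a frequency of 0.2 or 0.8 while the remaining
#' mass is split between the other two strains across 10 combinations (the
#' split grid `k/11`, `k = 1..10`, which never collides with the fixed
#' levels). This yields 60 unique labelled compositions per triplet.
#'
#' @param strains Character vector of 3 distinct strain ids.
#' @param levels Fixed focal frequencies (default `c(0.2, 0.8)`).
#' @param splits Fractions used to divide the non-focal mass (default
#'   `1:10 / 11`).
#' @return A long tibble with columns `strain_set_id`, `strain_id`,
#'   `frequency` (three rows per composition).
#' @examples
#' dplyr::n_distinct(design_three_strain()$strain_set_id) # 60
#' @export
design_three_strain <- function(strains = c("S01", "S02", "S03"),
                                levels = c(0.2, 0.8), splits = 1:10 / 11) {
  if (length(strains) != 3 || anyDuplicated(strains)) {
    abort("`strains` must be 3 distinct ids.", class = "cigame_data_error")
  }
  grid <- tidyr::expand_grid(focal = strains, q = levels,
                             k = seq_along(splits))
  purrr::pmap_dfr(grid, function(focal, q, k) {
    others <- setdiff(strains, focal)
    split <- splits[k]
    tibble(
      strain_set_id = sprintf("%s_q%03d_k%02d", focal, round(q * 100), k),
      strain_id = c(focal, others),
      frequency = c(q, (1 - q) * split, (1 - q) * (1 - split))
    )
  })
}

#' Equal-frequency N-strain designs
#'
#' One composition per group size `N`, with all strains at frequency `1/N`
#' (so every strain's relatedness to the group is `1/N`). The default sizes
#' are 4--10, 15 and 20.
#'
#' @param sizes Integer group sizes (each >= 2).
#' @param panel Strain id panel to draw members from (recycled prefix).
#' @return A long tibble with columns `strain_set_id`, `strain_id`,
#'   `frequency`, `group_size`.
#' @export
design_nstrain <- function(sizes = c(4:10, 15, 20),
                           panel = sprintf("S%02d", 1:20)) {
  if (any(sizes < 2)) {
    abort("all group sizes must be >= 2.", class = "cigame_data_error")
  }
  if (max(sizes) > length(panel)) {
    abort("strain panel smaller than the largest group size.",
          class = "cigame_data_error")
  }
  purrr::map_dfr(sizes, function(n) {
    tibble(
      strain_set_id = sprintf("N%02d", n),
      strain_id = panel[seq_len(n)],
      frequency = rep(1 / n, n),
      group_size = as.integer(n)
    )
  })
}

#' Simulate a spore-count assay
#'
#' Draws clonal spore totals per strain, computes each composition's
#' collective investment under the true game (with enforcement when the
#' spec's `D > 0`), converts investment to a chimeric spore total on the
#' chosen empirical map, and applies multiplicative log-normal measurement
#' noise (parameterised on the relative-production scale, so replicate means
#' of `S_G` are unbiased for the generating value). The
#' output uses the same long schema the readers and [estimate_investment()]
#' consume, so noiseless simulation followed by estimation inverts exactly on
#' the `"exact"` map.
#'
#' @param design A design table from [design_three_strain()] or
#'   [design_nstrain()] (columns `strain_set_id`, `strain_id`, `frequency`).
#' @param spec A [simulation_spec()].
#' @return A tibble with columns `strain_set_id`, `replicate_id`,
#'   `strain_id`, `frequency`, `clonal_spores`, `chimeric_spores`.
#' @export
simulate_assay <- function(design, spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  params <- spec$params
  th <- theta(params)
  strains <- sort(unique(design$strain_id))
  clonal <- setNames(rlnorm_cv(length(strains), spec$clonal_mean,
                               spec$clonal_cv), strains)

  comps <- split(design, design$strain_set_id)
  purrr::map_dfr(comps, function(d) {
    check_composition(d$frequency, d$strain_id,
                      call_name = paste0("design ", d$strain_set_id[1]))
    comp <- tibble(strain_id = d$strain_id, frequency = d$frequency)
    x_g <- if (spec$strain_theta_sd > 0) {
      strat <- if (params$D > 0) {
        function(rho) optimal_initial_allocation(rho, params)
      } else {
        function(rho) optimal_investment(rho, params)
      }
      base <- expected_investment(comp$frequency, params, spec$err,
                                  strategy = strat)
      if (params$D > 0) {
        base <- realized_investment(comp, base, params)$investment
      }
      x_i <- clip01(base + rnorm(nrow(comp), 0, spec$strain_theta_sd))
      sum(comp$frequency * x_i)
    } else {
      predict_collective(comp, params, spec$err,
                         with_transdiff = params$D > 0)
    }
    e_g <- sum(comp$frequency * clonal[comp$strain_id])
    s_true <- model_to_empirical(clip01(x_g / th), th,
                                 map = if (spec$map == "exact") "exact"
                                       else "linear")
    t_true <- e_g / s_true
    # noise enters on the relative-production scale (S = E/T), so that the
    # replicate mean of S is an unbiased estimate of the generating value
    t_obs <- t_true / rlnorm_cv(spec$n_rep, 1, spec$noise_cv)
    tidyr::expand_grid(replicate_id = sprintf("r%02d", seq_len(spec$n_rep)),
                       comp) |>
      dplyr::mutate(
        strain_set_id = d$strain_set_id[1],
        clonal_spores = clonal[.data$strain_id],
        chimeric_spores = t_obs[match(.data$replicate_id,
                                      sprintf("r%02d", seq_len(spec$n_rep)))]
      ) |>
      dplyr::select("strain_set_id", "replicate_id", "strain_id",
                    "frequency", "clonal_spores", "chimeric_spores")
  })
}

#' Simulate smFISH dot counts per cell
#'
#' Draws each cell's fate class, then negative-binomial transcript counts
#' with class-dependent means: prestalk cells express the prestalk marker
#' ecmA highly and pspA weakly, prespore cells the converse, and
#' transdifferentiating cells intermediate levels of both (the mixed
#' signature). A small fraction of cells is generated with both genes at low
#' counts to exercise the censoring rule. Defaults emulate the observed fate
#' proportions: clones ~43% prestalk with ~4% transdifferentiated, chimeras
#' ~26% prestalk with ~29% transdifferentiated.
#'
#' @param n_cells Named vector of cell counts per condition,
#'   `c(clonal = ..., chimeric = ...)` (a condition may be omitted).
#' @param clonal_props,chimeric_props Fate-class probabilities (prestalk,
#'   prespore, transdifferentiated), each summing to 1.
#' @param mean_major,mean_minor,mean_transdiff NB means for the dominant
#'   marker, the suppressed marker, and both markers in transdifferentiating
#'   cells.
#' @param mean_low NB mean of both genes in censorable low-signal cells.
#' @param low_fraction Fraction of cells generated as low-signal.
#' @param nb_size NB dispersion (shared).
#' @param n_replicates Number of replicates the cells are spread across.
#' @param seed Integer seed.
#' @return A tibble with columns `cell_id`, `replicate_id`, `condition`,
#'   `ecmA`, `pspA` and the generating `true_class`.
#' @export
simulate_smfish <- function(n_cells = c(clonal = 300, chimeric = 300),
                            clonal_props = c(prestalk = 0.43,
                                             prespore = 0.53,
                                             transdifferentiated = 0.04),
                            chimeric_props = c(prestalk = 0.26,
                                               prespore = 0.45,
                                               transdifferentiated = 0.29),
                            mean_major = 120, mean_minor = 4,
                            mean_transdiff = 60, mean_low = 6,
                            low_fraction = 0.08, nb_size = 40,
                            n_replicates = 2, seed = 1) {
  props <- list(clonal = clonal_props, chimeric = chimeric_props)
  for (p in props) {
    if (abs(sum(p) - 1) > 1e-9) {
      abort("fate-class proportions must sum to 1.",
            class = "cigame_config_error")
    }
  }
  set.seed(seed)
  purrr::map_dfr(names(n_cells), function(cond) {
    n <- n_cells[[cond]]
    if (n < 1) return(tibble())
    pr <- props[[cond]][c("prestalk", "prespore", "transdifferentiated")]
    is_low <- runif(n) < low_fraction
    cls <- ifelse(is_low, "low",
                  sample(names(pr), n, replace = TRUE, prob = pr))
    ecma <- numeric(n); pspa <- numeric(n)
    for (k in seq_len(n)) {
      mu <- switch(cls[k],
        prestalk = c(mean_major, mean_minor),
        prespore = c(mean_minor, mean_major),
        transdifferentiated = c(mean_transdiff, mean_transdiff),
        low = c(mean_low, mean_low)
      )
      ecma[k] <- rnbinom(1, mu = mu[1], size = nb_size)
      pspa[k] <- rnbinom(1, mu = mu[2], size = nb_size)
    }
    tibble(
      cell_id = sprintf("%s_c%05d", cond, seq_len(n)),
      replicate_id = sprintf("R%d", 1 + (seq_len(n) - 1) %% n_replicates),
      condition = cond,
      ecmA = as.integer(ecma),
      pspA = as.integer(pspa),
      true_class = cls
    )
  })
}

#' Simulate fruiting-body collapse proportions
#'
#' Collapse probability is a logistic decreasing function of collective
#' investment expressed as a proportion of the optimum:
#' `p = plogis(intercept + slope * y)`. Each replicate well draws a binomial
#' count of collapsed fruiting bodies. Defaults place clonal-level investment
#' near a 5% collapse floor and the low-relatedness plateau near 60%.
#'
#' @param investment A data frame with columns `group_size` and `y`
#'   (investment as a proportion of the optimum, in `[0, 1]`).
#' @param n_bodies Fruiting bodies scored per well.
#' @param n_rep Replicate wells per group size.
#' @param n_comps Distinct strain combinations per group size; replicate
#'   wells cycle over them (so each combination is measured repeatedly,
#'   which identifies the combination random effect).
#' @param intercept,slope Logistic link parameters (slope < 0 makes collapse
#'   fall as investment rises).
#' @param seed Integer seed.
#' @return A tibble of collapse records: `group_size`, `relatedness`,
#'   `composition_id`, `replicate_id`, `prop_collapsed`.
#' @export
simulate_collapse <- function(investment, n_bodies = 60, n_rep = 11,
                              n_comps = 4, intercept = 1, slope = -4,
                              seed = 1) {
  if (!all(c("group_size", "y") %in% names(investment))) {
    abort("need columns group_size and y.", class = "cigame_data_error")
  }
  if (any(investment$y < 0 | investment$y > 1)) {
    abort("`y` must lie in [0, 1].", class = "cigame_domain_error")
  }
  set.seed(seed)
  purrr::pmap_dfr(investment[, c("group_size", "y")],
                  function(group_size, y) {
    p <- plogis(intercept + slope * y)
    tibble(
      group_size = as.integer(group_size),
      relatedness = 1 / group_size,
      composition_id = sprintf("N%02d_c%02d", group_size,
                               1 + (seq_len(n_rep) - 1) %% n_comps),
      replicate_id = sprintf("r%02d", seq_len(n_rep)),
      prop_collapsed = rbinom(n_rep, n_bodies, p) / n_bodies
    )
  })
}
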