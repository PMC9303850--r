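# Cell-fate classification from smFISH transcript (dot) counts of the
# prestalk marker ecmA and the prespore marker pspA.

check_cell_table <- function(cells) {
  required <- c("cell_id", "replicate_id", "condition", "ecmA", "pspA")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  if (any(cells$ecmA < 0) || any(cells$pspA < 0) ||
      any(!is.finite(cells$ecmA)) || any(!is.finite(cells$pspA))) {
    abort("dot counts must be nonnegative and finite.",
          class = "cigame_data_error")
  }
  invisible(cells)
}

#' Censor low-signal cells
#'
#' Cells with fewer than `threshold` dots are excluded because low counts give
#' ambiguous fate assignments. The default reading (`rule = "both_below"`)
#' drops a cell only when *both* genes fall below the threshold: a committed
#' prespore cell legitimately has near-zero ecmA, so requiring both genes to
#' clear the threshold (`rule = "either_below"`, also provided) would censor
#' most committed cells.
#'
#' @param cells A data frame with columns `cell_id`, `replicate_id`,
#'   `condition`, `ecmA`, `pspA`.
#' @param threshold Minimum dot count (default 17; a cell with exactly 17 dots
#'   on one gene is retained).
#' @param rule `"both_below"` (default) or `"either_below"`.
#' @return The input with a logical `retained` column added.
#' @export
censor_cells <- function(cells, threshold = 17,
                         rule = c("both_below", "either_below")) {
  rule <- match.arg(rule)
  check_cell_table(cells)
  cells <- as_tibble(cells)
  cells$retained <- if (rule == "both_below") {
    cells$ecmA >= threshold | cells$pspA >= threshold
  } else {
    cells$ecmA >= threshold & cells$pspA >= threshold
  }
  cells
}

#' Normalise pspA counts to the ecmA scale
#'
#' Within each replicate, multiplies the pspA counts by the ratio of the ecmA
#' mean to the pspA mean over the retained cells, so that the two genes share
#' a common scale (the post-normalisation pspA mean equals the ecmA mean).
#' Replicates are normalised independently to absorb between-experiment
#' differences in hybridisation efficiency. Censoring must precede
#' normalisation; cells without a `retained` column are all treated as
#' retained.
#'
#' @inheritParams censor_cells
#' @return The input with a `pspA_norm` column added (`NA` for censored
#'   cells).
#' @export
normalize_pspa <- function(cells) {
  check_cell_table(cells)
  cells <- as_tibble(cells)
  if (!"retained" %in% names(cells)) cells$retained <- TRUE
  cells |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(d, key) {
      kept <- d[d$retained, ]
      if (nrow(kept) == 0) {
        abort(sprintf("replicate %s: no retained cells to normalise.",
                      key$replicate_id), class = "cigame_data_error")
      }
      if (mean(kept$pspA) == 0) {
        abort(sprintf("replicate %s: mean pspA count is 0.",
                      key$replicate_id), class = "cigame_data_error")
      }
      d$pspA_norm <- ifelse(d$retained,
                            d$pspA * mean(kept$ecmA) / mean(kept$pspA),
                            NA_real_)
      d
    }) |>
    dplyr::ungroup()
}

fate_levels <- c("prestalk", "transdifferentiated", "prespore", "censored")

#' Classify cell fate from the pspA index
#'
#' The pspA index is `pspA_norm / (ecmA + pspA_norm)`, the proportion of a
#' cell's (normalised) signal that comes from the prespore marker. Cells with
#' index <= `prestalk_max` are prestalk, >= `prespore_min` are prespore
#' (boundaries inclusive), and cells in between carry the mixed signature of
#' transdifferentiation.
#'
#' @param index Numeric pspA index values in `[0, 1]`.
#' @param prestalk_max,prespore_min Classification thresholds (defaults 0.3
#'   and 0.7).
#' @return A factor with levels prestalk, transdifferentiated, prespore.
#' @export
classify_fate <- function(index, prestalk_max = 0.3, prespore_min = 0.7) {
  fate <- ifelse(index <= prestalk_max, "prestalk",
                 ifelse(index >= prespore_min, "prespore",
                        "transdifferentiated"))
  factor(fate, levels = fate_levels[1:3])
}

#' Full smFISH classification pipeline
#'
#' Censors low-signal cells, normalises pspA within replicates, computes the
#' pspA index, and assigns fates. Censored cells carry no fate call.
#'
#' @inheritParams censor_cells
#' @inheritParams classify_fate
#' @return The input tibble with `retained`, `pspA_norm`, `pspA_index` and
#'   `fate` columns added; `fate` is a factor with an explicit `censored`
#'   level.
#' @examples
#' cells <- simulate_smfish(n_cells = c(clonal = 100, chimeric = 100), seed = 1)
#' classify_cells(cells) |> dplyr::count(condition, fate)
#' @export
classify_cells <- function(cells, threshold = 17,
                           rule = c("both_below", "either_below"),
                           prestalk_max = 0.3, prespore_min = 0.7) {
  rule <- match.arg(rule)
  out <- censor_cells(cells, threshold, rule) |>
    normalize_pspa()
  out$pspA_index <- ifelse(out$retained & (out$ecmA + out$pspA_norm) > 0,
                           out$pspA_norm / (out$ecmA + out$pspA_norm),
                           NA_real_)
  fate <- as.character(classify_fate(out$pspA_index, prestalk_max,
                                     prespore_min))
  fate[!out$retained | is.na(out$pspA_index)] <- "censored"
  out$fate <- factor(fate, levels = fate_levels)
  out
}

#' Compare a fate category between clonal and chimeric conditions
#'
#' Pearson chi-square test (1 df, no continuity correction by default) of the
#' 2x2 table (in category vs not) by (clonal vs chimeric), over classified
#' (non-censored) cells.
#'
#' @param cells Output of [classify_cells()] (needs `condition` and `fate`).
#' @param category One of `"prestalk"`, `"prespore"`,
#'   `"transdifferentiated"`.
#' @param correct Apply Yates continuity correction (default `FALSE`; counts
#'   in this assay are large).
#' @return A one-row tibble with the proportions per condition, statistic, df
#'   and p-value.
#' @export
compare_conditions <- function(cells, category, correct = FALSE) {
  category <- match.arg(category, fate_levels[1:3])
  kept <- cells[cells$fate != "censored", ]
  conds <- unique(kept$condition)
  if (!all(c("clonal", "chimeric") %in% conds)) {
    abort("both clonal and chimeric cells are required.",
          class = "cigame_data_error")
  }
  tab <- table(in_category = kept$fate == category,
               condition = factor(kept$condition,
                                  levels = c("clonal", "chimeric")))
  test <- suppressWarnings(chisq.test(tab, correct = correct))
  prop <- prop.table(tab, margin = 2)["TRUE", ]
  tibble(category = category,
         prop_clonal = unname(prop["clonal"]),
         prop_chimeric = unname(prop["chimeric"]),
         statistic = unname(test$statistic),
         df = unname(test$parameter),
         p_value = test$p.value)
}

#' Homogeneity of fate proportions across replicates
#'
#' Chi-square contingency test of the replicate-by-fate table (3 fate
#' categories) within one condition; with two replicates and all three
#' categories present this has 2 df. Categories absent from every replicate
#' are dropped (reducing the df) with a warning.
#'
#' @inheritParams compare_conditions
#' @param condition Condition to test (`"clonal"` or `"chimeric"`).
#' @return A one-row tibble with statistic, df and p-value.
#' @export
replicate_homogeneity <- function(cells, condition) {
  kept <- cells[cells$fate != "censored" & cells$condition == condition, ]
  if (dplyr::n_distinct(kept$replicate_id) < 2) {
    abort("need at least two replicates.", class = "cigame_data_error")
  }
  tab <- table(kept$replicate_id, droplevels(factor(kept$fate,
                                                    levels = fate_levels[1:3])))
  if (ncol(tab) < 3) {
    warn(sprintf(
      "only %d fate categories present; degrees of freedom reduced.",
      ncol(tab)))
  }
  test <- suppressWarnings(chisq.test(tab))
  tibble(condition = condition,
         statistic = unname(test$statistic),
         df = unname(test$parameter),
         p_value = test$p.value)
}

#' Summarise fate proportions
#'
#' Fate-category counts and proportions among classified cells, per
#' condition.
#'
#' @inheritParams compare_conditions
#' @return A tibble with `condition`, `fate`, `n`, `proportion`.
#' @export
fate_proportions <- function(cells) {
  cells[cells$fate != "censored", ] |>
    dplyr::count(.data$condition, .data$fate, .drop = FALSE) |>
    dplyr::filter(.data$fate != "censored") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
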