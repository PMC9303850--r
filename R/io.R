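# CSV readers and writers for the assay and cell tables. The dialect is
# plain comma-separated UTF-8 with a header row and '.' decimals, matching
# common supplementary-data exports.

assay_columns <- c("strain_set_id", "replicate_id", "strain_id", "frequency",
                   "clonal_spores", "chimeric_spores")
cell_columns <- c("cell_id", "replicate_id", "condition", "ecmA", "pspA")

#' Read a spore-assay table
#'
#' Reads and validates the long assay schema: one row per strain per group
#' replicate, with the chimeric total repeated on each strain row. Validation
#' errors name the offending group and rows; unknown extra columns are kept
#' with a warning.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_assay_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(assay_columns, names(d))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  extra <- setdiff(names(d), assay_columns)
  if (length(extra)) {
    warn(paste0("ignoring extra column(s): ", paste(extra, collapse = ", ")))
  }
  bad <- which(!is.finite(d$clonal_spores) | d$clonal_spores < 0 |
                 !is.finite(d$chimeric_spores) | d$chimeric_spores < 0)
  if (length(bad)) {
    abort(sprintf("negative or missing spore counts at row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "cigame_data_error")
  }
  sums <- d |>
    dplyr::group_by(.data$strain_set_id, .data$replicate_id) |>
    dplyr::summarise(fsum = sum(.data$frequency), .groups = "drop")
  off <- sums[abs(sums$fsum - 1) > 1e-6, ]
  if (nrow(off)) {
    abort(sprintf(
      "frequencies do not sum to 1 in group %s (replicate %s): sum = %.6f.",
      off$strain_set_id[1], off$replicate_id[1], off$fsum[1]),
      class = "cigame_data_error")
  }
  d
}

#' @rdname read_assay_table
#' @param data A table with the assay schema.
#' @export
write_assay_table <- function(data, path) {
  missing_cols <- setdiff(assay_columns, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  readr::write_csv(data[assay_columns], path)
  invisible(path)
}

#' Read a per-cell smFISH count table
#'
#' Reads and validates per-cell dot counts: integer `ecmA` and `pspA` counts
#' and a `condition` of `"clonal"` or `"chimeric"`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_cell_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cell_columns, names(d))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  extra <- setdiff(names(d), cell_columns)
  if (length(extra)) {
    warn(paste0("ignoring extra column(s): ", paste(extra, collapse = ", ")))
  }
  for (gene in c("ecmA", "pspA")) {
    v <- d[[gene]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      abort(sprintf("`%s` must hold nonnegative integer dot counts.", gene),
            class = "cigame_data_error")
    }
  }
  bad_cond <- setdiff(unique(d$condition), c("clonal", "chimeric"))
  if (length(bad_cond)) {
    abort(paste0("unknown condition label(s): ",
                 paste(bad_cond, collapse = ", "),
                 "; allowed: clonal, chimeric."),
          class = "cigame_data_error")
  }
  d
}

#' @rdname read_cell_table
#' @param data A table with the cell schema.
#' @export
write_cell_table <- function(data, path) {
  missing_cols <- setdiff(cell_columns, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cigame_data_error")
  }
  readr::write_csv(data[cell_columns], path)
  invisible(path)
}
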