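## Readers and writers for every table the pipeline touches, with strict
## schema validation. CSV/TSV only, UTF-8, header row mandatory. Unknown
## columns are preserved but never interpreted; missing required columns
## are a named error.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_no_duplicate_plots <- function(df, what) {
  key <- paste(df$accession_id, df$year, df$block, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("accession_id", "year", "block")][1, ]
    stop(what, ": duplicate (accession, year, block) row: ",
         paste(dup, collapse = " / "))
  }
  invisible(df)
}

read_table_file <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

write_table_file <- function(df, path, delim = ",") {
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read raw plot records (flowering fractions)
#'
#' Schema: `accession_id`, `year`, `block`, `n_plants`, `frac60`, `frac100`
#' with fractions in `[0, 1]`. Duplicate (accession, year, block) rows are
#' rejected.
#'
#' @param path CSV path.
#' @return Tibble of plot records.
#' @export
read_plot_records <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("accession_id", "year", "block", "n_plants",
                      "frac60", "frac100"), "plot records")
  check_no_duplicate_plots(df, "plot records")
  for (col in c("frac60", "frac100")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad) > 0) {
      stop("plot records: row ", bad[1], ", column '", col,
           "': fraction outside [0, 1]")
    }
  }
  df$year <- as.character(df$year)
  df
}

#' @rdname read_plot_records
#' @param records Tibble of plot records.
#' @export
write_plot_records <- function(records, path) {
  check_columns(records, c("accession_id", "year", "block", "n_plants",
                           "frac60", "frac100"), "plot records")
  write_table_file(records, path)
}

#' Read scored plot observations (5-point percentages)
#'
#' Schema: `accession_id`, `year`, `block`, `pct60`, `pct100`. In strict
#' mode any score outside `{0, 25, 50, 75, 100}` is a named error.
#'
#' @param path CSV path.
#' @param strict Enforce the 5-point score set (default TRUE).
#' @return Tibble of scored observations.
#' @export
read_observations <- function(path, strict = TRUE) {
  df <- read_table_file(path)
  check_columns(df, c("accession_id", "year", "block", "pct60", "pct100"),
                "observations")
  check_no_duplicate_plots(df, "observations")
  if (strict) {
    for (col in c("pct60", "pct100")) {
      bad <- which(!is.na(df[[col]]) &
                     !df[[col]] %in% c(0, 25, 50, 75, 100))
      if (length(bad) > 0) {
        stop("observations: row ", bad[1], ", column '", col, "': score ",
             df[[col]][bad[1]], " not in {0, 25, 50, 75, 100}")
      }
    }
  }
  df$year <- as.character(df$year)
  df
}

#' @rdname read_observations
#' @param observations Tibble of scored observations.
#' @export
write_observations <- function(observations, path) {
  check_columns(observations,
                c("accession_id", "year", "block", "pct60", "pct100"),
                "observations")
  write_table_file(observations, path)
}

#' Read or write generator truth labels
#'
#' Schema: `accession_id`, `true_category`, `p_early_annual`,
#' `p_late_annual`, `p_biennial`.
#'
#' @param path CSV path.
#' @return Tibble of truth labels.
#' @export
read_truth_labels <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("accession_id", "true_category", "p_early_annual",
                      "p_late_annual", "p_biennial"), "truth labels")
  df
}

#' @rdname read_truth_labels
#' @param profiles Accession profiles from [generate_collection()].
#' @export
write_truth_labels <- function(profiles, path) {
  check_columns(profiles, c("accession_id", "true_category",
                            "p_early_annual", "p_late_annual",
                            "p_biennial"), "truth labels")
  write_table_file(profiles[, c("accession_id", "true_category",
                                "p_early_annual", "p_late_annual",
                                "p_biennial")], path)
}

#' Read or write accession phenotypes (marginal means)
#'
#' Schema: `accession_id`, `scope`, `emm60`, `emm100`, `n_plots_used`.
#'
#' @param path CSV path.
#' @return Tibble of accession phenotypes.
#' @export
read_accession_phenotypes <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("accession_id", "scope", "emm60", "emm100",
                      "n_plots_used"), "accession phenotypes")
  df
}

#' @rdname read_accession_phenotypes
#' @param phenotypes Tibble from [accession_emmeans()].
#' @export
write_accession_phenotypes <- function(phenotypes, path) {
  check_columns(phenotypes, c("accession_id", "scope", "emm60", "emm100",
                              "n_plots_used"), "accession phenotypes")
  write_table_file(phenotypes, path)
}

#' Read or write flowering-habit calls
#'
#' Schema: `accession_id`, `scheme`, `category`, `subcategory`, `emm60`,
#' `emm100`.
#'
#' @param path CSV path.
#' @return Tibble of calls.
#' @export
read_habit_calls <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("accession_id", "scheme", "category", "subcategory",
                      "emm60", "emm100"), "habit calls")
  df
}

#' @rdname read_habit_calls
#' @param calls Tibble from [classify_accessions()].
#' @export
write_habit_calls <- function(calls, path) {
  check_columns(calls, c("accession_id", "scheme", "category",
                         "subcategory", "emm60", "emm100"), "habit calls")
  write_table_file(calls, path)
}

summary_row_order <- c(
  "Biennial", "Mixture", "Predominantly biennial", "All other mixtures",
  "Annual", "Annual (non-uniform)", "Uniformly-early annual",
  "Uniformly-late annual", "Flowering 60 DAS", "Flowering 100 DAS"
)

#' Write or read a collection summary (TSV)
#'
#' Rows follow the canonical summary-table order (Biennial; Mixture;
#' Predominantly biennial; All other mixtures; Annual; Annual
#' (non-uniform); Uniformly-early annual; Uniformly-late annual; Flowering
#' 60 DAS; Flowering 100 DAS); categories absent under a scheme are
#' omitted, empty categories keep a row with count 0. Percentages render to
#' 2 decimals. The writer is deterministic.
#'
#' @param summary Tibble from [summarize_collection()].
#' @param path TSV path.
#' @export
write_collection_summary <- function(summary, path) {
  check_columns(summary, c("scheme", "row_label", "level", "count",
                           "percent", "denominator"), "collection summary")
  ord <- match(summary$row_label, summary_row_order)
  if (anyNA(ord)) {
    stop("collection summary: unknown row label(s): ",
         paste(summary$row_label[is.na(ord)], collapse = ", "))
  }
  out <- summary[order(ord), ]
  out$percent <- sprintf("%.2f", out$percent)
  write_table_file(out, path, delim = "\t")
}

#' @rdname write_collection_summary
#' @return `read_collection_summary()` returns the summary tibble with
#'   numeric `percent`.
#' @export
read_collection_summary <- function(path) {
  df <- read_table_file(path, delim = "\t")
  check_columns(df, c("scheme", "row_label", "level", "count", "percent",
                      "denominator"), "collection summary")
  df$percent <- as.numeric(df$percent)
  df
}

#' Write the trait dictionary (TSV)
#'
#' @param dictionary Tibble from [flowering_trait_dictionary()].
#' @param path TSV path.
#' @export
write_trait_dictionary <- function(dictionary, path) {
  check_columns(dictionary, c("trait", "definition", "scale",
                              "timepoints_das"), "trait dictionary")
  write_table_file(dictionary, path, delim = "\t")
}

#' Write a QC report of senescence flags and outlier screens (TSV)
#'
#' @param flags Tibble from [detect_senescence()].
#' @param path TSV path.
#' @export
write_qc_report <- function(flags, path) {
  check_columns(flags, c("accession_id", "year", "block", "pct60",
                         "pct100", "flagged"), "QC report")
  write_table_file(flags, path, delim = "\t")
}
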