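## Two-timepoint flowering-habit trait ontology classifier, the
## three-category baseline scheme, and collection summaries.

#' Flowering-habit classification thresholds
#'
#' `t_low` separates "predominantly biennial" mixtures (and late-annual
#' mid-season flowering) from the rest; `t_high` separates annuals from
#' mixtures at end of season. Defaults 15 and 85 percent.
#'
#' @param t_low,t_high Percent thresholds with `0 < t_low < t_high < 100`.
#' @return List of class `habit_thresholds`.
#' @export
habit_thresholds <- function(t_low = 15, t_high = 85) {
  if (!(0 < t_low && t_low < t_high && t_high < 100)) {
    stop("need 0 < t_low < t_high < 100")
  }
  structure(list(t_low = t_low, t_high = t_high), class = "habit_thresholds")
}

#' Classify accessions under the two-timepoint flowering-habit ontology
#'
#' Total, disjoint partition of the `(emm60, emm100)` square, following the
#' ontology flowchart. With thresholds `(t_low, t_high)`:
#' \itemize{
#'   \item biennial: `emm100 == 0` (no flowering observed in season one);
#'   \item annual: `emm100 > t_high`, subdivided on `emm60` into
#'     uniformly-early (`emm60 > t_high`), uniformly-late
#'     (`emm60 <= t_low`) and non-uniform (otherwise);
#'   \item mixture: `0 < emm100 <= t_high`, subdivided into predominantly
#'     biennial (`emm100 <= t_low` and `emm60 <= t_low`) and all other
#'     mixtures.
#' }
#' Comparisons use marginal means rounded to 4 decimals, so category
#' boundaries have exact decimal semantics.
#'
#' @param emm60,emm100 Numeric vectors of estimated marginal mean flowering
#'   percentages at 60 and 100 DAS, in `[0, 100]`.
#' @param thresholds A [habit_thresholds()].
#' @return Tibble with `scheme` (`"carrotomics"`), `category`,
#'   `subcategory`, `emm60`, `emm100`.
#' @export
classify_carrotomics <- function(emm60, emm100,
                                 thresholds = habit_thresholds()) {
  stopifnot(length(emm60) == length(emm100))
  if (any(is.na(emm60) | is.na(emm100))) stop("marginal means must not be NA")
  if (any(emm60 < 0 | emm60 > 100 | emm100 < 0 | emm100 > 100)) {
    stop("marginal means must lie in [0, 100]")
  }
  e60 <- round(emm60, 4)
  e100 <- round(emm100, 4)
  lo <- thresholds$t_low
  hi <- thresholds$t_high

  category <- ifelse(e100 == 0, "biennial",
              ifelse(e100 > hi, "annual", "mixture"))
  subcategory <- rep("none", length(e60))
  ann <- category == "annual"
  subcategory[ann & e60 > hi] <- "uniformly_early_annual"
  subcategory[ann & e60 <= lo] <- "uniformly_late_annual"
  subcategory[ann & e60 > lo & e60 <= hi] <- "non_uniform_annual"
  mix <- category == "mixture"
  subcategory[mix & e100 <= lo & e60 <= lo] <- "predominantly_biennial"
  subcategory[mix & !(e100 <= lo & e60 <= lo)] <- "other_mixture"

  tibble::tibble(scheme = "carrotomics", category = category,
                 subcategory = subcategory, emm60 = emm60, emm100 = emm100)
}

#' Classify accessions under the three-category baseline scheme
#'
#' The traditional genebank life-form descriptor: annual means 100 percent
#' flowering at end of season, biennial means 0 percent, and anything in
#' between is a mixture. No subcategories.
#'
#' @param emm100 Numeric vector of end-of-season marginal means in
#'   `[0, 100]`.
#' @return Tibble with `scheme` (`"grin_baseline"`), `category`,
#'   `subcategory` (always `"none"`), `emm100`.
#' @export
classify_grin_baseline <- function(emm100) {
  if (any(is.na(emm100))) stop("marginal means must not be NA")
  if (any(emm100 < 0 | emm100 > 100)) {
    stop("marginal means must lie in [0, 100]")
  }
  e100 <- round(emm100, 4)
  category <- ifelse(e100 == 0, "biennial",
              ifelse(e100 == 100, "annual", "mixture"))
  tibble::tibble(scheme = "grin_baseline", category = category,
                 subcategory = "none", emm100 = emm100)
}

#' Assign flowering-habit calls to accession phenotypes
#'
#' @param phenotypes Accession phenotypes from [accession_emmeans()].
#' @param scheme `"carrotomics"` (two-timepoint ontology) or
#'   `"grin_baseline"` (three categories from 100 DAS only).
#' @param thresholds A [habit_thresholds()] (carrotomics scheme only).
#' @return Tibble of calls: `accession_id`, `scheme`, `category`,
#'   `subcategory`, `emm60`, `emm100`.
#' @export
classify_accessions <- function(phenotypes,
                                scheme = c("carrotomics", "grin_baseline"),
                                thresholds = habit_thresholds()) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("accession_id", "emm60", "emm100") %in% names(phenotypes)))
  calls <- if (scheme == "carrotomics") {
    classify_carrotomics(phenotypes$emm60, phenotypes$emm100, thresholds)
  } else {
    out <- classify_grin_baseline(phenotypes$emm100)
    out$emm60 <- phenotypes$emm60
    out
  }
  calls$accession_id <- phenotypes$accession_id
  calls[, c("accession_id", "scheme", "category", "subcategory",
            "emm60", "emm100")]
}

#' Summarize a classified collection
#'
#' Counts and percentages of accessions per category (and, for the
#' two-timepoint ontology, per subcategory), plus the number of accessions
#' with any flowering at each scoring date. Percentages are percent of the
#' full collection, printed to 2 decimals (half away from zero).
#'
#' @param calls Habit calls from [classify_accessions()], one scheme only.
#' @return Tibble with `scheme`, `row_label`, `level`
#'   (category/subcategory/flowering), `count`, `percent`, `denominator`.
#' @export
summarize_collection <- function(calls) {
  if (nrow(calls) == 0) stop("empty call set")
  scheme <- unique(calls$scheme)
  if (length(scheme) != 1) stop("calls must all share one scheme")
  n <- nrow(calls)
  cat_counts <- table(factor(calls$category, levels = habit_top_categories()))
  rows <- list(
    tibble::tibble(row_label = "Biennial", level = "category",
                   count = as.integer(cat_counts[["biennial"]])),
    tibble::tibble(row_label = "Mixture", level = "category",
                   count = as.integer(cat_counts[["mixture"]]))
  )
  if (scheme == "carrotomics") {
    sub_counts <- table(factor(calls$subcategory,
                               levels = habit_leaf_categories()))
    rows <- c(rows, list(
      tibble::tibble(row_label = "Predominantly biennial",
                     level = "subcategory",
                     count = as.integer(sub_counts[["predominantly_biennial"]])),
      tibble::tibble(row_label = "All other mixtures", level = "subcategory",
                     count = as.integer(sub_counts[["other_mixture"]])),
      tibble::tibble(row_label = "Annual", level = "category",
                     count = as.integer(cat_counts[["annual"]])),
      tibble::tibble(row_label = "Annual (non-uniform)", level = "subcategory",
                     count = as.integer(sub_counts[["non_uniform_annual"]])),
      tibble::tibble(row_label = "Uniformly-early annual",
                     level = "subcategory",
                     count = as.integer(sub_counts[["uniformly_early_annual"]])),
      tibble::tibble(row_label = "Uniformly-late annual",
                     level = "subcategory",
                     count = as.integer(sub_counts[["uniformly_late_annual"]]))
    ))
  } else {
    rows <- c(rows, list(
      tibble::tibble(row_label = "Annual", level = "category",
                     count = as.integer(cat_counts[["annual"]]))
    ))
  }
  rows <- c(rows, list(
    tibble::tibble(row_label = "Flowering 60 DAS", level = "flowering",
                   count = sum(!is.na(calls$emm60) & calls$emm60 > 0)),
    tibble::tibble(row_label = "Flowering 100 DAS", level = "flowering",
                   count = sum(calls$emm100 > 0))
  ))
  out <- dplyr::bind_rows(rows)
  out$percent <- round_half_away(100 * out$count / n, 2)
  out$denominator <- n
  out$scheme <- scheme
  out[, c("scheme", "row_label", "level", "count", "percent", "denominator")]
}

#' The flowering-habit trait dictionary
#'
#' The ontology exported as a Crop-Ontology-style trait dictionary: trait
#' name, definition, measurement scale, and scoring timepoints.
#'
#' @param thresholds A [habit_thresholds()] used to render the definitions.
#' @return Tibble with `trait`, `definition`, `scale`, `timepoints_das`.
#' @export
flowering_trait_dictionary <- function(thresholds = habit_thresholds()) {
  lo <- thresholds$t_low
  hi <- thresholds$t_high
  tibble::tibble(
    trait = c("percent_flowering", "biennial", "mixture",
              "predominantly_biennial", "other_mixture", "annual",
              "uniformly_early_annual", "uniformly_late_annual",
              "non_uniform_annual"),
    definition = c(
      "Percentage of plants within a plot with visible signs of flowering in the first planting season",
      "0% of plants flowering during the first growth season; flowering requires vernalization",
      sprintf("Both annual and biennial plants in the plot; >0%% and <=%s%% flowering at end of season", hi),
      sprintf("Mixture with >0%% and <=%s%% flowering plants at both scoring dates", lo),
      "Mixture not meeting the predominantly-biennial condition",
      sprintf("More than %s%% of plants flowering by end of season", hi),
      sprintf("Annual with >%s%% of plants flowering by mid-season", hi),
      sprintf("Annual with <=%s%% flowering at mid-season and >%s%% at end of season", lo, hi),
      sprintf("Annual flowering non-uniformly: >%s%% and <=%s%% at mid-season", lo, hi)
    ),
    scale = c("0-100% in increments of 25%", rep("categorical", 8)),
    timepoints_das = c("60,100", "60,100", "100", "60,100", "60,100",
                       "100", "60", "60,100", "60,100")
  )
}
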