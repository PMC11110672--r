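## Estimated marginal means of flowering percentage per accession.
##
## With genotype as the focal fixed term in the trial model, the marginal
## mean of an accession is the unweighted average of its year-level cell
## means, each cell mean being the average over blocks within that year.
## Under sum-to-zero coding this equals the least-squares mean of the
## genotype term, and on fully balanced data it reduces to the raw mean of
## the accession's plots.

#' Per-accession estimated marginal means of flowering percentage
#'
#' @param observations Scored observations (`accession_id`, `year`, `block`,
#'   `pct60`, `pct100`); scores may be any values in `[0, 100]`.
#' @param years Optional character vector restricting the scope to a year
#'   subset (e.g. the two comparable years of a three-year trial). Default:
#'   all years present.
#' @param min_years Minimum number of scoped years an accession must appear
#'   in to be retained (default 1; accessions present in fewer than all
#'   scoped years are kept with a warning).
#' @return Tibble of accession phenotypes: `accession_id`, `scope`,
#'   `emm60`, `emm100`, `n_plots_used`, `n_years_present`.
#' @export
accession_emmeans <- function(observations, years = NULL, min_years = 1L) {
  stopifnot(all(c("accession_id", "year", "pct60", "pct100")
                %in% names(observations)))
  if (nrow(observations) == 0) stop("empty observation set")
  obs <- tibble::as_tibble(observations)
  obs$year <- as.character(obs$year)
  if (is.null(years)) {
    years <- sort(unique(obs$year))
  } else {
    years <- as.character(years)
    absent <- setdiff(years, unique(obs$year))
    if (length(absent) > 0) {
      stop("requested year(s) absent from data: ",
           paste(absent, collapse = ", "))
    }
    obs <- obs[obs$year %in% years, ]
  }
  scope <- if (length(years) == 1) {
    paste0("single_year:", years)
  } else {
    paste0("multi_year:", paste(sort(years), collapse = "+"))
  }
  cells <- obs |>
    dplyr::filter(!is.na(.data$pct60), !is.na(.data$pct100)) |>
    dplyr::group_by(.data$accession_id, .data$year) |>
    dplyr::summarise(cell60 = mean(.data$pct60),
                     cell100 = mean(.data$pct100),
                     n_plots = dplyr::n(), .groups = "drop")
  out <- cells |>
    dplyr::group_by(.data$accession_id) |>
    dplyr::summarise(emm60 = mean(.data$cell60),
                     emm100 = mean(.data$cell100),
                     n_plots_used = sum(.data$n_plots),
                     n_years_present = dplyr::n(), .groups = "drop")
  out <- out[out$n_years_present >= min_years, ]
  if (nrow(out) == 0) stop("no accession meets the min_years filter")
  incomplete <- sum(out$n_years_present < length(years))
  if (incomplete > 0) {
    warning(incomplete, " accession(s) present in fewer than ",
            length(years), " scoped year(s); retained")
  }
  out$scope <- scope
  out[, c("accession_id", "scope", "emm60", "emm100",
          "n_plots_used", "n_years_present")]
}
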