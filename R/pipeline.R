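## End-to-end orchestration with reproducible seeded runs. Every run
## serializes its resolved configuration beside its outputs.

#' Build and validate a pipeline run configuration
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_accessions Collection size.
#' @param category_mix Named category proportions, see
#'   [generate_collection()].
#' @param years,blocks_per_year,plants_per_plot,emergence_rate Trial design,
#'   see [trial_design()].
#' @param env_sds Logit-scale environment SDs `c(year=, gy=, block=)`.
#' @param stand_loss_events Optional stand-loss table, see [trial_design()].
#' @param senescence_rate Early-annual senescence probability.
#' @param concentration,sd_genotype Collection-generator knobs.
#' @param t_low,t_high Ontology thresholds (percent).
#' @param quantize_policy `"detect"` or `"nearest"`.
#' @param year_subset Years used for classification marginal means
#'   (default: all trial years).
#' @param varcomp_method `"reml"` or `"ems_mom"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_accessions = 695L,
                       category_mix = default_category_mix(),
                       years = c("year1", "year2", "year3"),
                       blocks_per_year = 2L,
                       plants_per_plot = 50L,
                       emergence_rate = 0.9,
                       env_sds = c(year = 0.6, gy = 0.5, block = 0.15),
                       stand_loss_events = NULL,
                       senescence_rate = 0,
                       concentration = 2,
                       sd_genotype = 0,
                       t_low = 15,
                       t_high = 85,
                       quantize_policy = c("detect", "nearest"),
                       year_subset = NULL,
                       varcomp_method = c("reml", "ems_mom")) {
  quantize_policy <- match.arg(quantize_policy)
  varcomp_method <- match.arg(varcomp_method)
  design <- trial_design(years, blocks_per_year, plants_per_plot,
                         emergence_rate, stand_loss_events,
                         senescence_rate)
  thresholds <- habit_thresholds(t_low, t_high)
  if (is.null(year_subset)) year_subset <- as.character(years)
  if (!all(year_subset %in% years)) {
    stop("year_subset must be a subset of the trial years")
  }
  structure(
    list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
         category_mix = category_mix, design = design,
         env_sds = env_sds, concentration = concentration,
         sd_genotype = sd_genotype, thresholds = thresholds,
         quantize_policy = quantize_policy,
         year_subset = as.character(year_subset),
         varcomp_method = varcomp_method),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  d <- config$design
  list(
    seed = config$seed,
    n_accessions = config$n_accessions,
    category_mix = as.list(config$category_mix),
    years = d$years,
    blocks_per_year = d$blocks_per_year,
    plants_per_plot = d$plants_per_plot,
    emergence_rate = d$emergence_rate,
    stand_loss_events = if (is.null(d$stand_loss_events)) NULL else
      lapply(seq_len(nrow(d$stand_loss_events)),
             function(i) as.list(d$stand_loss_events[i, ])),
    senescence_rate = d$senescence_rate,
    env_sds = as.list(config$env_sds),
    concentration = config$concentration,
    sd_genotype = config$sd_genotype,
    t_low = config$thresholds$t_low,
    t_high = config$thresholds$t_high,
    quantize_policy = config$quantize_policy,
    year_subset = config$year_subset,
    varcomp_method = config$varcomp_method
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_as_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sl <- if (is.null(x$stand_loss_events)) NULL else
    dplyr::bind_rows(lapply(x$stand_loss_events, tibble::as_tibble))
  run_config(
    seed = x$seed, n_accessions = x$n_accessions,
    category_mix = unlist(x$category_mix),
    years = x$years, blocks_per_year = x$blocks_per_year,
    plants_per_plot = x$plants_per_plot,
    emergence_rate = x$emergence_rate,
    stand_loss_events = sl, senescence_rate = x$senescence_rate,
    env_sds = unlist(x$env_sds), concentration = x$concentration,
    sd_genotype = x$sd_genotype, t_low = x$t_low, t_high = x$t_high,
    quantize_policy = x$quantize_policy, year_subset = x$year_subset,
    varcomp_method = x$varcomp_method
  )
}

#' Simulate a collection and trial, writing plot records and truth labels
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); receives
#'   `plot_records.csv`, `truth_labels.csv` and `run_config.yaml`.
#' @return Invisibly, a list with `profiles` and `records`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- generate_collection(
    config$n_accessions, config$category_mix, config$concentration,
    config$sd_genotype, config$thresholds, config$seed
  )
  records <- simulate_trial(profiles, config$design, config$env_sds,
                            config$seed)
  write_truth_labels(profiles, file.path(out_dir, "truth_labels.csv"))
  write_plot_records(records, file.path(out_dir, "plot_records.csv"))
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(list(profiles = profiles, records = records))
}

#' Score, QC, classify and summarize a trial
#'
#' Scores raw plot records on the 5-point scale, flags senescence
#' declines, computes per-accession marginal means over the configured
#' year subset, classifies under both schemes, and writes calls plus
#' summary tables.
#'
#' @param records Plot records tibble or path to a plot-record CSV.
#' @param config A [run_config()].
#' @param out_dir Output directory; receives `observations.csv`,
#'   `qc_senescence.tsv`, `accession_phenotypes.csv`, `habit_calls.csv`,
#'   `summary_carrotomics.tsv`, `summary_grin.tsv`,
#'   `trait_dictionary.tsv`, `run_config.yaml`.
#' @return Invisibly, a list with `observations`, `phenotypes`, `calls`
#'   (both schemes) and `summaries`.
#' @export
run_classify <- function(records, config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(records)) records <- read_plot_records(records)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs <- score_plots(records, config$quantize_policy)
  flags <- detect_senescence(obs)
  pheno <- accession_emmeans(obs, years = config$year_subset)
  calls_co <- classify_accessions(pheno, "carrotomics", config$thresholds)
  calls_gr <- classify_accessions(pheno, "grin_baseline")
  sum_co <- summarize_collection(calls_co)
  sum_gr <- summarize_collection(calls_gr)
  write_observations(obs, file.path(out_dir, "observations.csv"))
  write_qc_report(flags, file.path(out_dir, "qc_senescence.tsv"))
  write_accession_phenotypes(pheno,
                             file.path(out_dir, "accession_phenotypes.csv"))
  write_habit_calls(dplyr::bind_rows(calls_co, calls_gr),
                    file.path(out_dir, "habit_calls.csv"))
  write_collection_summary(sum_co,
                           file.path(out_dir, "summary_carrotomics.tsv"))
  write_collection_summary(sum_gr, file.path(out_dir, "summary_grin.tsv"))
  write_trait_dictionary(flowering_trait_dictionary(config$thresholds),
                         file.path(out_dir, "trait_dictionary.tsv"))
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(list(observations = obs, phenotypes = pheno,
                 calls = list(carrotomics = calls_co,
                              grin_baseline = calls_gr),
                 summaries = list(carrotomics = sum_co,
                                  grin_baseline = sum_gr)))
}

#' ANOVA, variance-component and heritability report for a trial
#'
#' Per year and timepoint: the single-year Type III ANOVA and entry-mean
#' heritability; across the configured year subset: the multi-year ANOVA
#' and heritability. Writes `anova_report.tsv` and `heritability.tsv`.
#'
#' @inheritParams run_classify
#' @return Invisibly, a list with `anova_tables` and `h2` tibbles.
#' @export
run_heritability <- function(records, config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(records)) records <- read_plot_records(records)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs <- score_plots(records, config$quantize_policy)
  years <- sort(unique(obs$year))
  anova_tables <- list()
  h2_rows <- list()
  for (tp in c(60, 100)) {
    for (y in years) {
      oy <- obs[obs$year == y, ]
      tab <- anova_single_year(oy, tp)
      tab$scope <- paste0("single_year:", y)
      tab$timepoint <- tp
      anova_tables[[length(anova_tables) + 1]] <- tab
      h <- heritability(oy, "single_year", tp, config$varcomp_method)
      h2_rows[[length(h2_rows) + 1]] <- tibble::tibble(
        scope = paste0("single_year:", y), timepoint = tp, H2 = h$H2
      )
    }
    omy <- obs[obs$year %in% config$year_subset, ]
    if (length(config$year_subset) >= 2) {
      tab <- anova_multi_year(omy, tp)
      tab$scope <- paste0("multi_year:",
                          paste(config$year_subset, collapse = "+"))
      tab$timepoint <- tp
      anova_tables[[length(anova_tables) + 1]] <- tab
      h <- heritability(omy, "multi_year", tp, config$varcomp_method)
      h2_rows[[length(h2_rows) + 1]] <- tibble::tibble(
        scope = paste0("multi_year:",
                       paste(config$year_subset, collapse = "+")),
        timepoint = tp, H2 = h$H2
      )
    }
  }
  anova_all <- dplyr::bind_rows(anova_tables)
  h2_all <- dplyr::bind_rows(h2_rows)
  write_table_file(anova_all, file.path(out_dir, "anova_report.tsv"),
                   delim = "\t")
  write_table_file(h2_all, file.path(out_dir, "heritability.tsv"),
                   delim = "\t")
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(list(anova_tables = anova_all, h2 = h2_all))
}

#' Grouped trait-correlation report
#'
#' @param trait_table Trait table (one row per accession, numeric trait
#'   columns, `category` column), e.g. from
#'   [simulate_vegetative_traits()].
#' @param config A [run_config()].
#' @param out_dir Output directory; receives `trait_correlations.tsv`.
#' @param ... Passed to [grouped_pearson()].
#' @return Invisibly, the long-format correlation tibble.
#' @export
run_correlate <- function(trait_table, config, out_dir, ...) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cors <- grouped_pearson(trait_table, ...)
  write_table_file(cors, file.path(out_dir, "trait_correlations.tsv"),
                   delim = "\t")
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  invisible(cors)
}

#' Run the whole pipeline: simulate, classify, heritability, correlations
#'
#' @param config A [run_config()].
#' @param out_dir Run directory; every stage writes beside the resolved
#'   config.
#' @return Invisibly, a list with each stage's outputs.
#' @export
run_report <- function(config, out_dir) {
  sim <- run_simulate(config, out_dir)
  cls <- run_classify(sim$records, config, out_dir)
  her <- run_heritability(sim$records, config, out_dir)
  traits <- simulate_vegetative_traits(cls$calls$carrotomics, config$seed)
  cors <- run_correlate(traits, config, out_dir)
  invisible(list(simulate = sim, classify = cls, heritability = her,
                 correlations = cors))
}
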