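## Synthetic germplasm-trial simulator.
##
## Each simulated accession is a heterogeneous population: a mixture of
## early-annual, late-annual and biennial plants. A plot's flowering fraction
## at mid-season (60 DAS) and end of season (100 DAS) is the realized
## proportion of plants that have flowered by each timepoint, after
## perturbation of the annual fractions on the logit (liability) scale by
## year, genotype-by-year and block effects.

#' Derive a reproducible sub-stream seed from a global seed and keys
#'
#' Stable string hash so that every (accession, year, block) plot, and every
#' environment-effect draw, has its own RNG stream regardless of iteration
#' order. Arithmetic stays below 2^53 so the hash is exact in doubles.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric keys identifying the sub-stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(seed %% 2147483647)
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

#' Trial design for a multi-year RCBD germplasm evaluation
#'
#' @param years Character vector of year labels.
#' @param blocks_per_year Number of complete blocks per year (>= 1).
#' @param plants_per_plot Number of seeds hand-planted per plot (>= 1).
#' @param emergence_rate Probability a planted seed emerges (binomial
#'   thinning before life-form assignment).
#' @param stand_loss_events Optional data frame with columns `year`,
#'   `survival_fraction` (in (0, 1]) and `early_bias` (>= 0); a positive
#'   `early_bias` lowers the survival of early-flowering plants on the logit
#'   scale, emulating a weather event that preferentially removes
#'   early-emerging annuals.
#' @param senescence_rate Probability that an early-flowering plant senesces
#'   between the two scoring dates and shows no visible flowering at 100 DAS
#'   (off by default; a rare field event).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(years = c("year1", "year2", "year3"),
                         blocks_per_year = 2L,
                         plants_per_plot = 50L,
                         emergence_rate = 0.9,
                         stand_loss_events = NULL,
                         senescence_rate = 0) {
  stopifnot(length(years) >= 1, !anyDuplicated(years))
  if (blocks_per_year < 1) stop("blocks_per_year must be >= 1")
  if (plants_per_plot < 1) stop("plants_per_plot must be >= 1")
  if (emergence_rate <= 0 || emergence_rate > 1) {
    stop("emergence_rate must be in (0, 1]")
  }
  if (senescence_rate < 0 || senescence_rate > 1) {
    stop("senescence_rate must be in [0, 1]")
  }
  if (!is.null(stand_loss_events)) {
    stand_loss_events <- as.data.frame(stand_loss_events)
    req <- c("year", "survival_fraction", "early_bias")
    if (!all(req %in% names(stand_loss_events))) {
      stop("stand_loss_events needs columns: ", paste(req, collapse = ", "))
    }
    bad <- setdiff(stand_loss_events$year, years)
    if (length(bad) > 0) {
      stop("stand_loss_events refers to unknown year(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(stand_loss_events$survival_fraction <= 0 |
            stand_loss_events$survival_fraction > 1)) {
      stop("survival_fraction must be in (0, 1]")
    }
  }
  structure(
    list(years = as.character(years),
         blocks_per_year = as.integer(blocks_per_year),
         plants_per_plot = as.integer(plants_per_plot),
         emergence_rate = emergence_rate,
         stand_loss_events = stand_loss_events,
         senescence_rate = senescence_rate),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design:", length(x$years), "year(s) x", x$blocks_per_year,
      "block(s), ", x$plants_per_plot, "plants/plot (emergence ",
      x$emergence_rate, ")\n", sep = " ")
  if (!is.null(x$stand_loss_events)) {
    cat("  stand-loss events in:",
        paste(x$stand_loss_events$year, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default germplasm category mix
#'
#' The across-year composition of a large cultivated-carrot diversity panel
#' under the two-timepoint ontology (counts 197/160/250/50/5/6 of 668),
#' used as the default scenario for the simulator.
#'
#' @return Named numeric vector of category proportions summing to 1.
#' @export
default_category_mix <- function() {
  c(biennial = 197, predominantly_biennial = 160, other_mixture = 250,
    non_uniform_annual = 50, uniformly_early_annual = 5,
    uniformly_late_annual = 6) / 668
}

## Draw a within-accession life-form composition consistent with a target
## category's thresholds (fractions scale: t_low = 0.15, t_high = 0.85 by
## default). Constructive bounded draws keep the truth label exact.
draw_composition <- function(category, concentration, t_low, t_high) {
  eps <- 1e-4
  split_early <- function(total) total * rbeta(1, concentration, concentration)
  switch(
    category,
    biennial = c(early = 0, late = 0),
    predominantly_biennial = {
      tot <- runif(1, eps, t_low - eps)
      e <- split_early(tot)
      c(early = e, late = tot - e)
    },
    other_mixture = {
      tot <- runif(1, t_low + eps, t_high - eps)
      e <- split_early(tot)
      c(early = e, late = tot - e)
    },
    non_uniform_annual = {
      tot <- runif(1, t_high + eps, 1)
      e <- runif(1, t_low + eps, t_high - eps)
      c(early = e, late = tot - e)
    },
    uniformly_early_annual = {
      e <- runif(1, t_high + eps, 1)
      c(early = e, late = (1 - e) * runif(1))
    },
    uniformly_late_annual = {
      e <- runif(1, 0, t_low - eps)
      tot <- runif(1, t_high + eps, 1)
      c(early = e, late = tot - e)
    },
    annual = {
      tot <- runif(1, t_high + eps, 1)
      e <- runif(1, 0, tot)
      c(early = e, late = tot - e)
    },
    stop("unknown category: ", category)
  )
}

#' Generate a synthetic germplasm collection with known category truth
#'
#' Each accession is assigned a true flowering-habit category, then a
#' within-accession life-form composition (proportions of early-annual,
#' late-annual and biennial plants) is drawn inside that category's threshold
#' region, so truth labels are exact by construction. The aggregate label
#' `"annual"` draws any annual composition; its leaf label is derived from
#' the composition.
#'
#' @param n_accessions Number of accessions (>= 1).
#' @param category_mix Named vector of category proportions (leaf categories
#'   and/or `"annual"`); must be nonnegative and sum to 1.
#' @param concentration Positive shape of the symmetric Beta draw used for
#'   the early/late split inside mixtures; small values give extreme splits,
#'   large values balanced splits.
#' @param sd_genotype SD of an optional extra per-accession liability shift
#'   applied on the logit scale during simulation. Default 0: the
#'   composition itself carries all genotypic signal, keeping truth labels
#'   exact under zero environmental noise.
#' @param thresholds Ontology thresholds, see [habit_thresholds()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Tibble with columns `accession_id`, `true_category`,
#'   `p_early_annual`, `p_late_annual`, `p_biennial`, `genotype_effect`.
#' @export
generate_collection <- function(n_accessions,
                                category_mix = default_category_mix(),
                                concentration = 2,
                                sd_genotype = 0,
                                thresholds = habit_thresholds(),
                                seed = 1L) {
  if (n_accessions < 1) stop("n_accessions must be >= 1")
  if (is.null(names(category_mix)) || any(!nzchar(names(category_mix)))) {
    stop("category_mix must be a named vector")
  }
  known <- c(habit_leaf_categories(), "annual")
  bad <- setdiff(names(category_mix), known)
  if (length(bad) > 0) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (any(category_mix < 0)) stop("category proportions must be nonnegative")
  if (abs(sum(category_mix) - 1) > 1e-6) {
    stop("category proportions must sum to 1")
  }
  if (concentration <= 0) stop("concentration must be positive")
  t_low <- thresholds$t_low / 100
  t_high <- thresholds$t_high / 100

  ids <- sprintf("ACC%04d", seq_len(n_accessions))
  set.seed(substream_seed(seed, "collection"))
  cats <- sample(names(category_mix), n_accessions, replace = TRUE,
                 prob = category_mix)
  rows <- lapply(seq_len(n_accessions), function(i) {
    set.seed(substream_seed(seed, "composition", ids[i]))
    comp <- draw_composition(cats[i], concentration, t_low, t_high)
    g <- if (sd_genotype > 0) rnorm(1, 0, sd_genotype) else 0
    tibble::tibble(
      accession_id = ids[i],
      p_early_annual = unname(comp["early"]),
      p_late_annual = unname(comp["late"]),
      genotype_effect = g
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_biennial <- 1 - out$p_early_annual - out$p_late_annual
  ## truth label from the composition itself (resolves the "annual" aggregate)
  calls <- classify_carrotomics(100 * out$p_early_annual,
                                100 * (out$p_early_annual + out$p_late_annual),
                                thresholds = thresholds)
  out$true_category <- ifelse(calls$subcategory == "none",
                              calls$category, calls$subcategory)
  out[, c("accession_id", "true_category", "p_early_annual",
          "p_late_annual", "p_biennial", "genotype_effect")]
}

#' Ground-truth category labels of a generated collection
#'
#' Returns the generator's latent category labels; never inferred from
#' trial data.
#'
#' @param profiles Output of [generate_collection()].
#' @return Tibble with `accession_id` and `true_category`.
#' @export
truth_table <- function(profiles) {
  stopifnot(all(c("accession_id", "true_category") %in% names(profiles)))
  tibble::as_tibble(profiles[, c("accession_id", "true_category")])
}

#' Simulate a multi-year RCBD flowering trial
#'
#' For each accession x year x block plot, plants draw a life form from the
#' accession composition after the annual fractions are shifted on the logit
#' scale by genotype, year, genotype-by-year and block-within-year effects.
#' Plot records report the realized flowering fractions at 60 and 100 DAS.
#'
#' @param profiles Accession profiles from [generate_collection()].
#' @param design A [trial_design()].
#' @param env_sds Named numeric vector `c(year =, gy =, block =)` of logit-
#'   scale SDs for year, genotype-by-year and block-within-year effects.
#' @param seed Integer seed; output is byte-identical given seed and config.
#' @return Tibble with columns `accession_id`, `year`, `block`, `n_plants`,
#'   `frac60`, `frac100` (fractions in `[0, 1]`; `NA` if no plants survive).
#' @export
simulate_trial <- function(profiles,
                           design = trial_design(),
                           env_sds = c(year = 0.6, gy = 0.5, block = 0.15),
                           seed = 1L) {
  if (nrow(profiles) == 0) stop("profiles must be non-empty")
  stopifnot(inherits(design, "trial_design"))
  env_sds <- env_sds[c("year", "gy", "block")]
  if (anyNA(env_sds) || any(env_sds < 0)) {
    stop("env_sds must provide nonnegative 'year', 'gy' and 'block' SDs")
  }
  years <- design$years
  blocks <- seq_len(design$blocks_per_year)

  draw_effect <- function(sd, ...) {
    if (sd == 0) return(0)
    set.seed(substream_seed(seed, ...))
    rnorm(1, 0, sd)
  }
  year_eff <- setNames(
    vapply(years, function(y) draw_effect(env_sds[["year"]], "year", y), 0),
    years)
  block_eff <- outer(years, blocks, Vectorize(function(y, b) {
    draw_effect(env_sds[["block"]], "block", y, b)
  }))
  dimnames(block_eff) <- list(years, as.character(blocks))

  loss <- design$stand_loss_events
  out <- vector("list", nrow(profiles) * length(years) * length(blocks))
  k <- 0L
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    l_early <- qlogis(p$p_early_annual)
    l_tot <- qlogis(p$p_early_annual + p$p_late_annual)
    for (y in years) {
      gy <- draw_effect(env_sds[["gy"]], "gy", p$accession_id, y)
      for (b in blocks) {
        delta <- p$genotype_effect + year_eff[[y]] + gy +
          block_eff[y, as.character(b)]
        pe <- plogis(l_early + delta)
        ptot <- plogis(l_tot + delta)
        set.seed(substream_seed(seed, "plot", p$accession_id, y, b))
        n_emerged <- rbinom(1, design$plants_per_plot, design$emergence_rate)
        counts <- if (n_emerged > 0) {
          drop(rmultinom(1, n_emerged, c(pe, ptot - pe, 1 - ptot)))
        } else c(0L, 0L, 0L)
        n_early <- counts[1]; n_late <- counts[2]; n_bi <- counts[3]
        if (!is.null(loss) && y %in% loss$year) {
          ev <- loss[loss$year == y, ][1, ]
          s <- ev$survival_fraction
          s_early <- if (s >= 1) 1 else plogis(qlogis(s) - ev$early_bias)
          n_early <- rbinom(1, n_early, s_early)
          n_late <- rbinom(1, n_late, s)
          n_bi <- rbinom(1, n_bi, s)
        }
        n_sen <- if (design$senescence_rate > 0) {
          rbinom(1, n_early, design$senescence_rate)
        } else 0L
        n_plants <- n_early + n_late + n_bi
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          accession_id = p$accession_id, year = y, block = b,
          n_plants = as.integer(n_plants),
          frac60 = if (n_plants > 0) n_early / n_plants else NA_real_,
          frac100 = if (n_plants > 0) {
            (n_early - n_sen + n_late) / n_plants
          } else NA_real_
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a balanced Gaussian multi-year RCBD trial with known variance
#' components
#'
#' Direct draw from the random-effects model
#' `T_ijk = mu + g_i + y_j + (gy)_ij + b_k(j) + e_ijk` with independent
#' centered normal components, for calibrating variance-component and
#' heritability estimators against known truth.
#'
#' @param n_accessions,n_years,n_blocks Balanced design dimensions.
#' @param varcomps Named vector `c(Vg =, Vgy =, Vyear =, Vblock =, Verror =)`.
#' @param mu Grand mean.
#' @param seed Integer seed.
#' @return Tibble with `accession_id`, `year`, `block`, `y`.
#' @export
simulate_gaussian_trial <- function(n_accessions, n_years, n_blocks,
                                    varcomps = c(Vg = 8, Vgy = 2, Vyear = 1,
                                                 Vblock = 0.5, Verror = 4),
                                    mu = 50, seed = 1L) {
  need <- c("Vg", "Vgy", "Vyear", "Vblock", "Verror")
  stopifnot(all(need %in% names(varcomps)), all(varcomps[need] >= 0))
  set.seed(substream_seed(seed, "gaussian_trial"))
  g <- rnorm(n_accessions, 0, sqrt(varcomps[["Vg"]]))
  yr <- rnorm(n_years, 0, sqrt(varcomps[["Vyear"]]))
  gy <- matrix(rnorm(n_accessions * n_years, 0, sqrt(varcomps[["Vgy"]])),
               n_accessions, n_years)
  bl <- matrix(rnorm(n_years * n_blocks, 0, sqrt(varcomps[["Vblock"]])),
               n_years, n_blocks)
  grid <- expand.grid(i = seq_len(n_accessions), j = seq_len(n_years),
                      k = seq_len(n_blocks))
  e <- rnorm(nrow(grid), 0, sqrt(varcomps[["Verror"]]))
  tibble::tibble(
    accession_id = sprintf("ACC%04d", grid$i),
    year = sprintf("year%d", grid$j),
    block = grid$k,
    y = mu + g[grid$i] + yr[grid$j] + gy[cbind(grid$i, grid$j)] +
      bl[cbind(grid$j, grid$k)] + e
  )
}
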