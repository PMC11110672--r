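# Shared fixture builders and independent oracles.

# Literal transcription of the generalized ESD procedure: at each step
# compute R_i and lambda_i from their defining formulas, remove the extreme
# point, and take the largest significant step. Kept deliberately naive and
# separate from the package implementation.
rosner_oracle <- function(values, k, alpha = 0.05) {
  x <- values
  idx <- seq_along(values)
  R <- lambda <- numeric(k)
  removed <- integer(k)
  for (i in 1:k) {
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    devs <- abs(x - m) / s
    j <- which(devs == max(devs))[1]
    R[i] <- devs[j]
    removed[i] <- idx[j]
    x <- x[-j]
    idx <- idx[-j]
    n_i <- length(values) - i + 1
    p <- 1 - alpha / (2 * n_i)
    t_crit <- qt(p, df = n_i - 2)
    lambda[i] <- (n_i - 1) * t_crit / sqrt((n_i - 2 + t_crit^2) * n_i)
  }
  hits <- which(R > lambda)
  n_out <- if (length(hits) > 0) max(hits) else 0
  list(R = R, lambda = lambda, outliers = removed[seq_len(n_out)])
}

# Balanced single-year scored observations with known accession effects.
balanced_single_year_obs <- function(n_accessions = 6, n_blocks = 2,
                                     seed = 1, year = "y1") {
  set.seed(seed)
  acc_eff <- seq(0, 100, length.out = n_accessions)
  grid <- expand.grid(a = seq_len(n_accessions), b = seq_len(n_blocks))
  vals <- pmin(100, pmax(0, acc_eff[grid$a] + 5 * (grid$b - 1.5) +
                           rnorm(nrow(grid), 0, 3)))
  tibble::tibble(
    accession_id = sprintf("A%02d", grid$a), year = year, block = grid$b,
    pct60 = round(vals / 2, 4), pct100 = round(vals, 4)
  )
}

# The canonical 6-value worked ANOVA fixture:
# accessions A (10, 20), B (30, 40), C (50, 60) over blocks 1, 2.
toy_anova_obs <- function() {
  tibble::tibble(
    accession_id = rep(c("A", "B", "C"), each = 2),
    year = "y1",
    block = rep(1:2, 3),
    pct60 = 0,
    pct100 = c(10, 20, 30, 40, 50, 60)
  )
}

# Hand-built accession profiles (bypassing generate_collection) with the
# columns simulate_trial needs.
manual_profiles <- function(p_early, p_late, ids = NULL) {
  n <- length(p_early)
  tibble::tibble(
    accession_id = ids %||% sprintf("M%02d", seq_len(n)),
    true_category = NA_character_,
    p_early_annual = p_early,
    p_late_annual = p_late,
    p_biennial = 1 - p_early - p_late,
    genotype_effect = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
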