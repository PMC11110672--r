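## Pearson correlations of vegetative traits, grouped by flowering-habit
## category.

#' Grouped Pearson correlations of vegetative traits
#'
#' Within each flowering-habit group, computes the product-moment
#' correlation for every trait pair on pairwise-complete rows, with a
#' two-sided p-value from the t transform on `n - 2` degrees of freedom
#' and the usual star annotation. Cells with fewer than 3 complete pairs
#' are reported as `NA`.
#'
#' @param trait_table One row per accession with numeric trait columns and
#'   a grouping column (missing trait values allowed).
#' @param traits Character vector of trait column names (default: seed
#'   viability, seed weight, emergence, canopy height).
#' @param group_col Name of the grouping column (default `"category"`).
#' @param low_n Groups smaller than this get a `low_n` warning flag
#'   (correlations in tiny groups can be driven by drift/sampling noise).
#' @return Long-format tibble: `group`, `trait_a`, `trait_b`, `r`, `p`,
#'   `n`, `stars`, `low_n`.
#' @export
grouped_pearson <- function(trait_table,
                            traits = c("seed_viability", "seed_weight",
                                       "emergence", "canopy_height"),
                            group_col = "category",
                            low_n = 10L) {
  stopifnot(group_col %in% names(trait_table),
            all(traits %in% names(trait_table)))
  groups <- split(tibble::as_tibble(trait_table),
                  trait_table[[group_col]])
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (nrow(d) < 3) {
      stop("group '", g, "' has fewer than 3 rows")
    }
    if (nrow(d) < low_n) {
      warning("group '", g, "' has n = ", nrow(d),
              " (< ", low_n, "); correlations flagged low_n")
    }
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        if (j <= i) next
        xa <- d[[traits[i]]]
        xb <- d[[traits[j]]]
        ok <- complete.cases(xa, xb)
        n <- sum(ok)
        if (n >= 3 && sd(xa[ok]) > 0 && sd(xb[ok]) > 0) {
          ct <- cor.test(xa[ok], xb[ok], method = "pearson")
          r <- unname(ct$estimate)
          p <- ct$p.value
        } else {
          r <- NA_real_
          p <- NA_real_
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, trait_a = traits[i], trait_b = traits[j],
          r = r, p = p, n = n,
          stars = p_stars(p), low_n = nrow(d) < low_n
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate synthetic vegetative traits for a classified collection
#'
#' Generates per-accession seed viability, seed weight, emergence and
#' canopy height with a simple shared-factor correlation structure whose
#' strength differs by flowering-habit category (seed quality drives both
#' viability and emergence). Purely synthetic — for exercising
#' [grouped_pearson()] and the reporting pipeline, not a model of real
#' seed-lot biology.
#'
#' @param calls Habit calls from [classify_accessions()].
#' @param seed Integer seed.
#' @return Tibble: `accession_id`, `category`, `subcategory`,
#'   `seed_viability`, `seed_weight`, `emergence`, `canopy_height`.
#' @export
simulate_vegetative_traits <- function(calls, seed = 1L) {
  stopifnot(all(c("accession_id", "category", "subcategory")
                %in% names(calls)))
  n <- nrow(calls)
  set.seed(substream_seed(seed, "veg_traits"))
  quality <- rnorm(n) # latent seed-lot quality factor
  ## annuals couple viability/emergence more weakly than biennials/mixtures
  w <- ifelse(calls$category == "annual", 0.3, 0.7)
  tibble::tibble(
    accession_id = calls$accession_id,
    category = calls$category,
    subcategory = calls$subcategory,
    seed_viability = pmin(100, pmax(0, 75 + 12 * quality + 8 * rnorm(n))),
    seed_weight = exp(0.1 * quality + 0.25 * rnorm(n)), # grams/1000 seeds
    emergence = pmin(100, pmax(0, 60 + 15 * w * quality +
                                 10 * sqrt(1 - w^2) * rnorm(n))),
    canopy_height = pmax(5, 45 + 5 * quality + 7 * rnorm(n) +
                           ifelse(calls$category == "annual", 6, 0))
  )
}
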