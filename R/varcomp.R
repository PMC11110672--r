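## ANOVA, variance components, and broad-sense heritability for the RCBD
## flowering-trial models:
##   single-year: T_ik  = u + g_i + b_k + e_ik
##   multi-year:  T_ijk = u + g_i + y_j + (gy)_ij + b_k(j) + e_ijk

trait_column <- function(timepoint) {
  timepoint <- as.character(timepoint)
  if (!timepoint %in% c("60", "100")) stop("timepoint must be 60 or 100")
  paste0("pct", timepoint)
}

anova_frame <- function(observations, timepoint) {
  col <- trait_column(timepoint)
  stopifnot(all(c("accession_id", "year", "block", col)
                %in% names(observations)))
  d <- data.frame(
    y = observations[[col]],
    accession = factor(observations$accession_id),
    year = factor(observations$year),
    block = factor(observations$block)
  )
  d[!is.na(d$y), ]
}

## Type III sums of squares by explicit model comparison under sum-to-zero
## contrasts: the SS of a term is the increase in residual SS when that
## term's columns are dropped from the full model matrix (other terms
## retained). Coincides with sequential SS on balanced data. Rank-deficient
## reduced fits are handled through pivoted least squares.
type3_anova <- function(d, rhs_terms, term_labels) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  f <- stats::as.formula(paste("y ~", paste(rhs_terms, collapse = " + ")))
  mm <- stats::model.matrix(f, data = d)
  asn <- attr(mm, "assign")
  full <- stats::lm.fit(mm, d$y)
  rss_full <- sum(full$residuals^2)
  ## an exact fit leaves only rounding noise: report a hard zero so F is
  ## flagged undefined instead of astronomically inflated
  tot_ss <- sum((d$y - mean(d$y))^2)
  if (rss_full <= 1e-10 * max(tot_ss, 1)) rss_full <- 0
  df_res <- nrow(d) - full$rank
  ms_res <- if (df_res > 0) rss_full / df_res else NA_real_

  rows <- lapply(seq_along(rhs_terms), function(ti) {
    keep <- asn != ti
    red <- stats::lm.fit(mm[, keep, drop = FALSE], d$y)
    ss <- max(sum(red$residuals^2) - rss_full, 0)
    df <- full$rank - red$rank
    if (df == 0) stop("term '", rhs_terms[ti], "' has zero df")
    fval <- if (!is.na(ms_res) && ms_res > 0) (ss / df) / ms_res else NA_real_
    tibble::tibble(
      Source = unname(term_labels[rhs_terms[ti]]),
      df = as.integer(df), SS = ss, MS = ss / df, F = fval,
      p = if (is.na(fval)) NA_real_ else
        pf(fval, df, df_res, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    Source = "Residuals", df = as.integer(df_res), SS = rss_full,
    MS = ms_res, F = NA_real_, p = NA_real_
  ))
  out$stars <- p_stars(out$p)
  stopifnot(sum(out$df) == nrow(d) - 1)
  out
}

#' Single-year two-way ANOVA of flowering percentage
#'
#' Fits the fixed-effects model `T_ik = u + g_i + b_k + e_ik` (genotype and
#' block) and reports Type III sums of squares under sum-to-zero contrasts;
#' the Type III SS of a term equals the increase in residual SS when the
#' term is dropped from the full model, and coincides with sequential SS on
#' balanced data.
#'
#' @param observations Scored observations for one year.
#' @param timepoint `60` or `100` (selects `pct60` / `pct100`).
#' @return Tibble with `Source`, `df`, `SS`, `MS`, `F`, `p`, `stars`.
#' @export
anova_single_year <- function(observations, timepoint = 100) {
  d <- anova_frame(observations, timepoint)
  if (length(unique(d$year)) > 1) {
    stop("observations span multiple years; use anova_multi_year()")
  }
  if (nlevels(droplevels(d$accession)) < 2) stop("need >= 2 accessions")
  if (nlevels(droplevels(d$block)) < 2) stop("need >= 2 blocks")
  d$accession <- droplevels(d$accession)
  d$block <- droplevels(d$block)
  type3_anova(d, c("accession", "block"),
              c(accession = "Accession", block = "Block"))
}

#' Multi-year ANOVA of flowering percentage
#'
#' Fits `T_ijk = u + g_i + y_j + (gy)_ij + b_k(j) + e_ijk` (genotype, year,
#' genotype-by-year, block within year) with Type III sums of squares under
#' sum-to-zero contrasts. Year subsets (e.g. excluding a storm-damaged
#' year) are run by filtering `observations` before the call.
#'
#' @inheritParams anova_single_year
#' @return Tibble with `Source`, `df`, `SS`, `MS`, `F`, `p`, `stars`.
#' @export
anova_multi_year <- function(observations, timepoint = 100) {
  d <- anova_frame(observations, timepoint)
  d$accession <- droplevels(d$accession)
  d$year <- droplevels(d$year)
  d$block <- droplevels(d$block)
  if (nlevels(d$year) < 2) stop("need >= 2 years; use anova_single_year()")
  if (nlevels(d$accession) < 2) stop("need >= 2 accessions")
  type3_anova(d, c("accession", "year", "accession:year", "year:block"),
              c(accession = "Accession", year = "Year",
                `accession:year` = "Accession x Year",
                `year:block` = "Block within Year"))
}

## Balanced-design check: every accession x (year x) block cell exactly once.
check_balanced <- function(d, multi_year) {
  tab <- if (multi_year) table(d$accession, d$year, d$block)
         else table(d$accession, d$block)
  all(tab == 1)
}

## Closed-form mean squares on a balanced design.
balanced_mean_squares <- function(d, multi_year) {
  a <- nlevels(d$accession)
  r <- nlevels(d$block)
  m <- mean(d$y)
  ss_tot <- sum((d$y - m)^2)
  if (!multi_year) {
    mi <- tapply(d$y, d$accession, mean)
    mk <- tapply(d$y, d$block, mean)
    ss_g <- r * sum((mi - m)^2)
    ss_b <- a * sum((mk - m)^2)
    ss_e <- ss_tot - ss_g - ss_b
    df <- c(g = a - 1, b = r - 1, e = (a - 1) * (r - 1))
    list(ms = c(g = ss_g / df[["g"]], b = ss_b / df[["b"]],
                e = ss_e / df[["e"]]),
         df = df, a = a, r = r, y = 1L)
  } else {
    yn <- nlevels(d$year)
    mi <- tapply(d$y, d$accession, mean)
    mj <- tapply(d$y, d$year, mean)
    mij <- tapply(d$y, list(d$accession, d$year), mean)
    mjk <- tapply(d$y, list(d$year, d$block), mean)
    ss_g <- yn * r * sum((mi - m)^2)
    ss_y <- a * r * sum((mj - m)^2)
    ss_gy <- r * sum((sweep(sweep(mij, 1, mi), 2, mj) + m)^2)
    ss_b <- a * sum((sweep(mjk, 1, mj))^2)
    ss_e <- ss_tot - ss_g - ss_y - ss_gy - ss_b
    df <- c(g = a - 1, y = yn - 1, gy = (a - 1) * (yn - 1),
            b = yn * (r - 1), e = yn * (a - 1) * (r - 1))
    list(ms = c(g = ss_g / df[["g"]], y = ss_y / df[["y"]],
                gy = ss_gy / df[["gy"]], b = ss_b / df[["b"]],
                e = ss_e / df[["e"]]),
         df = df, a = a, r = r, y = yn)
  }
}

## REML for the all-random trial model. The fixed intercept is profiled
## out by lme4's machinery; the profiled restricted deviance is minimized
## over relative-SD parameters (nonnegativity via box constraints) with
## nlminb at tight tolerance, restarting once from the found optimum. On a
## balanced design with interior moments estimates, the moments solution
## is used as a warm start (on balanced data it is the exact REML
## stationary point, and the profiled surface around it is very flat, so a
## cold-started optimizer alone stalls several digits short).
reml_varcomp <- function(d, multi) {
  form <- if (multi) {
    y ~ 1 + (1 | accession) + (1 | year) + (1 | `accession:year`) +
      (1 | `year:block`)
  } else {
    y ~ 1 + (1 | accession) + (1 | block)
  }
  if (multi) {
    d$`accession:year` <- interaction(d$accession, d$year, drop = TRUE)
    d$`year:block` <- interaction(d$year, d$block, drop = TRUE)
  }
  lf <- lme4::lFormula(form, data = d, REML = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore"))
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  lower <- lf$reTrms$lower
  starts <- list(lf$reTrms$theta)
  if (check_balanced(d, multi)) {
    bs <- balanced_mean_squares(d, multi)
    ms <- bs$ms
    mom <- if (multi) {
      c(`accession:year` = (ms[["gy"]] - ms[["e"]]) / bs$r,
        accession = (ms[["g"]] - ms[["gy"]]) / (bs$r * bs$y),
        `year:block` = (ms[["b"]] - ms[["e"]]) / bs$a,
        year = (ms[["y"]] - ms[["gy"]] - ms[["b"]] + ms[["e"]]) /
          (bs$a * bs$r))
    } else {
      c(accession = (ms[["g"]] - ms[["e"]]) / bs$r,
        block = (ms[["b"]] - ms[["e"]]) / bs$a)
    }
    ve <- ms[["e"]]
    if (ve > 0 && all(mom > 0)) {
      starts <- c(starts,
                  list(sqrt(mom[names(lf$reTrms$flist)] / ve)))
    }
  }
  ctl <- list(abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-14,
              iter.max = 2000, eval.max = 5000)
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, devfun, lower = lower, control = ctl)
    opt <- stats::nlminb(opt$par, devfun, lower = lower, control = ctl)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (!best$convergence %in% c(0, 1)) {
    warning("REML optimizer reported non-convergence (code ",
            best$convergence, "): ", best$message)
  }
  fit <- lme4::mkMerMod(environment(devfun),
                        list(par = best$par, fval = best$objective,
                             conv = 0L),
                        lf$reTrms, lf$fr)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) NA_real_ else v
  }
  c(Vg = getv("accession"),
    Vgy = if (multi) getv("accession:year") else NA_real_,
    Vyear = if (multi) getv("year") else NA_real_,
    Vblock = if (multi) getv("year:block") else getv("block"),
    Verror = getv("Residual"))
}

truncate0 <- function(x) {
  truncated <- names(x)[!is.na(x) & x < 0]
  x[!is.na(x) & x < 0] <- 0
  list(x = x, truncated = truncated)
}

#' Estimate variance components of the flowering-trial model
#'
#' The same model as the ANOVA with all effects random. Two estimators:
#' \describe{
#'   \item{reml}{restricted maximum likelihood via a mixed-model fit
#'     (any connected design).}
#'   \item{ems_mom}{method of moments equating observed to expected mean
#'     squares on a balanced design: single-year
#'     `Vg = (MS_g - MS_e)/r`; multi-year `Vgy = (MS_gy - MS_e)/r`,
#'     `Vg = (MS_g - MS_gy)/(r*y)`.}
#' }
#' Negative method-of-moments solutions are truncated to 0 and flagged.
#' On balanced data the two estimators agree.
#'
#' @param observations Scored observations.
#' @param scope `"single_year"` or `"multi_year"`.
#' @param timepoint `60` or `100`.
#' @param method `"reml"` (default) or `"ems_mom"`.
#' @return A list of class `varcomp`: `components` (named vector `Vg`,
#'   `Vgy`, `Vyear`, `Vblock`, `Verror`; `NA` where not in the model),
#'   `n_reps`, `n_years`, `scope`, `method`, `truncated`.
#' @export
estimate_varcomp <- function(observations,
                             scope = c("multi_year", "single_year"),
                             timepoint = 100,
                             method = c("reml", "ems_mom")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  d <- anova_frame(observations, timepoint)
  d$accession <- droplevels(d$accession)
  d$year <- droplevels(d$year)
  d$block <- droplevels(d$block)
  multi <- scope == "multi_year"
  if (multi && nlevels(d$year) < 2) stop("multi_year scope needs >= 2 years")
  if (!multi && nlevels(d$year) > 1) {
    stop("single_year scope: observations span multiple years")
  }
  n_reps <- nlevels(d$block)
  n_years <- nlevels(d$year)

  if (method == "ems_mom") {
    if (!check_balanced(d, multi)) {
      stop("method 'ems_mom' requires a balanced design; use method 'reml'")
    }
    bs <- balanced_mean_squares(d, multi)
    ms <- bs$ms
    if (!multi) {
      raw <- c(Vg = (ms[["g"]] - ms[["e"]]) / bs$r,
               Vgy = NA_real_, Vyear = NA_real_,
               Vblock = (ms[["b"]] - ms[["e"]]) / bs$a,
               Verror = ms[["e"]])
    } else {
      vgy <- (ms[["gy"]] - ms[["e"]]) / bs$r
      raw <- c(Vg = (ms[["g"]] - ms[["gy"]]) / (bs$r * bs$y),
               Vgy = vgy,
               Vyear = (ms[["y"]] - ms[["gy"]] - ms[["b"]] + ms[["e"]]) /
                 (bs$a * bs$r),
               Vblock = (ms[["b"]] - ms[["e"]]) / bs$a,
               Verror = ms[["e"]])
    }
    tr <- truncate0(raw)
    comps <- tr$x
    truncated <- tr$truncated
  } else {
    comps <- reml_varcomp(d, multi)
    truncated <- character(0)
  }
  structure(
    list(components = comps, n_reps = n_reps, n_years = n_years,
         scope = scope, method = method, truncated = truncated),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Variance components (", x$scope, ", ", x$method, ")\n", sep = "")
  print(round(x$components[!is.na(x$components)], 6))
  if (length(x$truncated) > 0) {
    cat("  truncated to 0:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-year broad-sense heritability
#'
#' Entry-mean basis: `H2 = Vg / (Vg + Verror / n_reps)`.
#'
#' @param Vg,Verror Nonnegative variance components.
#' @param n_reps Number of replicates (blocks) per accession, >= 1.
#' @return A list of class `heritability_estimate` with `H2`, `scope`, and
#'   `components`.
#' @export
h2_single <- function(Vg, Verror, n_reps) {
  if (any(c(Vg, Verror) < 0)) stop("variance components must be nonnegative")
  if (n_reps < 1) stop("n_reps must be >= 1")
  denom <- Vg + Verror / n_reps
  if (denom == 0) stop("all variance components are zero: H2 undefined")
  structure(
    list(H2 = Vg / denom, scope = "single_year",
         components = c(Vg = Vg, Verror = Verror, n_reps = n_reps)),
    class = "heritability_estimate"
  )
}

#' Multi-year broad-sense heritability
#'
#' Entry-mean basis across years:
#' `H2 = Vg / (Vg + Vgy / n_years + Verror / (n_years * n_reps))`.
#'
#' @param Vg,Vgy,Verror Nonnegative variance components.
#' @param n_years Number of years, >= 2.
#' @param n_reps Replicates (blocks) per year, >= 1.
#' @return A list of class `heritability_estimate` with `H2`, `scope`, and
#'   `components`.
#' @export
h2_multi <- function(Vg, Vgy, Verror, n_years, n_reps) {
  if (any(c(Vg, Vgy, Verror) < 0)) {
    stop("variance components must be nonnegative")
  }
  if (n_years < 2) stop("n_years must be >= 2")
  if (n_reps < 1) stop("n_reps must be >= 1")
  denom <- Vg + Vgy / n_years + Verror / (n_years * n_reps)
  if (denom == 0) stop("all variance components are zero: H2 undefined")
  structure(
    list(H2 = Vg / denom, scope = "multi_year",
         components = c(Vg = Vg, Vgy = Vgy, Verror = Verror,
                        n_years = n_years, n_reps = n_reps)),
    class = "heritability_estimate"
  )
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("Broad-sense heritability (", x$scope, "): H2 = ",
      round(x$H2, 4), "\n", sep = "")
  invisible(x)
}

#' Broad-sense heritability from trial observations
#'
#' Convenience wrapper: estimates variance components
#' ([estimate_varcomp()]) and applies the entry-mean heritability formula
#' for the requested scope.
#'
#' @inheritParams estimate_varcomp
#' @return A `heritability_estimate` with the `varcomp` attached as
#'   `$varcomp`.
#' @export
heritability <- function(observations,
                         scope = c("multi_year", "single_year"),
                         timepoint = 100,
                         method = c("reml", "ems_mom")) {
  scope <- match.arg(scope)
  vc <- estimate_varcomp(observations, scope, timepoint, method)
  h <- if (scope == "single_year") {
    h2_single(vc$components[["Vg"]], vc$components[["Verror"]], vc$n_reps)
  } else {
    h2_multi(vc$components[["Vg"]], vc$components[["Vgy"]],
             vc$components[["Verror"]], vc$n_years, vc$n_reps)
  }
  h$varcomp <- vc
  h
}
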