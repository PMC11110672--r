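## Field phenotyping: 5-point plot scores, senescence anomaly flags, and
## Rosner's generalized ESD outlier screen.

#' Quantize a flowering fraction to the 5-point field scale
#'
#' Field plots are scored on a 5-point percentage scale (0, 25, 50, 75, 100)
#' by eye. Two policies model how a scorer treats very low nonzero
#' flowering:
#' \describe{
#'   \item{detect (default)}{as `nearest`, except any strictly positive
#'     fraction scores at least 25 — a 0 score then certifies that no
#'     flowering plant was observed, which the biennial category requires.}
#'   \item{nearest}{nearest multiple of 25, ties rounding away from zero.}
#' }
#'
#' @param fraction Numeric vector of flowering fractions in `[0, 1]`
#'   (NA passed through).
#' @param policy `"detect"` or `"nearest"`.
#' @return Numeric vector of scores in `{0, 25, 50, 75, 100}`.
#' @export
quantize_score <- function(fraction, policy = c("detect", "nearest")) {
  policy <- match.arg(policy)
  ok <- !is.na(fraction)
  if (any(fraction[ok] < 0 | fraction[ok] > 1)) {
    stop("fraction must be in [0, 1]")
  }
  score <- ifelse(ok, floor(fraction * 4 + 0.5) * 25, NA_real_)
  if (policy == "detect") {
    score <- ifelse(ok & fraction > 0 & score == 0, 25, score)
  }
  score
}

#' Score raw plot records on the 5-point scale
#'
#' @param records Plot records with `frac60`/`frac100` columns (see
#'   [simulate_trial()]).
#' @param policy Quantization policy, see [quantize_score()].
#' @return Tibble of scored observations: `accession_id`, `year`, `block`,
#'   `pct60`, `pct100` (plus `n_plants` if present).
#' @export
score_plots <- function(records, policy = c("detect", "nearest")) {
  policy <- match.arg(policy)
  stopifnot(all(c("accession_id", "year", "block", "frac60", "frac100")
                %in% names(records)))
  out <- tibble::as_tibble(records)
  out$pct60 <- quantize_score(out$frac60, policy)
  out$pct100 <- quantize_score(out$frac100, policy)
  keep <- intersect(c("accession_id", "year", "block", "n_plants",
                      "pct60", "pct100"), names(out))
  out[, keep]
}

#' Flag plots with a flowering decline between scoring dates
#'
#' A decline from the 60 DAS score to the 100 DAS score indicates early
#' annuals that senesced before end of season; such plots can masquerade as
#' (partly) biennial if taken at face value.
#'
#' @param observations Scored observations with `pct60`, `pct100`.
#' @return The observations with a logical `flagged` column
#'   (`pct100 < pct60`).
#' @export
detect_senescence <- function(observations) {
  stopifnot(all(c("pct60", "pct100") %in% names(observations)))
  out <- tibble::as_tibble(observations)
  out$flagged <- !is.na(out$pct60) & !is.na(out$pct100) &
    out$pct100 < out$pct60
  out
}

#' Rosner's generalized extreme Studentized deviate (ESD) outlier test
#'
#' Screens for up to `max_outliers` simultaneous outliers in a univariate
#' sample assumed approximately normal. At step i (i = 1..k) the most
#' extreme remaining point (largest `|x - mean|/sd`) gives the statistic
#' `R_i` and is set aside; `R_i` is compared with the critical value
#' `lambda_i` built from Student-t quantiles at level `alpha`. The outlier
#' set is the first `i*` removed points, where `i*` is the *largest* i with
#' `R_i > lambda_i` (this makes the procedure robust to masking).
#'
#' Results are advisory QC; nothing is deleted automatically.
#'
#' @param values Numeric vector (length >= `max_outliers + 2`, no NA).
#' @param max_outliers Maximum number of outliers tested (k >= 1).
#' @param alpha Significance level (default 0.05).
#' @return Integer vector of outlier indices into `values` (possibly
#'   empty), ordered by extremeness, with attributes `R` and `lambda`
#'   holding the k statistics and critical values.
#' @export
rosner_esd_test <- function(values, max_outliers = 3L, alpha = 0.05) {
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  k <- as.integer(max_outliers)
  if (k < 1) stop("max_outliers must be >= 1")
  if (n < k + 2) stop("need length(values) >= max_outliers + 2")
  if (sd(values) == 0) stop("constant input: sd is zero")

  remaining <- seq_len(n)
  cand <- integer(k)
  R <- lambda <- numeric(k)
  for (i in seq_len(k)) {
    x <- values[remaining]
    if (sd(x) == 0) {
      ## no dispersion left: later steps cannot implicate anything
      R[i:k] <- 0
      lambda[i:k] <- Inf
      cand[i:k] <- remaining[1]
      break
    }
    dev <- abs(x - mean(x)) / sd(x)
    j <- which.max(dev)
    R[i] <- dev[j]
    cand[i] <- remaining[j]
    ni <- n - i + 1 # sample size at this step
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, ni - 2)
    lambda[i] <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
    remaining <- remaining[-j]
  }
  n_out <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  structure(cand[seq_len(n_out)], R = R, lambda = lambda)
}
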