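#' Liability-scale transformation parameters
#'
#' Under the liability-threshold model, disease occurs when a standard
#' normal liability exceeds t = qnorm(1 - K), K the population prevalence.
#' For a case-control sample ascertained to case fraction P, a variance
#' fraction estimated on the observed 0/1 scale converts to the liability
#' scale by the factor
#'
#'   c = K^2 (1 - K)^2 / ( P (1 - P) z^2 ),   z = dnorm(t),
#'
#' which combines the observed-to-liability correction K(1-K)/z^2 with the
#' ascertainment correction K(1-K)/(P(1-P)).  When P = K (no ascertainment)
#' c reduces to K(1-K)/z^2.
#'
#' @param K population prevalence, in (0, 1).
#' @param P sample case fraction, in (0, 1).
#' @return An object of class `liability_params`: list with `K`, `P`, `t`,
#'   `z`, `c`.
#' @examples
#' liability_params(K = 0.0507, P = 0.632)
#' @export
liability_params <- function(K, P) {
  if (!is.finite(K) || K <= 0 || K >= 1) stop("K must be in (0, 1)")
  if (!is.finite(P) || P <= 0 || P >= 1) stop("P must be in (0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  structure(list(K = K, P = P, t = t, z = z,
                 c = K^2 * (1 - K)^2 / (P * (1 - P) * z^2)),
            class = "liability_params")
}

#' @export
print.liability_params <- function(x, ...) {
  cat(sprintf(
    "liability_params: K = %.4g, P = %.4g, t = %.4f, z = %.4f, c = %.4f\n",
    x$K, x$P, x$t, x$z, x$c))
  invisible(x)
}

#' Age-weighted population prevalence
#'
#' Averages an age-stratified prevalence table over the cohort: every
#' individual contributes the prevalence of the stratum containing their
#' age, and K is the mean of those contributions.
#'
#' @param ages numeric vector of ages (years).
#' @param table data.frame with columns `age_lo`, `age_hi`, `prevalence`;
#'   strata are closed intervals `[age_lo, age_hi]`, must not overlap, and
#'   must cover every supplied age.  A decade-stratum template with
#'   synthetic example rates ships as
#'   `system.file("extdata", "prevalence_by_decade_template.tsv",
#'   package = "pathpre")`; real analyses should substitute published
#'   age-specific rates.
#' @return Weighted prevalence K (scalar).
#' @examples
#' tab <- data.frame(age_lo = c(50, 70), age_hi = c(69, 99),
#'                   prevalence = c(0.05, 0.12))
#' weighted_prevalence(c(60, 60, 75, 80), tab)  # 0.085
#' @export
weighted_prevalence <- function(ages, table) {
  stopifnot(all(c("age_lo", "age_hi", "prevalence") %in% names(table)))
  if (any(table$prevalence < 0 | table$prevalence > 1))
    stop("prevalences must be in [0, 1]")
  o <- order(table$age_lo)
  table <- table[o, , drop = FALSE]
  if (nrow(table) > 1 &&
      any(table$age_lo[-1] <= table$age_hi[-nrow(table)]))
    stop("prevalence strata overlap")
  idx <- vapply(ages, function(a) {
    i <- which(a >= table$age_lo & a <= table$age_hi)
    if (length(i) != 1) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("age(s) outside all strata at individual(s): ",
         paste(utils::head(which(is.na(idx)), 5), collapse = ", "))
  mean(table$prevalence[idx])
}

#' Transform an observed-scale variance fraction to the liability scale
#'
#' Multiplies the observed-scale estimate (and, delta-method style, its SE)
#' by the factor `c` of [liability_params()].  Estimates above 1 are
#' reported with a warning, never silently clamped.
#'
#' @param h2_obs observed-scale variance fraction(s), >= 0.
#' @param params a [liability_params()].
#' @param se optional SE(s) on the observed scale, transformed by the same
#'   factor.
#' @return list with `estimate` and `se` (NULL when no SE supplied), both on
#'   the liability scale.
#' @examples
#' lp <- liability_params(K = 0.0507, P = 0.632)
#' observed_to_liability(0.10, lp)$estimate   # ~0.0916
#' @export
observed_to_liability <- function(h2_obs, params, se = NULL) {
  stopifnot(inherits(params, "liability_params"))
  if (any(h2_obs < 0)) stop("h2_obs must be >= 0")
  est <- h2_obs * params$c
  if (any(est > 1))
    warning("liability-scale estimate(s) exceed 1; reported unclamped")
  list(estimate = est, se = if (is.null(se)) NULL else se * params$c)
}

#' Per-SNP proportion of risk explained
#'
#' Divides a region set's PRE by its SNP count, so pathways of very
#' different sizes can be compared on effect per SNP.
#'
#' @param pre proportion of risk explained (any scale), >= 0.
#' @param n_snps SNP count, >= 1.
#' @return `pre / n_snps`.
#' @export
per_snp_pre <- function(pre, n_snps) {
  if (any(n_snps < 1)) stop("n_snps must be >= 1")
  pre / n_snps
}
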