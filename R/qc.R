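#' Quality-control thresholds
#'
#' Bundle of SNP and sample filter thresholds.  Defaults follow the common
#' array-QC convention for case-control GWAS: SNP call rate >= 95%, MAF >=
#' 1%, HWE p >= 1e-6, sample call rate >= 90%, autosomes only.
#'
#' @param snp_call_rate_min minimum SNP genotyping efficiency.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value.
#' @param sample_call_rate_min minimum per-sample genotyping efficiency.
#' @param autosomes_only drop non-autosomal SNPs first?
#' @param hwe_controls_only compute the HWE test in controls only (requires a
#'   `phenotype` column in the sample metadata); default uses all samples.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95, maf_min = 0.01,
                          hwe_p_min = 1e-6, sample_call_rate_min = 0.90,
                          autosomes_only = TRUE, hwe_controls_only = FALSE) {
  vals <- c(snp_call_rate_min, maf_min, hwe_p_min, sample_call_rate_min)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min,
                 autosomes_only = autosomes_only,
                 hwe_controls_only = hwe_controls_only),
            class = "qc_thresholds")
}

#' Exclusion ledger
#'
#' An ordered record of filtering steps: each step stores its label, the
#' count removed and the count remaining.  `ledger_remove()` appends a step;
#' conservation (remaining after step k = remaining before minus removed) is
#' enforced by construction and checked by `ledger_validate()`.
#'
#' @param start starting item count.
#' @param what label for the item type (informational).
#' @return An object of class `qc_ledger` (a data.frame with attributes).
#' @examples
#' led <- qc_ledger(906600, "Affymetrix SNPs")
#' led <- ledger_remove(led, "non-autosomal", 38443)
#' ledger_remaining(led)
#' @export
qc_ledger <- function(start, what = "items") {
  stopifnot(is.numeric(start), start >= 0)
  structure(data.frame(step = character(), removed = numeric(),
                       remaining = numeric()),
            start = as.numeric(start), what = what, class = c("qc_ledger", "data.frame"))
}

#' @rdname qc_ledger
#' @param ledger a `qc_ledger`.
#' @param step label of the filtering step.
#' @param removed count removed at this step.
#' @export
ledger_remove <- function(ledger, step, removed) {
  stopifnot(inherits(ledger, "qc_ledger"), removed >= 0)
  before <- ledger_remaining(ledger)
  if (removed > before)
    stop("cannot remove ", removed, " from ", before, " remaining")
  out <- rbind(as.data.frame(ledger),
               data.frame(step = step, removed = as.numeric(removed),
                          remaining = before - removed))
  attributes(out)[c("start", "what")] <- attributes(ledger)[c("start", "what")]
  class(out) <- c("qc_ledger", "data.frame")
  out
}

#' @rdname qc_ledger
#' @export
ledger_remaining <- function(ledger) {
  stopifnot(inherits(ledger, "qc_ledger"))
  if (nrow(ledger) == 0) attr(ledger, "start") else
    ledger$remaining[nrow(ledger)]
}

#' @rdname qc_ledger
#' @export
ledger_validate <- function(ledger) {
  stopifnot(inherits(ledger, "qc_ledger"))
  run <- attr(ledger, "start") - cumsum(ledger$removed)
  if (nrow(ledger) && any(run != ledger$remaining))
    stop("ledger conservation violated")
  invisible(TRUE)
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat("QC ledger (", attr(x, "what"), "), start = ",
      format(attr(x, "start"), big.mark = ","), "\n", sep = "")
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$removed <- format(df$removed, big.mark = ",")
    df$remaining <- format(df$remaining, big.mark = ",")
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square goodness-of-fit test (1 df) of observed genotype
#' counts against Hardy-Weinberg expectations computed from the sample
#' allele frequency.  Monomorphic SNPs return p = 1.  Vectorized over SNPs.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; recycled together).
#' @return Numeric vector of p-values.
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)    # total heterozygote deficit: p ~ 1.5e-23
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("at least one genotype observation required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * q
  e_aa <- n * q^2
  chi2 <- ifelse(p == 0 | q == 0, 0,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' SNP quality-control filter
#'
#' Applies SNP filters in a fixed order -- non-autosomal, call rate, MAF,
#' HWE, duplicate positions -- recording each step in an exclusion ledger.
#' MAF, call rate and HWE are computed on all retained samples (cases and
#' controls together) unless `hwe_controls_only` is set in the thresholds.
#' Duplicate positions keep one SNP per (chrom, pos); when the metadata has a
#' `platform` column, non-"affymetrix" platforms win (targeted assays
#' supersede the array copy), otherwise the first listed SNP wins.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `keep` (SNP ids retained) and `ledger` (a [qc_ledger()]).
#' @export
filter_snps <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (ncol(G$geno) == 0) stop("empty genotype matrix")
  led <- qc_ledger(ncol(G$geno), "SNPs")
  alive <- rep(TRUE, ncol(G$geno))

  if (thresholds$autosomes_only) {
    bad <- alive & !(G$snps$chrom %in% as.character(1:22))
    led <- ledger_remove(led, "non-autosomal", sum(bad))
    alive <- alive & !bad
  }
  cr <- colMeans(!is.na(G$geno))
  bad <- alive & cr < thresholds$snp_call_rate_min
  led <- ledger_remove(led, sprintf("call rate < %g", thresholds$snp_call_rate_min),
                       sum(bad))
  alive <- alive & !bad

  p <- colSums(G$geno, na.rm = TRUE) / (2 * pmax(colSums(!is.na(G$geno)), 1L))
  maf <- pmin(p, 1 - p)
  bad <- alive & maf < thresholds$maf_min
  led <- ledger_remove(led, sprintf("MAF < %g", thresholds$maf_min), sum(bad))
  alive <- alive & !bad

  hwe_rows <- seq_len(nrow(G$geno))
  if (thresholds$hwe_controls_only) {
    if (is.null(G$samples$phenotype))
      stop("hwe_controls_only requires a `phenotype` sample column")
    hwe_rows <- which(G$samples$phenotype == 0)
  }
  x <- G$geno[hwe_rows, , drop = FALSE]
  pv <- hwe_test(colSums(x == 0L, na.rm = TRUE), colSums(x == 1L, na.rm = TRUE),
                 colSums(x == 2L, na.rm = TRUE))
  bad <- alive & pv < thresholds$hwe_p_min
  led <- ledger_remove(led, sprintf("HWE p < %g", thresholds$hwe_p_min), sum(bad))
  alive <- alive & !bad

  key <- paste(G$snps$chrom, G$snps$pos)
  pref <- if (!is.null(G$snps$platform))
    order(tolower(G$snps$platform) == "affymetrix") else seq_along(key)
  keep_dup <- !duplicated(key[pref])[order(pref)]
  bad <- alive & !keep_dup
  led <- ledger_remove(led, "duplicate position", sum(bad))
  alive <- alive & !bad

  if (!any(alive)) warning("no SNPs remain after QC")
  ledger_validate(led)
  list(keep = G$snps$id[alive], ledger = led)
}

#' Sample quality-control filter
#'
#' Removes samples whose genotyping efficiency falls below the threshold,
#' then samples missing any required metadata field (e.g. `age`), recording
#' each step in an exclusion ledger.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param required_fields character vector of sample-metadata columns that
#'   must be non-missing.
#' @return list with `keep` (individual ids retained) and `ledger`.
#' @export
filter_samples <- function(G, thresholds = qc_thresholds(),
                           required_fields = character()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (nrow(G$geno) == 0) stop("empty genotype matrix")
  led <- qc_ledger(nrow(G$geno), "samples")
  alive <- rep(TRUE, nrow(G$geno))
  cr <- rowMeans(!is.na(G$geno))
  bad <- alive & cr < thresholds$sample_call_rate_min
  led <- ledger_remove(led, sprintf("call rate < %g",
                                    thresholds$sample_call_rate_min), sum(bad))
  alive <- alive & !bad
  for (f in required_fields) {
    if (is.null(G$samples[[f]]))
      stop("required field '", f, "' absent from sample metadata")
    bad <- alive & is.na(G$samples[[f]])
    led <- ledger_remove(led, paste0("missing ", f), sum(bad))
    alive <- alive & !bad
  }
  ledger_validate(led)
  list(keep = G$samples$iid[alive], ledger = led)
}

#' Replay a printed exclusion chain through the ledger machinery
#'
#' Convenience for auditing published QC narratives: applies a named vector
#' of removal counts to a starting total and returns the ledger.
#'
#' @param start starting count.
#' @param removals named numeric vector: step label -> count removed.
#' @param what item label.
#' @return A [qc_ledger()].
#' @examples
#' led <- replay_ledger(1967, c("ancestry outliers" = 12, "low call rate" = 5,
#'                              "no targeted genotyping" = 84, "no age" = 53),
#'                      what = "samples")
#' ledger_remaining(led)  # 1813
#' @export
replay_ledger <- function(start, removals, what = "items") {
  stopifnot(!is.null(names(removals)))
  led <- qc_ledger(start, what)
  for (i in seq_along(removals))
    led <- ledger_remove(led, names(removals)[i], removals[[i]])
  ledger_validate(led)
  led
}
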