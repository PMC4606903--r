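# End-to-end drivers: partition -> exclusions -> GRMs -> EM-REML -> LRT ->
# liability transform, one result row per pathway / component.

# shared plumbing: fixed-effect design from cohort covariates + GRM PCs
.design_matrix <- function(cohort, covariates, pcs = NULL) {
  n <- length(cohort$phenotype)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (v in covariates) {
    col <- cohort$covariates[[v]]
    if (is.null(col)) stop("covariate '", v, "' absent from cohort")
    X <- cbind(X, stats::setNames(data.frame(col), v))
  }
  X <- as.matrix(X)
  if (!is.null(pcs)) X <- cbind(X, pcs)
  X
}

.resolve_K <- function(cohort, K = NULL, prevalence_table = NULL) {
  if (!is.null(K) && !is.null(prevalence_table))
    stop("supply exactly one prevalence source (K or prevalence_table)")
  if (!is.null(K)) return(K)
  if (!is.null(prevalence_table))
    return(weighted_prevalence(cohort$covariates$age, prevalence_table))
  stop("supply a prevalence constant K or an age-stratified table")
}

#' Pathway partitioned-heritability analysis
#'
#' For each pathway: build the SNP partition under the requested strategy,
#' optionally carve out known risk regions and LD-excluded SNPs, compute a
#' pathway GRM and a remainder GRM, fit the two-component mixed model with
#' covariates, test the pathway component by boundary LRT, transform the
#' observed-scale fractions to the liability scale at the run's prevalence,
#' and report per-SNP PRE.  Excluded SNPs enter neither GRM.
#'
#' @param cohort a `synthetic_cohort` (or any list with `genotypes`,
#'   `phenotype`, `covariates`).
#' @param genes,dhs annotation tables (see [build_partition()]).
#' @param pathways named list: pathway -> gene-name vector.
#' @param strategy partitioning strategy (see [build_partition()]).
#' @param risk_snps optional risk-SNP table (`id`, `chrom`, `pos`).
#' @param risk_flank_bp risk-region half width in bp, or `NULL` for no risk
#'   exclusion.
#' @param ld_r2,ld_window_bp,ld_blanket_bp optional LD-exclusion settings
#'   (see [ld_exclusion()]); applied on top of the risk-region exclusion.
#' @param K population prevalence constant (exclusive with
#'   `prevalence_table`).
#' @param prevalence_table age-stratified prevalence table for
#'   [weighted_prevalence()].
#' @param covariates sample-metadata columns used as fixed effects.
#' @param n_pcs number of GRM principal components added as covariates.
#' @param seed RNG seed recorded in the output (the analysis itself is
#'   deterministic given the cohort).
#' @param ... passed to [fit_em_reml()].
#' @return data.frame, one row per pathway: SNP counts, observed- and
#'   liability-scale PRE with SEs, LRT statistic and p (raw and
#'   Bonferroni-adjusted), per-SNP PRE, convergence flag.  Attributes
#'   `liability_params`, `config` and `seed` record the run.
#' @export
run_pathway_analysis <- function(cohort, genes, pathways, dhs = NULL,
                                 strategy = "flank50", risk_snps = NULL,
                                 risk_flank_bp = NULL, ld_r2 = NULL,
                                 ld_window_bp = 500000, ld_blanket_bp = NULL,
                                 K = NULL, prevalence_table = NULL,
                                 covariates = c("age", "sex"), n_pcs = 2,
                                 seed = NULL, ...) {
  G <- cohort$genotypes
  y <- cohort$phenotype
  lp <- liability_params(.resolve_K(cohort, K, prevalence_table), mean(y))
  pcs <- if (n_pcs > 0) pca_covariates(compute_grm(G), n_pcs) else NULL
  X <- .design_matrix(cohort, covariates, pcs)
  ld_excl <- if (!is.null(risk_snps) && (!is.null(ld_r2) || !is.null(ld_blanket_bp)))
    ld_exclusion(G, risk_snps, r2_threshold = if (is.null(ld_r2)) 0.1 else ld_r2,
                 window_bp = ld_window_bp, blanket_bp = ld_blanket_bp)
  else character(0)
  rows <- lapply(names(pathways), function(pw) {
    part <- build_partition(G, genes, pathways[[pw]], strategy = strategy,
                            dhs = dhs, name = pw)
    if (!is.null(risk_snps) && !is.null(risk_flank_bp))
      part <- exclude_risk_regions(part, risk_snps, risk_flank_bp, G)
    if (length(ld_excl)) {
      part$snps_pathway <- setdiff(part$snps_pathway, ld_excl)
      part$snps_remainder <- setdiff(part$snps_remainder, ld_excl)
      part$snps_excluded <- union(part$snps_excluded,
                                  intersect(ld_excl, part$all_snps))
    }
    partition_validate(part)
    base <- data.frame(pathway = pw, strategy = strategy,
                       n_snps_pathway = length(part$snps_pathway),
                       n_snps_remainder = length(part$snps_remainder),
                       n_snps_excluded = length(part$snps_excluded))
    if (length(part$snps_pathway) == 0)
      return(cbind(base, data.frame(status = "empty", pre_obs = NA,
                                    se_obs = NA, pre_liability = NA,
                                    se_liability = NA, lrt = NA, p = NA,
                                    per_snp_pre = NA, converged = NA)))
    grms <- list(pathway = compute_grm(G, part$snps_pathway),
                 remainder = compute_grm(G, part$snps_remainder))
    fit <- fit_em_reml(y, X, grms, ...)
    lrt <- lrt_drop(y, X, grms, fit, "pathway", ...)
    obs <- fit$fractions$fraction[fit$fractions$source == "pathway"]
    se_obs <- fit$fractions$se[fit$fractions$source == "pathway"]
    li <- observed_to_liability(obs, lp, se_obs)
    cbind(base, data.frame(status = "ok", pre_obs = obs, se_obs = se_obs,
                           pre_liability = li$estimate, se_liability = li$se,
                           lrt = lrt$statistic, p = lrt$p,
                           per_snp_pre = per_snp_pre(li$estimate,
                                                     length(part$snps_pathway)),
                           converged = fit$converged))
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * sum(!is.na(out$p)))
  attr(out, "liability_params") <- lp
  attr(out, "seed") <- seed
  attr(out, "config") <- list(strategy = strategy,
                              risk_flank_bp = risk_flank_bp, ld_r2 = ld_r2,
                              ld_blanket_bp = ld_blanket_bp,
                              covariates = covariates, n_pcs = n_pcs)
  out
}

#' Known-risk-SNP partitioned analysis
#'
#' Splits the panel into a risk GRM (risk SNPs plus `flank_bp` around each,
#' inclusive) and a remainder GRM (everything else), fits both jointly and
#' reports each component's observed- and liability-scale PRE with the LRT
#' for the risk component.
#'
#' @inheritParams run_pathway_analysis
#' @param flank_bp flank included in the risk GRM: 0 (just the SNPs), 5000,
#'   50000, ...
#' @return data.frame with one row per component (`risk`, `remainder`).
#' @export
run_risk_snp_analysis <- function(cohort, risk_snps, flank_bp = 0,
                                  K = NULL, prevalence_table = NULL,
                                  covariates = c("age", "sex"), n_pcs = 2,
                                  ...) {
  G <- cohort$genotypes
  y <- cohort$phenotype
  lp <- liability_params(.resolve_K(cohort, K, prevalence_table), mean(y))
  hit <- rep(FALSE, nrow(G$snps))
  for (r in seq_len(nrow(risk_snps)))
    hit <- hit | (G$snps$chrom == as.character(risk_snps$chrom[r]) &
                    abs(G$snps$pos - risk_snps$pos[r]) <= flank_bp)
  risk_ids <- union(G$snps$id[hit], intersect(risk_snps$id, G$snps$id))
  if (!length(risk_ids)) stop("no risk SNP genotyped in the panel")
  pcs <- if (n_pcs > 0) pca_covariates(compute_grm(G), n_pcs) else NULL
  X <- .design_matrix(cohort, covariates, pcs)
  grms <- list(risk = compute_grm(G, risk_ids),
               remainder = compute_grm(G, setdiff(G$snps$id, risk_ids)))
  fit <- fit_em_reml(y, X, grms, ...)
  lrt <- lrt_drop(y, X, grms, fit, "risk", ...)
  li <- observed_to_liability(fit$fractions$fraction, lp, fit$fractions$se)
  out <- data.frame(component = fit$fractions$source,
                    n_snps = c(length(risk_ids),
                               nrow(G$snps) - length(risk_ids)),
                    pre_obs = fit$fractions$fraction,
                    se_obs = fit$fractions$se,
                    pre_liability = li$estimate, se_liability = li$se,
                    converged = fit$converged)
  attr(out, "lrt_risk") <- lrt
  attr(out, "liability_params") <- lp
  out
}

#' Pathway-overlap decomposition
#'
#' Decomposes two pathways' SNP sets (genic + flank partition by default)
#' into shared / unique-to-a / unique-to-b, fits a joint model with one GRM
#' per non-empty set plus a remainder GRM over all other SNPs, and a
#' shared-only model (shared + remainder), reporting liability-scale PRE per
#' set.  An empty overlap skips the shared component with a message.
#'
#' @inheritParams run_pathway_analysis
#' @param pathway_a,pathway_b names of the two pathways in `pathways`.
#' @return data.frame, one row per fitted component, with a `model` column
#'   (`joint` or `shared_only`).
#' @export
run_overlap_analysis <- function(cohort, genes, pathways, pathway_a, pathway_b,
                                 strategy = "flank50", dhs = NULL, K = NULL,
                                 prevalence_table = NULL,
                                 covariates = c("age", "sex"), n_pcs = 2,
                                 ...) {
  G <- cohort$genotypes
  y <- cohort$phenotype
  lp <- liability_params(.resolve_K(cohort, K, prevalence_table), mean(y))
  sets_ab <- lapply(c(pathway_a, pathway_b), function(pw)
    build_partition(G, genes, pathways[[pw]], strategy = strategy,
                    dhs = dhs, name = pw)$snps_pathway)
  ov <- overlap_sets(sets_ab[[1]], sets_ab[[2]])
  if (!length(ov$shared))
    message("pathways '", pathway_a, "' and '", pathway_b,
            "' share no SNPs; shared component skipped")
  comp_sets <- Filter(length, list(shared = ov$shared, unique_a = ov$unique_a,
                                   unique_b = ov$unique_b))
  remainder <- setdiff(G$snps$id, unique(c(sets_ab[[1]], sets_ab[[2]])))
  pcs <- if (n_pcs > 0) pca_covariates(compute_grm(G), n_pcs) else NULL
  X <- .design_matrix(cohort, covariates, pcs)
  fit_one <- function(sets, model) {
    grms <- c(lapply(sets, function(ids) compute_grm(G, ids)),
              list(remainder = compute_grm(G, remainder)))
    fit <- fit_em_reml(y, X, grms, ...)
    li <- observed_to_liability(fit$fractions$fraction, lp, fit$fractions$se)
    data.frame(model = model, component = fit$fractions$source,
               n_snps = vapply(c(sets, list(remainder = remainder)),
                               length, numeric(1)),
               pre_obs = fit$fractions$fraction, se_obs = fit$fractions$se,
               pre_liability = li$estimate, se_liability = li$se,
               converged = fit$converged)
  }
  out <- fit_one(comp_sets, "joint")
  if (length(ov$shared))
    out <- rbind(out, fit_one(comp_sets["shared"], "shared_only"))
  attr(out, "overlap") <- lapply(ov, length)
  attr(out, "liability_params") <- lp
  out
}

#' Smoker indicator from lifetime cigarette count
#'
#' An individual counts as a smoker at 100 or more lifetime cigarettes;
#' missing counts return `NA` (such individuals are excluded from
#' smoking-adjusted analyses upstream).
#'
#' @param cigarettes_lifetime numeric vector of lifetime cigarette counts.
#' @return Integer vector: 1 = smoker, 0 = non-smoker, `NA` = unknown.
#' @examples
#' smokers_flag(c(99, 100, NA))
#' @export
smokers_flag <- function(cigarettes_lifetime) {
  if (any(cigarettes_lifetime < 0, na.rm = TRUE))
    stop("cigarette counts must be >= 0")
  as.integer(cigarettes_lifetime >= 100)
}
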