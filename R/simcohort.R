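#' Specification for a synthetic case-control cohort
#'
#' Collects every tunable of the generator: population and panel size, allele
#' frequency bounds, LD block structure, liability-threshold disease model
#' with case-enriched ascertainment, causal architecture by region set, and
#' covariate effects.  Defaults emulate the cohort the pipeline targets:
#' population prevalence K = 0.05 and a sampled case fraction of 0.632.
#'
#' Liability is standard normal in the population; disease occurs when
#' liability exceeds t = qnorm(1 - K).  `causal_spec` assigns liability
#' variance fractions to named region sets (resolved against the region sets
#' passed to [simulate_phenotype()]); `covariate_effects` assigns small
#' variance fractions to simulated covariates (`sex`, `smoke`).  The
#' remaining variance is independent Gaussian noise.
#'
#' @param n_population number of individuals in the simulated population pool.
#' @param m_snps number of autosomal biallelic SNPs.
#' @param n_sample size of the ascertained analysis sample.
#' @param maf_range length-2 numeric in (0, 0.5], allele-frequency bounds.
#' @param ld_block_size SNPs per LD block (1 = all SNPs independent).
#' @param ld_rho adjacent-SNP haplotype correlation within a block, in [0, 1).
#' @param prevalence_K population disease prevalence in (0, 1).
#' @param target_case_fraction case proportion of the ascertained sample.
#' @param causal_spec named numeric vector/list: region-set label ->
#'   liability variance fraction.
#' @param covariate_effects named numeric vector/list: covariate ->
#'   liability variance fraction (supported: `sex`, `smoke`).
#' @param n_chromosomes number of chromosomes the panel is spread over.
#' @param age_case,age_control mean/SD pairs for age assigned by case status
#'   (years).
#' @param seed integer RNG seed; one stream drives every draw, in documented
#'   order (layout, annotations, haplotypes, effect sizes, covariates,
#'   residuals, ascertainment).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_population = 20000, m_snps = 2000, n_sample = 1000,
                     maf_range = c(0.05, 0.5), ld_block_size = 1, ld_rho = 0,
                     prevalence_K = 0.05, target_case_fraction = 0.632,
                     causal_spec = c(pathway = 0.35, background = 0.15),
                     covariate_effects = c(sex = 0.02, smoke = 0.03),
                     n_chromosomes = 2,
                     age_case = c(77.6, 7.9), age_control = c(70.9, 7.7),
                     seed = 1L) {
  causal_spec <- unlist(causal_spec)
  covariate_effects <- unlist(covariate_effects)
  if (length(causal_spec) && is.null(names(causal_spec)))
    stop("causal_spec must be named by region-set label")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be ordered bounds in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (prevalence_K <= 0 || prevalence_K >= 1) stop("prevalence_K must be in (0, 1)")
  if (target_case_fraction <= 0 || target_case_fraction >= 1)
    stop("target_case_fraction must be in (0, 1)")
  if (n_sample > n_population) stop("n_sample must be <= n_population")
  tot <- sum(causal_spec) + sum(covariate_effects)
  if (any(causal_spec < 0) || any(covariate_effects < 0) || tot > 1)
    stop("causal + covariate liability fractions must be >= 0 and sum to <= 1")
  if (!is.finite(seed) || abs(seed) >= 2^31)
    stop("seed must be a finite 32-bit integer")
  structure(list(n_population = as.integer(n_population),
                 m_snps = as.integer(m_snps), n_sample = as.integer(n_sample),
                 maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho, prevalence_K = prevalence_K,
                 target_case_fraction = target_case_fraction,
                 causal_spec = causal_spec,
                 covariate_effects = covariate_effects,
                 n_chromosomes = as.integer(n_chromosomes),
                 age_case = age_case, age_control = age_control,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Genome layout for a simulation
#'
#' Draws SNP positions (strictly increasing within each chromosome, mean
#' spacing ~2 kb), assigns LD blocks of `ld_block_size` consecutive SNPs, and
#' draws one allele frequency per block from `maf_range` (a shared per-block
#' frequency keeps the copying process stationary, so the adjacent-haplotype
#' correlation is exactly `ld_rho`).
#'
#' @param spec a [sim_spec()].
#' @return data.frame with columns `id`, `chrom`, `pos`, `block`, `maf`,
#'   `a1`, `a2`.
#' @export
genome_layout <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  m <- spec$m_snps
  per_chr <- diff(round(seq(0, m, length.out = spec$n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(spec$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    cumsum(sample(500:3500, k, replace = TRUE))), use.names = FALSE)
  # blocks never straddle a chromosome boundary
  block <- unlist(lapply(seq_along(per_chr), function(i) {
    k <- per_chr[i]
    paste0(i, "b", ceiling(seq_len(k) / spec$ld_block_size))
  }), use.names = FALSE)
  maf_by_block <- stats::runif(length(unique(block)),
                               spec$maf_range[1], spec$maf_range[2])
  names(maf_by_block) <- unique(block)
  data.frame(id = sprintf("snp%06d", seq_len(m)), chrom = chrom, pos = pos,
             block = block, maf = unname(maf_by_block[block]),
             a1 = "A", a2 = "B")
}

#' Simulate genotypes under HWE with optional LD blocks
#'
#' Two haplotypes per individual.  Within an LD block, each haplotype is a
#' first-order copying chain: the allele at SNP i equals the allele at SNP
#' i-1 with probability `ld_rho`, and is otherwise a fresh Bernoulli(p) draw.
#' Blocks are independent; genotype = sum of the two haplotypes.
#'
#' @param spec a [sim_spec()].
#' @param layout optional precomputed [genome_layout()]; drawn from `spec`
#'   (advancing the RNG) when `NULL`.
#' @param n number of individuals (default `spec$n_population`).
#' @param snp_subset optional SNP ids restricting which columns are generated
#'   (whole blocks containing the requested SNPs are simulated so LD is
#'   preserved; only requested columns are returned).
#' @param id_offset integer offset for generated individual ids.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(spec, layout = NULL, n = spec$n_population,
                               snp_subset = NULL, id_offset = 0L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(layout)) layout <- genome_layout(spec)
  keep <- layout$id
  if (!is.null(snp_subset)) {
    if (!all(snp_subset %in% layout$id)) stop("snp_subset not in layout")
    blocks <- unique(layout$block[layout$id %in% snp_subset])
    sim <- layout[layout$block %in% blocks, , drop = FALSE]
    keep <- snp_subset
  } else sim <- layout
  geno <- matrix(NA_integer_, n, nrow(sim))
  colnames(geno) <- sim$id
  rho <- spec$ld_rho
  # SNPs in singleton blocks (or with rho = 0) are mutually independent:
  # draw them in bulk, chunked to bound memory
  tab <- table(sim$block)
  indep <- rho == 0 | sim$block %in% names(tab)[tab == 1L]
  if (any(indep)) {
    jj <- which(indep)
    for (s in split(jj, ceiling(seq_along(jj) / 200L))) {
      pp <- rep(sim$maf[s], each = n)
      geno[, s] <- matrix(stats::rbinom(n * length(s), 2L, pp), n)
    }
  }
  for (b in unique(sim$block[!indep])) {
    j <- which(sim$block == b)
    p <- sim$maf[j[1]]
    h1 <- stats::rbinom(n, 1L, p)
    h2 <- stats::rbinom(n, 1L, p)
    geno[, j[1]] <- h1 + h2
    for (k in j[-1]) {
      if (rho > 0) {
        c1 <- stats::runif(n) < rho
        c2 <- stats::runif(n) < rho
        h1 <- ifelse(c1, h1, stats::rbinom(n, 1L, p))
        h2 <- ifelse(c2, h2, stats::rbinom(n, 1L, p))
      } else {
        h1 <- stats::rbinom(n, 1L, p)
        h2 <- stats::rbinom(n, 1L, p)
      }
      geno[, k] <- h1 + h2
    }
  }
  iid <- sprintf("ind%06d", id_offset + seq_len(n))
  genotype_matrix(geno[, match(keep, colnames(geno)), drop = FALSE],
                  layout[match(keep, layout$id), , drop = FALSE],
                  data.frame(fid = iid, iid = iid))
}

#' Simulate gene, pathway and open-chromatin annotations
#'
#' Lays `n_genes` non-overlapping genes across the simulated coordinate
#' span (one slot per gene, gene length 5-30 kb), assigns genes to pathways,
#' and scatters ~1 kb DNaseI-hypersensitive (DHS) intervals until they cover
#' approximately `dhs_density` of the span.  The default pathway layout
#' produces three pathways of which two share at least one gene, so the
#' overlap analysis is exercised.
#'
#' @param spec a [sim_spec()].
#' @param layout a [genome_layout()] (defines the coordinate span).
#' @param n_genes number of genes to place.
#' @param pathway_layout named list: pathway -> integer gene indices.  `NULL`
#'   uses the default three-pathway layout with one shared gene.
#' @param dhs_density fraction of the span covered by DHS intervals, in [0, 1].
#' @return list with elements `genes` (data.frame name/chrom/start/end),
#'   `pathways` (named list of gene-name vectors), `dhs` (data.frame
#'   chrom/start/end).
#' @export
simulate_annotations <- function(spec, layout, n_genes,
                                 pathway_layout = NULL, dhs_density = 0.1) {
  stopifnot(inherits(spec, "sim_spec"))
  chroms <- unique(layout$chrom)
  span <- vapply(chroms, function(ch) max(layout$pos[layout$chrom == ch]),
                 numeric(1))
  if (n_genes == 0) {
    genes <- data.frame(name = character(), chrom = character(),
                        start = integer(), end = integer())
    pw <- pathway_layout
    if (is.null(pw)) pw <- list(pw1 = integer(), pw2 = integer(), pw3 = integer())
    return(list(genes = genes,
                pathways = lapply(pw, function(i) character(0)),
                dhs = .sim_dhs(chroms, span, dhs_density)))
  }
  per_chr <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1)))
  glist <- list()
  gi <- 0
  for (ci in seq_along(chroms)) {
    k <- per_chr[ci]
    if (k == 0) next
    slot <- floor(span[ci] / k)
    if (slot < 30000)
      stop("coordinate space too small to place ", k, " genes on chromosome ",
           chroms[ci])
    for (s in seq_len(k)) {
      gi <- gi + 1
      len <- round(stats::runif(1, 5000, 30000))
      start <- (s - 1) * slot + sample.int(max(1L, slot - len), 1)
      glist[[gi]] <- data.frame(name = sprintf("gene%03d", gi),
                                chrom = chroms[ci],
                                start = start, end = start + len - 1)
    }
  }
  genes <- do.call(rbind, glist)
  if (is.null(pathway_layout)) {
    # three pathways; pw1 and pw2 share the middle gene
    third <- max(1L, floor(n_genes / 3))
    upper2 <- min(2L * third, n_genes)
    pathway_layout <- list(
      pw1 = seq_len(third),
      pw2 = unique(c(third, if (upper2 > third) seq(third + 1L, upper2))),
      pw3 = if (2L * third < n_genes) seq(2L * third + 1L, n_genes) else integer())
  }
  pathways <- lapply(pathway_layout, function(i) genes$name[i])
  list(genes = genes, pathways = pathways,
       dhs = .sim_dhs(chroms, span, dhs_density))
}

.sim_dhs <- function(chroms, span, density) {
  stopifnot(density >= 0, density <= 1)
  out <- list()
  for (ci in seq_along(chroms)) {
    n_iv <- floor(span[ci] * density / 1000)
    if (n_iv == 0) next
    start <- sort(sample.int(span[ci], n_iv))
    out[[ci]] <- data.frame(chrom = chroms[ci], start = start,
                            end = pmin(start + 999, span[ci]))
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Simulate a liability-threshold phenotype
#'
#' Builds liability as a sum of region-set genetic components, covariate
#' components and Gaussian noise.  Each causal region set contributes
#' `W beta` over its SNPs (W = sample-standardized genotypes, beta iid
#' normal), rescaled so the component's realized variance equals its
#' specified fraction; covariates (`sex` ~ Bernoulli(0.5), `smoke` ~
#' Bernoulli(0.55)) likewise.  Residual variance is the complement, so
#' marginal liability variance is ~1.  Disease = liability > qnorm(1 - K).
#' Age is assigned conditional on case status (means/SDs from `spec`), so
#' age-stratified prevalence weighting can be exercised downstream.
#'
#' @param G a [genotype_matrix()] for the population.
#' @param spec a [sim_spec()]; `spec$causal_spec` labels must appear in
#'   `region_sets`.
#' @param region_sets named list: region-set label -> SNP ids in `G`.
#' @return An object of class `synthetic_cohort`: list with `genotypes`,
#'   `phenotype` (0/1), `liability`, `covariates` (fid, iid, age, sex,
#'   smoke), `truth` (realized variance fraction per component), `spec`.
#' @export
simulate_phenotype <- function(G, spec, region_sets) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "sim_spec"))
  n <- nrow(G$geno)
  cs <- spec$causal_spec
  cs <- cs[cs > 0]
  if (length(cs) && !all(names(cs) %in% names(region_sets)))
    stop("causal region set(s) missing from region_sets: ",
         paste(setdiff(names(cs), names(region_sets)), collapse = ", "))
  comps <- list()
  for (lab in names(cs)) {
    ids <- region_sets[[lab]]
    if (!length(ids)) stop("causal region set '", lab, "' is empty")
    g <- .genetic_component(G, ids)
    comps[[lab]] <- g * sqrt(cs[[lab]]) / stats::sd(g)
  }
  ce <- spec$covariate_effects
  sex <- stats::rbinom(n, 1L, 0.5)
  smoke <- stats::rbinom(n, 1L, 0.55)
  cov_vals <- list(sex = sex, smoke = smoke)
  for (lab in names(ce)[ce > 0]) {
    v <- cov_vals[[lab]]
    if (is.null(v)) stop("unsupported covariate effect: ", lab)
    z <- (v - mean(v))
    comps[[paste0("cov_", lab)]] <- z * sqrt(ce[[lab]]) / stats::sd(z)
  }
  resid_frac <- 1 - sum(cs) - sum(ce[names(ce) %in% names(cov_vals) & ce > 0])
  e <- stats::rnorm(n)
  comps[["residual"]] <- e * sqrt(resid_frac) / stats::sd(e)
  liability <- Reduce(`+`, comps)
  status <- as.integer(liability > stats::qnorm(1 - spec$prevalence_K))
  vl <- stats::var(liability)
  truth <- vapply(comps, function(x) stats::var(x) / vl, numeric(1))
  age <- ifelse(status == 1,
                stats::rnorm(n, spec$age_case[1], spec$age_case[2]),
                stats::rnorm(n, spec$age_control[1], spec$age_control[2]))
  structure(list(genotypes = G, phenotype = status, liability = liability,
                 covariates = data.frame(fid = G$samples$fid,
                                         iid = G$samples$iid,
                                         age = age, sex = sex, smoke = smoke),
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

# W beta over a SNP id set, chunked so population-scale standardized
# genotypes are never all in memory at once
.genetic_component <- function(G, ids, chunk = 500L) {
  j <- match(ids, G$snps$id)
  if (anyNA(j)) stop("region set contains SNPs absent from genotypes")
  beta <- stats::rnorm(length(j))
  g <- numeric(nrow(G$geno))
  for (s in split(seq_along(j), ceiling(seq_along(j) / chunk))) {
    x <- G$geno[, j[s], drop = FALSE]
    p <- colMeans(x, na.rm = TRUE) / 2
    keep <- p > 0 & p < 1
    if (!any(keep)) next
    w <- scale(x[, keep, drop = FALSE], center = 2 * p[keep],
               scale = sqrt(2 * p[keep] * (1 - p[keep])))
    w[is.na(w)] <- 0
    g <- g + as.numeric(w %*% beta[s][keep])
  }
  if (stats::sd(g) == 0) stop("degenerate genetic component (all monomorphic?)")
  g
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$phenotype), "individuals,",
      ncol(x$genotypes$geno), "SNPs; case fraction",
      sprintf("%.3f", mean(x$phenotype)), "\n")
  cat("  realized variance fractions:",
      paste(sprintf("%s=%.3f", names(x$truth), x$truth), collapse = ", "), "\n")
  invisible(x)
}

#' Ascertain a case-enriched analysis sample
#'
#' Samples without replacement from the population cohort so the returned
#' sample has exactly `round(n_sample * target_case_fraction)` cases.
#'
#' @param cohort a population-level `synthetic_cohort`
#'   (from [simulate_phenotype()]).
#' @param target_case_fraction sample case proportion (default from the
#'   cohort's spec).
#' @param n_sample sample size (default from the cohort's spec).
#' @return A `synthetic_cohort` restricted to the sampled individuals, with
#'   the population `truth` carried over.
#' @export
ascertain <- function(cohort, target_case_fraction = cohort$spec$target_case_fraction,
                      n_sample = cohort$spec$n_sample) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n_cases <- round(n_sample * target_case_fraction)
  n_ctrl <- n_sample - n_cases
  ci <- which(cohort$phenotype == 1)
  ui <- which(cohort$phenotype == 0)
  if (length(ci) < n_cases)
    stop("insufficient cases in population pool (", length(ci), " < ",
         n_cases, ")")
  if (length(ui) < n_ctrl)
    stop("insufficient controls in population pool (", length(ui), " < ",
         n_ctrl, ")")
  take <- sort(c(ci[sample.int(length(ci), n_cases)],
                 ui[sample.int(length(ui), n_ctrl)]))
  out <- cohort
  out$genotypes <- subset_genotypes(cohort$genotypes, samples = take)
  out$phenotype <- cohort$phenotype[take]
  out$liability <- cohort$liability[take]
  out$covariates <- cohort$covariates[take, , drop = FALSE]
  rownames(out$covariates) <- NULL
  out
}

#' Simulate a full ascertained cohort
#'
#' End-to-end generator: layout, annotations, population genotypes,
#' liability-threshold phenotype, case-enriched ascertainment.  All
#' randomness comes from one stream seeded with `spec$seed`.
#'
#' When `region_sets` is `NULL`, causal-spec labels are resolved against the
#' simulated pathways (genic + 50 kb flank partition), with the label
#' `background` meaning all SNPs outside every pathway.
#'
#' For large populations the generator runs in two stages: population
#' genotypes are simulated only for LD blocks containing causal SNPs (these
#' determine liability and hence selection), and the remaining, phenotype-
#' independent blocks are filled in for the ascertained sample only.  The
#' joint distribution of the returned sample is identical to full-population
#' simulation because independent blocks are unaffected by selection.
#'
#' @param spec a [sim_spec()].
#' @param region_sets optional named list of SNP id vectors defining causal
#'   region sets directly (bypasses annotation-derived sets).
#' @param n_genes genes to simulate when deriving sets from annotations.
#' @param dhs_density DHS coverage for [simulate_annotations()].
#' @return A `synthetic_cohort` for the ascertained sample, with extra
#'   elements `layout`, `annotations`, `region_sets`.
#' @export
simulate_cohort <- function(spec, region_sets = NULL, n_genes = 30,
                            dhs_density = 0.1) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  layout <- genome_layout(spec)
  ann <- simulate_annotations(spec, layout, n_genes, dhs_density = dhs_density)
  if (is.null(region_sets)) {
    region_sets <- lapply(ann$pathways, function(gn) {
      part <- build_partition(layout, ann$genes, gn, strategy = "flank50")
      part$snps_pathway
    })
    region_sets$background <- setdiff(layout$id,
                                      unique(unlist(region_sets)))
  }
  causal_ids <- unique(unlist(
    region_sets[names(spec$causal_spec)[spec$causal_spec > 0]]))
  stage1 <- if (length(causal_ids)) {
    blocks <- unique(layout$block[layout$id %in% causal_ids])
    layout$id[layout$block %in% blocks]
  } else layout$id[0]
  if (!length(stage1)) stage1 <- layout$id[1]  # null model: any block will do
  Gpop <- simulate_genotypes(spec, layout, n = spec$n_population,
                             snp_subset = stage1)
  pop <- simulate_phenotype(Gpop, spec, region_sets)
  samp <- ascertain(pop)
  rest <- setdiff(layout$id, stage1)
  if (length(rest)) {
    Grest <- simulate_genotypes(spec, layout, n = spec$n_sample,
                                snp_subset = rest)
    geno <- cbind(samp$genotypes$geno, Grest$geno)
    ord <- match(layout$id, colnames(geno))
    samp$genotypes <- genotype_matrix(geno[, ord, drop = FALSE], layout,
                                      samp$genotypes$samples)
  }
  samp$layout <- layout
  samp$annotations <- ann
  samp$region_sets <- region_sets
  samp
}
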