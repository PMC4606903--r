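test_that("spec validation catches impossible settings", {
  expect_error(sim_spec(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_spec(ld_rho = 1), "ld_rho")
  expect_error(sim_spec(n_population = 100, n_sample = 200), "n_sample")
  expect_error(sim_spec(causal_spec = c(a = 0.7, b = 0.4)), "sum")
  expect_error(sim_spec(prevalence_K = 0), "prevalence_K")
})

test_that("genotypes are HWE draws with the requested LD structure", {
  # independent SNPs: near-zero genotype correlation
  spec0 <- sim_spec(n_population = 3000, m_snps = 2, n_sample = 100,
                    maf_range = c(0.3, 0.4), ld_rho = 0, seed = 51)
  set.seed(51)
  G0 <- simulate_genotypes(spec0, n = 3000)
  expect_lt(abs(cor(G0$geno[, 1], G0$geno[, 2])), 3 / sqrt(3000))
  # maf fixed at 0.5: genotype mean 1 within 3 SE
  spec5 <- sim_spec(n_population = 4000, m_snps = 5, n_sample = 100,
                    maf_range = c(0.5, 0.5), seed = 52)
  set.seed(52)
  G5 <- simulate_genotypes(spec5, n = 4000)
  se <- sqrt(0.5) / sqrt(4000)   # var of a genotype mean = 2pq/n
  expect_true(all(abs(colMeans(G5$geno) - 1) < 3 * se))
  # block copying: adjacent-SNP genotype correlation ~ ld_rho
  spec9 <- sim_spec(n_population = 10000, m_snps = 2, n_sample = 100,
                    ld_block_size = 2, ld_rho = 0.9, n_chromosomes = 1,
                    maf_range = c(0.2, 0.5), seed = 53)
  set.seed(53)
  G9 <- simulate_genotypes(spec9, n = 10000)
  expect_lt(abs(cor(G9$geno[, 1], G9$geno[, 2]) - 0.9), 0.05)
  # positions strictly increasing per chromosome; reproducible given seed
  spec <- sim_spec(m_snps = 200, n_sample = 10, n_population = 50,
                   n_chromosomes = 2, seed = 54)
  set.seed(54); A <- simulate_genotypes(spec, n = 50)
  set.seed(54); B <- simulate_genotypes(spec, n = 50)
  expect_identical(A$geno, B$geno)
  for (ch in unique(A$snps$chrom))
    expect_true(all(diff(A$snps$pos[A$snps$chrom == ch]) > 0))
})

test_that("annotations place genes, guarantee a shared gene, scale DHS", {
  spec <- sim_spec(m_snps = 500, n_sample = 10, n_population = 50, seed = 55)
  set.seed(55)
  lay <- genome_layout(spec)
  ann <- simulate_annotations(spec, lay, n_genes = 12, dhs_density = 0.1)
  expect_equal(nrow(ann$genes), 12)
  expect_true(all(ann$genes$start <= ann$genes$end))
  # default layout shares at least one gene between two pathways
  shared <- intersect(ann$pathways$pw1, ann$pathways$pw2)
  expect_gte(length(shared), 1)
  # overlap of the derived SNP sets is nonempty for the sharing pair
  p1 <- build_partition(lay, ann$genes, ann$pathways$pw1, "flank50")
  p2 <- build_partition(lay, ann$genes, ann$pathways$pw2, "flank50")
  ov <- overlap_sets(p1$snps_pathway, p2$snps_pathway)
  expect_gte(length(ov$shared), 1)
  # zero genes: empty map, empty pathways
  ann0 <- simulate_annotations(spec, lay, n_genes = 0)
  expect_equal(nrow(ann0$genes), 0)
  expect_true(all(lengths(ann0$pathways) == 0))
  # dhs_density 0: strategy 3 degenerates to strategy 2
  ann_nodhs <- simulate_annotations(spec, lay, n_genes = 8, dhs_density = 0)
  s2 <- build_partition(lay, ann_nodhs$genes, ann_nodhs$pathways$pw1,
                        "flank50")
  s3 <- build_partition(lay, ann_nodhs$genes, ann_nodhs$pathways$pw1,
                        "flank50_dhs", dhs = ann_nodhs$dhs)
  expect_setequal(s2$snps_pathway, s3$snps_pathway)
})

test_that("liability threshold yields the specified prevalence and truths", {
  spec <- sim_spec(n_population = 200000, m_snps = 60, n_sample = 100,
                   prevalence_K = 0.05,
                   causal_spec = c(pathway = 0.3),
                   covariate_effects = c(sex = 0.02), seed = 56)
  set.seed(56)
  lay <- genome_layout(spec)
  G <- simulate_genotypes(spec, lay, n = 200000)
  ph <- simulate_phenotype(G, spec, list(pathway = lay$id[1:30]))
  # binomial oracle: 200000 * 0.05 = 10000 cases, SE = sqrt(n K (1-K)) ~ 69
  expect_lt(abs(sum(ph$phenotype) - 10000), 3 * sqrt(200000 * 0.05 * 0.95))
  expect_equal(var(ph$liability), 1, tolerance = 0.02)
  expect_equal(unname(ph$truth["pathway"]), 0.3, tolerance = 0.02)
  # K = 0.5 puts the threshold at zero: half the population affected
  spec5 <- sim_spec(n_population = 50000, m_snps = 20, n_sample = 100,
                    prevalence_K = 0.5, causal_spec = c(p = 0.2), seed = 57)
  set.seed(57)
  lay5 <- genome_layout(spec5)
  G5 <- simulate_genotypes(spec5, lay5, n = 50000)
  ph5 <- simulate_phenotype(G5, spec5, list(p = lay5$id[1:10]))
  expect_lt(abs(mean(ph5$phenotype) - 0.5), 3 * sqrt(0.25 / 50000))
  # all-zero causal spec: phenotype independent of genotype
  spec0 <- sim_spec(n_population = 5000, m_snps = 50, n_sample = 100,
                    causal_spec = c(), covariate_effects = c(), seed = 58)
  set.seed(58)
  lay0 <- genome_layout(spec0)
  G0 <- simulate_genotypes(spec0, lay0, n = 5000)
  ph0 <- simulate_phenotype(G0, spec0, list())
  w <- scale(G0$geno[, 1:10])
  cors <- abs(cor(w, ph0$phenotype))
  expect_lt(max(cors), 4.5 / sqrt(5000))
})

test_that("ascertainment hits the target case count exactly and reproducibly", {
  spec <- sim_spec(n_population = 30000, m_snps = 40, n_sample = 1813,
                   prevalence_K = 0.1, target_case_fraction = 0.6316,
                   causal_spec = c(p = 0.2), seed = 59)
  set.seed(59)
  lay <- genome_layout(spec)
  G <- simulate_genotypes(spec, lay, n = 30000)
  ph <- simulate_phenotype(G, spec, list(p = lay$id[1:20]))
  set.seed(99)
  samp <- ascertain(ph)
  # round(1813 * 0.6316) = 1145 cases, 668 controls
  expect_equal(sum(samp$phenotype == 1), 1145)
  expect_equal(sum(samp$phenotype == 0), 668)
  expect_equal(length(samp$phenotype), 1813)
  set.seed(99)
  samp2 <- ascertain(ph)
  expect_identical(samp$genotypes$samples$iid, samp2$genotypes$samples$iid)
  # all-cases sampling
  set.seed(100)
  allc <- ascertain(ph, target_case_fraction = 0.999, n_sample = 1000)
  expect_equal(sum(allc$phenotype), 999)
  expect_error(ascertain(ph, n_sample = 200000), "insufficient")
  # age assigned by status follows the configured means
  expect_gt(mean(samp$covariates$age[samp$phenotype == 1]),
            mean(samp$covariates$age[samp$phenotype == 0]))
})

test_that("simulate_cohort composes the stages deterministically", {
  spec <- sim_spec(n_population = 4000, m_snps = 300, n_sample = 400,
                   prevalence_K = 0.1, target_case_fraction = 0.6,
                   causal_spec = c(pw1 = 0.3), seed = 60)
  co <- simulate_cohort(spec, n_genes = 12)
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(dim(co$genotypes$geno), c(400, 300))
  expect_equal(mean(co$phenotype), 0.6)
  expect_equal(colnames(co$genotypes$geno), co$layout$id)
  co2 <- simulate_cohort(spec, n_genes = 12)
  expect_identical(co$genotypes$geno, co2$genotypes$geno)
  expect_identical(co$phenotype, co2$phenotype)
})
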