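# one small deterministic fixture used across partition tests
ann_fixture <- function() {
  snps <- data.frame(
    id = sprintf("s%02d", 1:12), chrom = "1",
    pos = c(49999L, 50000L, 70001L, 100000L, 110000L, 120000L, 170000L,
            170001L, 250000L, 370000L, 370001L, 900000L))
  genes <- data.frame(name = c("gA", "gB"), chrom = "1",
                      start = c(100000L, 600000L), end = c(120000L, 610000L))
  dhs <- data.frame(chrom = "1", start = c(249500L, 899000L),
                    end = c(250500L, 901000L))
  list(snps = snps, genes = genes, dhs = dhs)
}

test_that("flank and annulus boundaries are inclusive exactly as documented", {
  fx <- ann_fixture()
  # gene gA = [100000, 120000]; 50 kb flank reaches [50000, 170000]
  p2 <- build_partition(fx$snps, fx$genes, "gA", strategy = "flank50")
  expect_true("s03" %in% p2$snps_pathway)    # distance 49,999
  expect_true("s02" %in% p2$snps_pathway)    # distance exactly 50,000
  expect_false("s01" %in% p2$snps_pathway)   # distance 50,001
  expect_true("s07" %in% p2$snps_pathway)    # 120000 + 50000 boundary
  expect_false("s08" %in% p2$snps_pathway)   # one past the boundary
  # strategy 3: annulus (50 kb, 250 kb] requires DHS membership
  p3 <- build_partition(fx$snps, fx$genes, "gA", strategy = "flank50_dhs",
                        dhs = fx$dhs)
  expect_true("s09" %in% p3$snps_pathway)    # distance 130,000, inside DHS
  expect_false("s10" %in% p3$snps_pathway)   # distance 250,000 but no DHS
  expect_false("s12" %in% p3$snps_pathway)   # in DHS but beyond 250 kb of gA
  # s08 (distance 50,001) is in the annulus but outside every DHS interval
  expect_false("s08" %in% p3$snps_pathway)
})

test_that("strategies nest and partitions tile the panel", {
  set.seed(31)
  for (rep in 1:4) {
    n_snps <- 400
    snps <- data.frame(id = sprintf("s%03d", 1:n_snps), chrom = "1",
                       pos = sort(sample.int(4e6, n_snps)))
    genes <- data.frame(name = paste0("g", 1:6), chrom = "1",
                        start = sort(sample.int(3.5e6, 6)))
    genes$end <- genes$start + sample(5000:30000, 6)
    genes <- genes[order(genes$start), ]
    dhs_start <- sort(sample.int(4e6, 120))
    dhs <- data.frame(chrom = "1", start = dhs_start, end = dhs_start + 999L)
    pw <- paste0("g", sample(6, 3))
    sets <- lapply(c("genic", "flank50", "flank50_dhs"), function(st)
      build_partition(snps, genes, pw, strategy = st, dhs = dhs))
    expect_true(all(sets[[1]]$snps_pathway %in% sets[[2]]$snps_pathway))
    expect_true(all(sets[[2]]$snps_pathway %in% sets[[3]]$snps_pathway))
    for (s in sets) expect_true(partition_validate(s))
  }
})

test_that("partition membership agrees with the brute-force distance scan", {
  set.seed(32)
  for (rep in 1:3) {
    snps <- data.frame(id = sprintf("s%03d", 1:300),
                       chrom = sample(c("1", "2"), 300, replace = TRUE),
                       pos = sample.int(3e6, 300))
    snps <- snps[order(snps$chrom, snps$pos), ]
    genes <- data.frame(name = paste0("g", 1:5),
                        chrom = sample(c("1", "2"), 5, replace = TRUE),
                        start = sample.int(2.5e6, 5))
    genes$end <- genes$start + sample(5000:40000, 5)
    dhs_start <- sort(sample.int(3e6, 80))
    dhs <- data.frame(chrom = sample(c("1", "2"), 80, replace = TRUE),
                      start = dhs_start, end = dhs_start + 1500L)
    pw <- paste0("g", 1:3)
    for (st in c("genic", "flank50", "flank50_dhs")) {
      got <- build_partition(snps, genes, pw, strategy = st,
                             dhs = dhs)$snps_pathway
      want <- brute_partition(snps, genes, pw, st, dhs = dhs)
      expect_setequal(got, want)
    }
  }
})

test_that("empty pathways and unresolved gene names degrade gracefully", {
  fx <- ann_fixture()
  p <- build_partition(fx$snps, fx$genes, character(0), strategy = "genic")
  expect_length(p$snps_pathway, 0)
  expect_setequal(p$snps_remainder, fx$snps$id)
  p2 <- build_partition(fx$snps, fx$genes, c("gA", "ghost"), strategy = "genic")
  expect_equal(p2$unresolved, "ghost")
  expect_setequal(p2$snps_pathway, c("s04", "s05", "s06"))
})

test_that("risk-region exclusion removes SNPs from both sets, inclusively", {
  fx <- ann_fixture()
  part <- build_partition(fx$snps, fx$genes, "gA", strategy = "flank50")
  risk <- data.frame(id = "rs1", chrom = "1", pos = 105000L)
  # 5 kb flank: [100000, 110000] inclusive
  out <- exclude_risk_regions(part, risk, 5000, fx$snps)
  expect_setequal(out$snps_excluded, c("s04", "s05"))
  expect_false(any(out$snps_excluded %in% out$snps_pathway))
  expect_false(any(out$snps_excluded %in% out$snps_remainder))
  expect_true(partition_validate(out))
  # boundary: risk at 1,000,000 with 5 kb flank keeps 1,005,001, drops 1,004,999
  snps <- data.frame(id = c("a", "b", "c"), chrom = "1",
                     pos = c(1004999L, 1005000L, 1005001L))
  part2 <- build_partition(snps, fx$genes, character(0), strategy = "genic")
  out2 <- exclude_risk_regions(part2, data.frame(id = "rs2", chrom = "1",
                                                 pos = 1000000L), 5000, snps)
  expect_setequal(out2$snps_excluded, c("a", "b"))
  # flank 0 with an ungenotyped risk SNP changes nothing
  out3 <- exclude_risk_regions(part2, data.frame(id = "rs9", chrom = "1",
                                                 pos = 2000000L), 0, snps)
  expect_length(out3$snps_excluded, 0)
})

test_that("LD exclusion thresholds act on the sample r-squared", {
  set.seed(33)
  n <- 600
  base <- rbinom(n, 2, 0.4)
  # constructed comparators: a duplicate (r2 = 1), an independent SNP, and
  # a weakly correlated SNP built by copying with small probability
  mix <- ifelse(runif(n) < 0.12, base, rbinom(n, 2, 0.4))
  geno <- cbind(risk = base, dup = base, ind = rbinom(n, 2, 0.4), weak = mix,
                mono = rep(1L, n), far = rbinom(n, 2, 0.4))
  snps <- data.frame(id = colnames(geno), chrom = "1",
                     pos = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6, 5e6))
  G <- genotype_matrix(geno, snps)
  risk <- data.frame(id = "risk", chrom = "1", pos = 1e6)
  r2_weak <- cor(base, mix)^2
  expect_gt(r2_weak, 0.001)   # fixture sanity
  for (thr in c(0.10, 0.05, 0.01)) {
    ex <- ld_exclusion(G, risk, r2_threshold = thr)
    expect_true(all(c("risk", "dup") %in% ex))   # r2 = 1 always excluded
    expect_false("far" %in% ex)                  # outside the 500 kb window
    expect_false("mono" %in% ex)                 # monomorphic: r2 defined 0
    expect_equal("weak" %in% ex, r2_weak >= thr)
  }
  # blanket mode ignores LD entirely
  ex_blanket <- ld_exclusion(G, risk, blanket_bp = 1e6)
  expect_setequal(ex_blanket, c("risk", "dup", "ind", "weak", "mono"))
})

test_that("overlap decomposition is an exact set partition", {
  ov <- overlap_sets(sprintf("a%d", 1:10), sprintf("a%d", 6:15))
  expect_setequal(ov$shared, sprintf("a%d", 6:10))
  expect_length(ov$unique_a, 5)
  expect_length(ov$unique_b, 5)
  expect_length(overlap_sets(c("x"), c("y"))$shared, 0)
  same <- overlap_sets(c("p", "q"), c("q", "p"))
  expect_length(same$unique_a, 0)
  expect_setequal(same$shared, c("p", "q"))
  # |A| = 1343 with |shared| = 955 leaves 388 unique to A
  A <- sprintf("v%04d", 1:1343)
  B <- c(sprintf("v%04d", 1:955), sprintf("w%04d", 1:500))
  expect_length(overlap_sets(A, B)$unique_a, 388)
})
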