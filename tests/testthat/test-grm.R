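test_that("worked 3x2 example matches the hand computation", {
  # standardized scores (x-1)/sqrt(0.5): individual 1 = (-r, r),
  # individual 3 = (r, -r) with r = sqrt(2); A13 = -2, A12 = 0, diag = 2,0,2
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3,
                              dimnames = list(NULL, c("s1", "s2"))))
  A <- compute_grm(g)$A
  expect_equal(A[1, 3], -2.0)
  expect_equal(A[1, 2], 0.0)
  expect_equal(A[1, 1], 2.0)
  expect_equal(A[2, 2], 0.0)  # heterozygous everywhere: standardized score 0
  expect_equal(A, t(A))
})

test_that("grm agrees with the naive double-loop oracle", {
  set.seed(21)
  for (rep in 1:3) {
    x <- sapply(runif(50, 0.1, 0.5), function(p) rbinom(20, 2, p))
    x[sample(length(x), 30)] <- NA   # exercise mean imputation
    G <- genotype_matrix(matrix(as.integer(x), 20, 50,
                                dimnames = list(NULL, sprintf("s%02d", 1:50))))
    expect_equal(max(abs(compute_grm(G)$A - naive_grm(x))), 0,
                 tolerance = 1e-6)
  }
})

test_that("allele frequencies handle missing data and degenerate SNPs", {
  g <- genotype_matrix(matrix(c(0L, 0L, 1L, NA), ncol = 1,
                              dimnames = list(NULL, "s1")))
  expect_equal(unname(allele_frequencies(g)), 1 / 6)
  g2 <- genotype_matrix(matrix(c(2L, 2L, 2L), ncol = 1,
                               dimnames = list(NULL, "s1")))
  expect_equal(unname(allele_frequencies(g2)), 1.0)
  g3 <- genotype_matrix(matrix(c(NA, NA, 1L, 1L), ncol = 2,
                               dimnames = list(NULL, c("bad", "ok"))))
  expect_error(allele_frequencies(g3), "bad")
})

test_that("row sums vanish and disjoint subsets average by SNP count", {
  set.seed(22)
  G <- rand_panel(25, 60)
  gr <- compute_grm(G)
  # in-sample standardization: column sums of W are 0, so row sums of A are 0
  expect_lt(max(abs(rowSums(gr$A))), 1e-8)
  expect_equal(mean(diag(gr$A)), 1, tolerance = 0.25)
  a <- G$snps$id[1:25]
  b <- G$snps$id[26:60]
  ga <- compute_grm(G, a)
  gb <- compute_grm(G, b)
  # exact identity: union GRM = SNP-count-weighted average of subset GRMs
  expect_equal(gr$A, (ga$m * ga$A + gb$m * gb$A) / (ga$m + gb$m),
               tolerance = 1e-12)
  # identical genotype rows give A_jk = A_jj = A_kk
  x <- G$geno
  x[2, ] <- x[1, ]
  gdup <- compute_grm(genotype_matrix(x, G$snps))
  expect_equal(gdup$A[1, 2], gdup$A[1, 1])
  expect_equal(gdup$A[2, 2], gdup$A[1, 1])
})

test_that("monomorphic SNPs are dropped with a warning", {
  x <- cbind(a = c(0L, 1L, 2L, 1L), b = c(2L, 2L, 2L, 2L))
  G <- genotype_matrix(x)
  expect_warning(gr <- compute_grm(G), "monomorphic")
  expect_equal(gr$m, 1)
  expect_equal(gr$snps, "a")
})

test_that("binary GRM triplet round-trips and validates sizes", {
  set.seed(23)
  G <- rand_panel(7, 40)
  gr <- suppressWarnings(compute_grm(G))  # n = 7: chance monomorphic SNPs
  pre <- file.path(tempdir(), "rt")
  write_grm(gr, pre)
  # n = 7 -> exactly n(n+1)/2 = 28 float32 values
  expect_equal(file.size(paste0(pre, ".grm.bin")), 28 * 4)
  back <- read_grm(pre)
  expect_equal(back$A, gr$A, tolerance = 1e-6)   # float32 precision
  expect_equal(back$N, gr$N, tolerance = 1e-6)
  expect_equal(back$ids$iid, gr$ids$iid)
  # worked example survives the round trip exactly (values are float32-exact)
  g3 <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3,
                               dimnames = list(NULL, c("s1", "s2"))))
  write_grm(compute_grm(g3), pre)
  expect_equal(read_grm(pre)$A[1, 3], -2.0)
  # id / payload size mismatch is a format error
  ids <- utils::read.table(paste0(pre, ".grm.id"))
  utils::write.table(rbind(ids, c("x", "x"), c("y", "y")),
                     paste0(pre, ".grm.id"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  expect_error(read_grm(pre), "format")
})
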