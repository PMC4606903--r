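# Independent oracles used across tests.  These deliberately share no code
# with the package implementation: double loops, brute-force scans and
# closed forms only.

# naive GRM: explicit double loop over pairs and SNPs, mean imputation,
# denominator m
naive_grm <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  p <- colSums(x, na.rm = TRUE) / (2 * colSums(!is.na(x)))
  A <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    acc <- 0
    for (i in 1:m) {
      xj <- x[j, i]; xk <- x[k, i]
      if (is.na(xj)) xj <- 2 * p[i]
      if (is.na(xk)) xk <- 2 * p[i]
      acc <- acc + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    }
    A[j, k] <- acc / m
  }
  A
}

# brute-force pathway membership: O(genes x SNPs) distance scan with plain
# arithmetic (distance to the nearest gene boundary; 0 inside the gene)
brute_partition <- function(snps, genes, gene_names, strategy,
                            dhs = NULL, flank = 50000, outer = 250000) {
  gs <- genes[genes$name %in% gene_names, , drop = FALSE]
  in_dhs <- function(chrom, pos) {
    any(dhs$chrom == chrom & dhs$start <= pos & pos <= dhs$end)
  }
  hits <- character(0)
  for (i in seq_len(nrow(snps))) {
    d <- Inf
    for (g in seq_len(nrow(gs))) {
      if (snps$chrom[i] != gs$chrom[g]) next
      dd <- if (snps$pos[i] < gs$start[g]) gs$start[g] - snps$pos[i]
      else if (snps$pos[i] > gs$end[g]) snps$pos[i] - gs$end[g]
      else 0
      d <- min(d, dd)
    }
    ok <- switch(strategy,
                 genic = d == 0,
                 flank50 = d <= flank,
                 flank50_dhs = d <= flank ||
                   (d > flank && d <= outer && in_dhs(snps$chrom[i], snps$pos[i])))
    if (ok) hits <- c(hits, snps$id[i])
  }
  hits
}

# dense grid search of the restricted likelihood for a single-GRM model:
# variance parametrized as total * (f, 1-f), f and total on grids
grid_reml <- function(y, X, grm, f_grid = seq(0.001, 0.999, length.out = 400),
                      s_grid = seq(0.25, 2.5, length.out = 80)) {
  vp <- stats::var(y)
  best <- -Inf
  for (s in s_grid) for (f in f_grid) {
    ll <- restricted_loglik(y, X, list(grm), vp * s * c(f, 1 - f))
    if (ll > best) best <- ll
  }
  best
}

# liability transformation factor from first principles
oracle_liability_c <- function(K, P) {
  t <- qnorm(1 - K)
  z <- exp(-t^2 / 2) / sqrt(2 * pi)
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

# small random genotype panel with ids and positions
rand_panel <- function(n, m, maf = NULL, chrom = "1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  x <- sapply(maf, function(p) rbinom(n, 2, p))
  snps <- data.frame(id = sprintf("s%04d", seq_len(m)), chrom = chrom,
                     pos = sort(sample.int(5e6, m)))
  genotype_matrix(matrix(as.integer(x), n, m), snps)
}
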