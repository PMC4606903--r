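#' Compute an additive genetic relationship matrix
#'
#' Standard GRM over a SNP subset: with x_ij the dosage of individual j at
#' SNP i and p_i the in-sample allele frequency,
#'
#'   A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))
#'
#' Allele frequencies are estimated from the analysis sample (cases and
#' controls pooled).  Missing genotypes are mean-imputed (x -> 2 p_i), i.e.
#' their standardized value is 0, and the denominator is the full subset SNP
#' count m, not pairwise-complete counts.  Monomorphic SNPs are dropped with
#' a warning.  Per-pair non-missing SNP counts are recorded alongside.
#'
#' @param G a [genotype_matrix()].
#' @param snp_subset SNP ids or column indices (default: all SNPs).
#' @return An object of class `grm`: list with `A` (n x n symmetric), `N`
#'   (n x n pairwise non-missing SNP counts), `ids` (data.frame fid/iid),
#'   `m` (SNPs used), `snps` (their ids).
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3,
#'                             dimnames = list(NULL, c("s1", "s2"))))
#' compute_grm(g)$A   # A[1,3] = -2, diagonal 1, 0, 1
#' @export
compute_grm <- function(G, snp_subset = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  x <- G$geno
  ids <- if (is.null(snp_subset)) G$snps$id else {
    j <- if (is.character(snp_subset)) match(snp_subset, G$snps$id) else snp_subset
    if (anyNA(j)) stop("unknown SNP id(s) in subset")
    G$snps$id[j]
  }
  x <- x[, match(ids, G$snps$id), drop = FALSE]
  if (ncol(x) == 0) stop("empty SNP subset")
  nobs <- colSums(!is.na(x))
  if (any(nobs == 0))
    stop("all-missing SNP(s): ",
         paste(utils::head(ids[nobs == 0], 5), collapse = ", "))
  p <- colSums(x, na.rm = TRUE) / (2 * nobs)
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped from GRM")
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
    ids <- ids[poly]
  }
  m <- ncol(x)
  if (m == 0) stop("no polymorphic SNPs left in subset")
  has_na <- anyNA(x)
  w <- sweep(x, 2, 2 * p)
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  if (has_na) w[is.na(w)] <- 0
  A <- tcrossprod(w) / m
  n <- nrow(x)
  N <- if (has_na) tcrossprod(!is.na(x)) * 1 else
    matrix(m, n, n)
  dimnames(A) <- dimnames(N) <- list(G$samples$iid, G$samples$iid)
  structure(list(A = A, N = N,
                 ids = G$samples[, c("fid", "iid")], m = m, snps = ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$A), "individuals,", x$m, "SNPs; mean diagonal",
      sprintf("%.4f", mean(diag(x$A))), "\n")
  invisible(x)
}

#' Write / read a GRM in GCTA binary format
#'
#' The binary triplet convention: `<prefix>.grm.bin` holds the lower
#' triangle of A row-wise including the diagonal (A\[1,1\], A\[2,1\],
#' A\[2,2\], ...) as 32-bit little-endian floats; `<prefix>.grm.N.bin` holds
#' the per-pair non-missing SNP counts in the same layout; `<prefix>.grm.id`
#' is two-column text (FID IID).  `read_grm(write_grm(g))` recovers `g`
#' within float32 precision.
#'
#' @param grm a [compute_grm()] result.
#' @param prefix file path prefix.
#' @return `write_grm`: the prefix, invisibly.  `read_grm`: a `grm` object
#'   (with `m` set to the maximum recorded pair count and `snps` unknown).
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  lower <- grm$A[upper.tri(grm$A, diag = TRUE)]  # column-major upper triangle
  # == row-wise lower triangle of a symmetric matrix
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(grm$N[upper.tri(grm$N, diag = TRUE)]), con,
           size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           col.names = c("fid", "iid"),
                           colClasses = "character")
  n <- nrow(ids)
  want <- n * (n + 1) / 2
  for (suffix in c(".grm.bin", ".grm.N.bin")) {
    fn <- paste0(prefix, suffix)
    have <- file.size(fn) / 4
    if (have != want)
      stop("GRM format error: ", fn, " holds ", have, " floats but ", n,
           " ids imply ", want)
  }
  rd <- function(fn) {
    con <- file(fn, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = want, size = 4L, endian = "little")
  }
  unpack <- function(v) {
    M <- matrix(0, n, n)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(ids$iid, ids$iid)
    M
  }
  A <- unpack(rd(paste0(prefix, ".grm.bin")))
  N <- unpack(rd(paste0(prefix, ".grm.N.bin")))
  structure(list(A = A, N = N, ids = ids, m = max(N), snps = NULL),
            class = "grm")
}
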