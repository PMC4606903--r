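#' Genotype matrix container
#'
#' Bundles an individuals x SNPs matrix of additive genotype codes (0/1/2
#' copies of the A1 allele, `NA` for missing) with SNP metadata (id,
#' chromosome, 1-based position, alleles) and sample metadata (FID/IID plus
#' any phenotype or covariate columns).  Positions must be sorted within each
#' chromosome; all GRM, QC and annotation operations consume this container.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns. Row
#'   names are taken as individual ids and column names as SNP ids when the
#'   corresponding metadata is not supplied.
#' @param snps data.frame with columns `id`, `chrom`, `pos` and optionally
#'   `a1`, `a2` (defaulted to "A"/"B") plus any extra columns (e.g.
#'   `platform`), one row per genotyped SNP.
#' @param samples data.frame with columns `fid`, `iid`, one row per
#'   individual.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `snps`, `samples`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3,
#'                             dimnames = list(paste0("i", 1:3), c("s1", "s2"))),
#'                      snps = data.frame(id = c("s1", "s2"), chrom = "1",
#'                                        pos = c(100L, 200L)))
#' dim(g)
#' @export
genotype_matrix <- function(geno, snps = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(snps)) {
    if (is.null(colnames(geno)))
      stop("`snps` metadata or column names required")
    snps <- data.frame(id = colnames(geno), chrom = "1",
                       pos = seq_len(ncol(geno)))
  }
  snps <- as.data.frame(snps)
  if (!all(c("id", "chrom", "pos") %in% names(snps)))
    stop("`snps` needs columns id, chrom, pos")
  if (is.null(snps$a1)) snps$a1 <- "A"
  if (is.null(snps$a2)) snps$a2 <- "B"
  snps$chrom <- as.character(snps$chrom)
  if (nrow(snps) != ncol(geno))
    stop("snps rows (", nrow(snps), ") != genotype columns (", ncol(geno), ")")
  if (is.null(samples)) {
    iid <- rownames(geno)
    if (is.null(iid)) iid <- paste0("id", seq_len(nrow(geno)))
    samples <- data.frame(fid = iid, iid = iid)
  }
  samples <- as.data.frame(samples)
  if (!all(c("fid", "iid") %in% names(samples)))
    stop("`samples` needs columns fid, iid")
  if (nrow(samples) != nrow(geno))
    stop("samples rows (", nrow(samples), ") != genotype rows (", nrow(geno), ")")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE))
    stop("genotype codes must be 0, 1, 2 or NA")
  # positions sorted within chromosome
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p))
      stop("SNP positions not sorted on chromosome ", ch)
  }
  colnames(geno) <- snps$id
  rownames(geno) <- samples$iid
  structure(list(geno = geno, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "SNPs on", length(unique(x$snps$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing rate %.4f\n", miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param snps SNP ids (character) or column indices to keep; `NULL` keeps all.
#' @param samples individual ids (character, matched to `iid`) or row indices
#'   to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested SNPs/samples.
#' @export
subset_genotypes <- function(G, snps = NULL, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  sj <- if (is.null(snps)) seq_len(ncol(G$geno)) else
    if (is.character(snps)) match(snps, G$snps$id) else snps
  if (anyNA(sj)) stop("unknown SNP id(s): ",
                      paste(utils::head(snps[is.na(sj)], 3), collapse = ", "))
  si <- if (is.null(samples)) seq_len(nrow(G$geno)) else
    if (is.character(samples)) match(samples, G$samples$iid) else samples
  if (anyNA(si)) stop("unknown sample id(s)")
  # keep SNP order position-sorted: reorder the requested columns by (chrom, pos)
  sn <- G$snps[sj, , drop = FALSE]
  o <- order(sn$chrom, sn$pos)
  genotype_matrix(G$geno[si, sj[o], drop = FALSE], sn[o, , drop = FALSE],
                  G$samples[si, , drop = FALSE])
}

#' Allele frequencies over a SNP subset
#'
#' Frequency of the A1 (dosage-counted) allele, estimated from all
#' non-missing genotypes in the sample: p_i = sum(x_i) / (2 * n_obs_i).
#'
#' @param G a [genotype_matrix()].
#' @param snp_subset SNP ids or indices (default: all SNPs).
#' @return Named numeric vector of A1 allele frequencies.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L), ncol = 1,
#'                             dimnames = list(NULL, "s1")))
#' allele_frequencies(g)  # 0.5
#' @export
allele_frequencies <- function(G, snp_subset = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  x <- G$geno
  if (!is.null(snp_subset)) {
    j <- if (is.character(snp_subset)) match(snp_subset, G$snps$id) else snp_subset
    if (anyNA(j)) stop("unknown SNP id(s) in subset")
    if (length(j) == 0L) stop("empty SNP subset")
    x <- x[, j, drop = FALSE]
  }
  nobs <- colSums(!is.na(x))
  if (any(nobs == 0L))
    stop("SNP(s) with all genotypes missing: ",
         paste(utils::head(colnames(x)[nobs == 0L], 5), collapse = ", "))
  colSums(x, na.rm = TRUE) / (2 * nobs)
}
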