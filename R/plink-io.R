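# PLINK 1 binary genotype files and the small whitespace-delimited text
# formats around them.  The BED layout is fixed: magic bytes 0x6c 0x1b, mode
# byte 0x01 (SNP-major), then ceiling(n/4) bytes per SNP, two bits per
# individual, LSB first: 00 = homozygous A1 (code 2), 01 = missing,
# 10 = heterozygous (1), 11 = homozygous A2 (0).

.bed_byte_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      codes <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
      lut <<- matrix(0L, 256, 4)
      for (b in 0:255)
        lut[b + 1, ] <<- codes[as.character(bitwAnd(bitwShiftR(b, c(0, 2, 4, 6)), 3L))]
      lut
    }
    lut
  }
})

#' Write genotypes as PLINK1 BED/BIM/FAM
#'
#' SNP-major BED (magic bytes 0x6c 0x1b 0x01), BIM with chromosome, SNP id,
#' 0 cM, position, A1, A2, and FAM with FID IID 0 0 sex phenotype.  Genotype
#' codes count A1 alleles; phenotype is written as case = 2 / control = 1
#' (PLINK convention) when a 0/1 `phenotype` column is present in the sample
#' metadata, else -9.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix (directories must exist).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$geno)
  m <- ncol(G$geno)
  bed <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(bed))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), bed)
  nb <- ceiling(n / 4)
  pad <- nb * 4
  # genotype code -> 2-bit value
  bits <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  for (j in seq_len(m)) {
    x <- G$geno[, j]
    v <- ifelse(is.na(x), 1L, bits[as.character(x)])
    v <- c(v, rep(0L, pad - n))
    q <- matrix(v, nrow = 4)
    byte <- q[1, ] + q[2, ] * 4L + q[3, ] * 16L + q[4, ] * 64L
    writeBin(as.raw(byte), bed)
  }
  bim <- data.frame(chrom = G$snps$chrom, id = G$snps$id, cm = 0,
                    pos = G$snps$pos, a1 = G$snps$a1, a2 = G$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ph <- if (!is.null(G$samples$phenotype))
    ifelse(is.na(G$samples$phenotype), -9L, G$samples$phenotype + 1L) else -9L
  sex <- if (!is.null(G$samples$sex)) G$samples$sex else 0L
  fam <- data.frame(fid = G$samples$fid, iid = G$samples$iid,
                    pat = 0L, mat = 0L, sex = sex, phe = ph)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK1 BED/BIM/FAM genotypes
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A [genotype_matrix()]; a PLINK phenotype column of 1/2 is mapped
#'   back to 0/1 (missing codes -9/0 become `NA`).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phe"))
  n <- nrow(fam)
  m <- nrow(bim)
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK1 BED file: ", prefix, ".bed")
  raw <- readBin(con, "raw", nb * m)
  if (length(raw) != nb * m)
    stop("BED file truncated: expected ", nb * m, " body bytes")
  lut <- .bed_byte_lut()
  vals <- lut[as.integer(raw) + 1L, , drop = FALSE]  # (nb*m) x 4
  geno <- matrix(as.integer(t(vals)), nrow = nb * 4)[seq_len(n), , drop = FALSE]
  samples <- data.frame(fid = as.character(fam$fid), iid = as.character(fam$iid),
                        sex = fam$sex)
  phe <- suppressWarnings(as.integer(fam$phe))
  samples$phenotype <- ifelse(phe %in% c(1L, 2L), phe - 1L, NA_integer_)
  genotype_matrix(geno, bim[, c("id", "chrom", "pos", "a1", "a2")], samples)
}

#' Read/write GCTA-style phenotype and covariate tables
#'
#' Whitespace-delimited text with FID and IID as the first two columns.
#' `write_pheno_table()` writes without a header (the GCTA convention for
#' `.phen` files) unless `header = TRUE`.
#'
#' @param path file path.
#' @param col_names column names to assign after FID/IID when the file has
#'   no header.
#' @return `read_pheno_table`: a data.frame with `fid`, `iid` and value
#'   columns.
#' @export
read_pheno_table <- function(path, col_names = NULL) {
  df <- utils::read.table(path, header = FALSE)
  names(df)[1:2] <- c("fid", "iid")
  df$fid <- as.character(df$fid)
  df$iid <- as.character(df$iid)
  if (!is.null(col_names)) {
    if (length(col_names) != ncol(df) - 2)
      stop("col_names length does not match file columns")
    names(df)[-(1:2)] <- col_names
  }
  df
}

#' @rdname read_pheno_table
#' @param df data.frame whose first two columns are FID and IID.
#' @param header write a header line?
#' @export
write_pheno_table <- function(df, path, header = FALSE) {
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Read/write BED4 interval files
#'
#' Browser BED is 0-based half-open on disk; intervals are converted to the
#' package's 1-based inclusive convention on read (`start + 1`) and back on
#' write.
#'
#' @param path file path.
#' @return `read_bed4`: data.frame with `chrom`, `start`, `end`, `name`
#'   (1-based inclusive).
#' @export
read_bed4 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  names(df) <- c("chrom", "start", "end", "name")
  df$start <- df$start + 1L
  df
}

#' @rdname read_bed4
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, in 1-based inclusive coordinates.
#' @export
write_bed4 <- function(intervals, path) {
  nm <- if (!is.null(intervals$name)) intervals$name else
    paste0("iv", seq_len(nrow(intervals)))
  out <- data.frame(chrom = intervals$chrom, start = intervals$start - 1L,
                    end = intervals$end, name = nm)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
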