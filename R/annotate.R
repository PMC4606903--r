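#' @importFrom methods as
NULL

# internal: SNP table (id, chrom, pos) -> width-1 GRanges; coordinates are
# 1-based inclusive throughout the package
.snp_gr <- function(snps) {
  GenomicRanges::GRanges(snps$chrom,
                         IRanges::IRanges(snps$pos, snps$pos, names = snps$id))
}

.interval_gr <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end,
                                                    names = df$name))
}

# extend interval starts/ends by `bp`, clamping starts at position 1
.extend <- function(gr, bp) {
  if (length(gr) == 0 || bp == 0) return(gr)
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(gr) - as.integer(bp)),
                     GenomicRanges::end(gr) + as.integer(bp)))
}

.overlap_ids <- function(snp_gr, target_gr) {
  if (length(target_gr) == 0) return(character(0))
  hits <- GenomicRanges::findOverlaps(snp_gr, target_gr, ignore.strand = TRUE)
  unique(names(snp_gr)[S4Vectors::queryHits(hits)])
}

#' Partition SNPs into pathway / remainder / excluded sets
#'
#' Assigns SNPs to a pathway region set under one of three nested
#' strategies, mirroring the additive design of partitioned-heritability
#' pathway analyses:
#'
#' * `"genic"` -- SNPs inside any pathway-gene interval;
#' * `"flank50"` -- genic SNPs plus SNPs within `flank_bp` (default 50 kb)
#'   of a gene boundary (distance measured coordinate-to-boundary, boundary
#'   inclusive: distance d qualifies iff d <= `flank_bp`);
#' * `"flank50_dhs"` -- the `"flank50"` set plus SNPs whose distance d to the
#'   nearest pathway-gene boundary satisfies `flank_bp < d <= dhs_outer_bp`
#'   (default 250 kb annulus) *and* which lie inside an open-chromatin (DHS)
#'   interval.  With `dhs_strict = TRUE` the DHS condition is additionally
#'   imposed on the 0-50 kb flank (the stricter reading); the default applies
#'   it only to the distal annulus.
#'
#' Flanks are clamped at position 1.  Strand is ignored.  Gene names in
#' `pathway_genes` that do not resolve against `genes` are recorded in the
#' `unresolved` element, not treated as errors.
#'
#' @param snps data.frame with `id`, `chrom`, `pos` (or a [genotype_matrix()],
#'   whose `$snps` is used).
#' @param genes data.frame with `name`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param pathway_genes character vector of gene names defining the pathway,
#'   or a list with elements `name` and `genes`.
#' @param strategy one of `"genic"`, `"flank50"`, `"flank50_dhs"`.
#' @param dhs data.frame of open-chromatin intervals (`chrom`, `start`,
#'   `end`); required for `"flank50_dhs"`.
#' @param flank_bp inner flank size in bp (default 50,000).
#' @param dhs_outer_bp outer bound of the DHS annulus in bp (default 250,000).
#' @param dhs_strict apply the DHS condition inside the inner flank too?
#' @param name pathway label stored in the result.
#' @return An object of class `partition_spec`: list with `pathway` (label),
#'   `strategy`, `snps_pathway`, `snps_remainder`, `snps_excluded` (empty
#'   here; populated by [exclude_risk_regions()]), `unresolved`, and the
#'   flank parameters.  The three id sets always tile the input SNP set.
#' @export
build_partition <- function(snps, genes, pathway_genes,
                            strategy = c("genic", "flank50", "flank50_dhs"),
                            dhs = NULL, flank_bp = 50000, dhs_outer_bp = 250000,
                            dhs_strict = FALSE, name = NULL) {
  strategy <- match.arg(strategy)
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  if (is.list(pathway_genes) && !is.null(pathway_genes$genes)) {
    if (is.null(name)) name <- pathway_genes$name
    pathway_genes <- pathway_genes$genes
  }
  if (is.null(name)) name <- "pathway"
  unresolved <- setdiff(pathway_genes, genes$name)
  gsub <- genes[genes$name %in% pathway_genes, , drop = FALSE]
  snp_gr <- .snp_gr(snps)
  gene_gr <- .interval_gr(gsub)

  genic <- .overlap_ids(snp_gr, gene_gr)
  if (strategy == "genic") {
    set <- genic
  } else {
    inner <- .overlap_ids(snp_gr, .extend(gene_gr, flank_bp))
    if (strategy == "flank50") {
      set <- inner
    } else {
      if (is.null(dhs)) stop("strategy 'flank50_dhs' requires DHS intervals")
      dhs_gr <- .interval_gr(data.frame(name = seq_len(nrow(dhs)),
                                        chrom = dhs$chrom, start = dhs$start,
                                        end = dhs$end))
      in_dhs <- .overlap_ids(snp_gr, dhs_gr)
      outer <- .overlap_ids(snp_gr, .extend(gene_gr, dhs_outer_bp))
      annulus <- setdiff(outer, inner)
      set <- union(if (dhs_strict) union(genic, intersect(setdiff(inner, genic), in_dhs))
                   else inner,
                   intersect(annulus, in_dhs))
    }
  }
  structure(list(pathway = name, strategy = strategy,
                 snps_pathway = intersect(snps$id, set),
                 snps_remainder = setdiff(snps$id, set),
                 snps_excluded = character(0),
                 unresolved = unresolved,
                 flank_bp = flank_bp, dhs_outer_bp = dhs_outer_bp,
                 risk_exclusion = "none",
                 all_snps = snps$id),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat("partition_spec '", x$pathway, "' [", x$strategy, "]: ",
      length(x$snps_pathway), " pathway / ", length(x$snps_remainder),
      " remainder / ", length(x$snps_excluded), " excluded SNPs",
      if (x$risk_exclusion != "none") paste0(" (risk exclusion: ",
                                             x$risk_exclusion, ")"),
      "\n", sep = "")
  if (length(x$unresolved))
    cat("  unresolved gene names:", length(x$unresolved), "\n")
  invisible(x)
}

#' Validate that a partition tiles the SNP panel
#'
#' Checks that pathway, remainder and excluded id sets are pairwise disjoint
#' and that their union equals the full analysis SNP set.
#'
#' @param part a `partition_spec`.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
partition_validate <- function(part) {
  stopifnot(inherits(part, "partition_spec"))
  sets <- list(part$snps_pathway, part$snps_remainder, part$snps_excluded)
  tot <- unlist(sets)
  if (anyDuplicated(tot)) stop("partition sets are not disjoint")
  if (!setequal(tot, part$all_snps)) stop("partition sets do not tile the panel")
  invisible(TRUE)
}

#' Carve known risk regions out of a partition
#'
#' Moves every SNP lying within `flank_bp` (inclusive, by coordinate
#' distance) of a known risk SNP -- plus any panel SNP with a risk-SNP id --
#' into the excluded set.  Excluded SNPs leave *both* the pathway and the
#' remainder sets: risk regions are dropped from the analysis entirely, so a
#' pathway's estimate reflects risk additional to the known loci.
#'
#' @param part a `partition_spec` from [build_partition()].
#' @param risk_snps data.frame with `id`, `chrom`, `pos` of known risk SNPs
#'   (risk SNPs need not be genotyped in the panel).
#' @param flank_bp exclusion half-width in bp (0 = just the SNPs themselves).
#' @param snps SNP table (`id`, `chrom`, `pos`) or [genotype_matrix()]
#'   giving panel positions.
#' @return The updated `partition_spec`.
#' @export
exclude_risk_regions <- function(part, risk_snps, flank_bp, snps) {
  stopifnot(inherits(part, "partition_spec"))
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  snps <- snps[snps$id %in% part$all_snps, , drop = FALSE]
  hit <- rep(FALSE, nrow(snps))
  for (r in seq_len(nrow(risk_snps))) {
    hit <- hit | (snps$chrom == as.character(risk_snps$chrom[r]) &
                    abs(snps$pos - risk_snps$pos[r]) <= flank_bp)
  }
  excl <- union(snps$id[hit], intersect(risk_snps$id, part$all_snps))
  part$snps_pathway <- setdiff(part$snps_pathway, excl)
  part$snps_remainder <- setdiff(part$snps_remainder, excl)
  part$snps_excluded <- union(part$snps_excluded, excl)
  part$risk_exclusion <- sprintf("snp+/-%gkb", flank_bp / 1000)
  partition_validate(part)
  part
}

#' LD-based exclusion around risk SNPs
#'
#' Excludes panel SNPs in linkage disequilibrium with known risk SNPs.
#' r-squared is the squared Pearson correlation of additive genotype codes
#' (composite LD) between each risk SNP and every panel SNP within `window_bp`
#' of it on the same chromosome; SNPs with r2 >= `r2_threshold` are excluded
#' (a genotyped risk SNP always excludes itself, r2 = 1).  With
#' `blanket_bp` set, all SNPs within that distance are excluded regardless of
#' LD (the conservative blanket mode, e.g. 1 Mb).  Monomorphic comparator
#' SNPs have r2 defined as 0.
#'
#' @param G a [genotype_matrix()].
#' @param risk_snps data.frame with `id`, `chrom`, `pos`.
#' @param r2_threshold exclusion threshold in (0, 1]; ignored in blanket mode.
#' @param window_bp LD search window around each risk SNP (default 500 kb).
#' @param blanket_bp if non-`NULL`, exclude everything within this distance
#'   instead of testing LD.
#' @return Character vector of excluded SNP ids.
#' @export
ld_exclusion <- function(G, risk_snps, r2_threshold = 0.10,
                         window_bp = 500000, blanket_bp = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(blanket_bp) &&
      (r2_threshold <= 0 || r2_threshold > 1))
    stop("r2_threshold must be in (0, 1]")
  excl <- character(0)
  for (r in seq_len(nrow(risk_snps))) {
    same_chr <- G$snps$chrom == as.character(risk_snps$chrom[r])
    if (!is.null(blanket_bp)) {
      hit <- same_chr & abs(G$snps$pos - risk_snps$pos[r]) <= blanket_bp
      excl <- union(excl, G$snps$id[hit])
      next
    }
    ri <- which(G$snps$id == risk_snps$id[r])
    if (!length(ri)) next  # risk SNP not genotyped: no LD information
    near <- which(same_chr & abs(G$snps$pos - risk_snps$pos[r]) <= window_bp)
    x <- G$geno[, ri]
    if (stats::var(x, na.rm = TRUE) == 0) next
    r2 <- vapply(near, function(j) {
      y <- G$geno[, j]
      if (isTRUE(stats::var(y, na.rm = TRUE) == 0)) return(0)
      cc <- stats::cor(x, y, use = "pairwise.complete.obs")
      if (is.na(cc)) 0 else cc^2
    }, numeric(1))
    excl <- union(excl, G$snps$id[near[r2 >= r2_threshold]])
  }
  excl
}

#' Overlap decomposition of two SNP sets
#'
#' @param set_a,set_b character vectors of SNP ids.
#' @return list with `shared`, `unique_a`, `unique_b` (exact set partition
#'   of the union).
#' @examples
#' overlap_sets(c("s1", "s2", "s3"), c("s2", "s3", "s4"))
#' @export
overlap_sets <- function(set_a, set_b) {
  list(shared = intersect(set_a, set_b),
       unique_a = setdiff(set_a, set_b),
       unique_b = setdiff(set_b, set_a))
}
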