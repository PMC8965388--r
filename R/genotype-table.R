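#' Genotype table container
#'
#' A `genotype_table` holds diploid biallelic genotypes for a set of
#' individuals as alternate-allele dosages (0, 1, 2; `NA` = missing call),
#' together with per-genotype read depth, reference-allele read counts, and
#' per-locus metadata (chromosome, 1-based position, optional capture-target
#' region).
#'
#' @param geno integer matrix, individuals x loci, values 0/1/2/NA.
#' @param loci data.frame with columns `id`, `chrom`, `pos` and optionally
#'   `target_region` (NA for off-target loci).
#' @param depth optional matrix of total read depth per genotype.
#' @param ad_ref optional matrix of reads supporting the reference allele.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, loci, depth = NULL, ad_ref = NULL) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(loci), all(c("id", "chrom", "pos") %in% names(loci)),
            nrow(loci) == ncol(geno))
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be dosages 0, 1, 2 or NA")
  }
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  colnames(geno) <- loci$id
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(geno)))
    dimnames(depth) <- dimnames(geno)
  }
  if (!is.null(ad_ref)) {
    ad_ref <- as.matrix(ad_ref)
    stopifnot(all(dim(ad_ref) == dim(geno)))
    dimnames(ad_ref) <- dimnames(geno)
  }
  if (is.null(loci$target_region)) loci$target_region <- NA_character_
  structure(
    list(geno = geno, depth = depth, ad_ref = ad_ref, loci = loci),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d loci (%.1f%% missing)\n",
    nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))
  ))
  cat(sprintf("  chromosomes: %d; depth: %s; ref read counts: %s\n",
              length(unique(x$loci$chrom)),
              if (is.null(x$depth)) "absent" else "present",
              if (is.null(x$ad_ref)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Subset a genotype table by individuals and/or loci
#'
#' @param x a `genotype_table`.
#' @param i individual index (names, logical, or integer).
#' @param j locus index.
#' @param ... unused.
#' @return A `genotype_table`.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  # resolve the locus index against column names so loci metadata stays aligned
  jj <- setNames(seq_len(ncol(x$geno)), colnames(x$geno))[j]
  genotype_table(
    x$geno[i, jj, drop = FALSE],
    x$loci[jj, , drop = FALSE],
    depth = if (!is.null(x$depth)) x$depth[i, jj, drop = FALSE],
    ad_ref = if (!is.null(x$ad_ref)) x$ad_ref[i, jj, drop = FALSE]
  )
}

#' Alternate-allele frequencies from called genotypes
#'
#' @param gt a `genotype_table` or a dosage matrix.
#' @return Numeric vector of per-locus allele frequencies (counted allele).
#' @export
allele_freqs <- function(gt) {
  g <- if (inherits(gt, "genotype_table")) gt$geno else gt
  colMeans(g, na.rm = TRUE) / 2
}

# minor allele frequency per locus, from called genotypes only
locus_maf <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
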