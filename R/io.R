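#' Write a genotype table as VCF v4.2
#'
#' Emits one biallelic SNP record per locus with GT:DP:AD genotype fields
#' (AD = ref,alt read counts) and a `TR` INFO tag carrying the capture-target
#' region when known. Positions are written 1-based as stored.
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(gt, path) {
  loci <- gt$loci
  n <- nrow(gt$geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lampreyNb",
    paste0("##contig=<ID=", unique(loci$chrom), ">"),
    "##INFO=<ID=TR,Number=1,Type=String,Description=\"Capture target region\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gt$geno)), collapse = "\t")
  ), con)

  gt_str <- matrix("./.", n, ncol(gt$geno))
  gt_str[gt$geno == 0] <- "0/0"
  gt_str[gt$geno == 1] <- "0/1"
  gt_str[gt$geno == 2] <- "1/1"
  dp <- if (is.null(gt$depth)) matrix(".", n, ncol(gt$geno)) else gt$depth
  adr <- if (is.null(gt$ad_ref)) NULL else gt$ad_ref

  lines <- vapply(seq_len(ncol(gt$geno)), function(j) {
    if (is.null(adr)) {
      ad <- rep(".", n)
    } else {
      ad <- paste0(adr[, j], ",", as.integer(dp[, j]) - adr[, j])
    }
    cells <- paste0(gt_str[, j], ":", dp[, j], ":", ad)
    info <- if (is.na(loci$target_region[j])) "." else
      paste0("TR=", loci$target_region[j])
    paste(c(loci$chrom[j], loci$pos[j], loci$id[j], "A", "G", ".", "PASS",
            info, "GT:DP:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF file into a genotype table
#'
#' Parses diploid GT calls from a VCF v4.x file. Multiallelic and non-SNP
#' records are skipped (counted in a message); DP and AD genotype fields are
#' used when present; the `TR` INFO tag, if present, populates the
#' capture-target region.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [genotype_table()] with attribute `n_skipped` (number of
#'   multiallelic/non-SNP records dropped).
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  keep <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " multiallelic or non-SNP record(s) skipped")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]

  gtm <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtm)) stop("VCF has no GT field: ", path)
  dose <- matrix(NA_integer_, nrow(gtm), ncol(gtm), dimnames = dimnames(gtm))
  dose[gtm %in% c("0/0", "0|0")] <- 0L
  dose[gtm %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gtm %in% c("1/1", "1|1")] <- 2L
  bad <- !is.na(gtm) & !(gtm %in% c("0/0", "0|0", "0/1", "1/0", "0|1", "1|0",
                                    "1/1", "1|1", "./.", ".|.", "."))
  if (any(bad)) {
    stop("unparseable GT value(s), first at record ",
         rownames(gtm)[which(bad, arr.ind = TRUE)[1, 1]])
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  loci <- data.frame(
    id = names(rr),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    target_region = if ("TR" %in% names(info)) as.character(info$TR)
                    else NA_character_
  )

  depth <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  ad_ref <- NULL
  if (!is.null(ad)) {
    ad_ref <- matrix(vapply(ad, function(x) {
      if (length(x) >= 1 && !all(is.na(x))) as.integer(x[1]) else NA_integer_
    }, integer(1)), nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }

  out <- genotype_table(
    t(dose), loci,
    depth = if (!is.null(depth)) t(depth),
    ad_ref = if (!is.null(ad_ref)) t(ad_ref)
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read the individual metadata table
#'
#' @param path CSV with header `id,stream,collection_year,length_mm`.
#' @param vcf_ids optional character vector of genotyped individual ids; ids
#'   present in the CSV but absent from the VCF are reported via a warning.
#' @return data.frame of individual metadata. The same id may legitimately
#'   appear in more than one collection year (recapture); fully duplicated
#'   `(id, collection_year)` rows are an error.
#' @export
read_individual_table <- function(path, vcf_ids = NULL) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "stream", "collection_year", "length_mm")
  if (!all(need %in% names(ind))) {
    stop("individuals CSV must have header: ", paste(need, collapse = ","))
  }
  key <- paste(ind$id, ind$collection_year)
  if (anyDuplicated(key)) {
    stop("duplicate individual id in a collection: ",
         ind$id[duplicated(key)][1])
  }
  if (any(!is.finite(ind$length_mm)) || any(ind$length_mm < 0)) {
    stop("lengths must be non-negative finite numbers")
  }
  if (!is.null(vcf_ids)) {
    missing_ids <- setdiff(ind$id, vcf_ids)
    if (length(missing_ids)) {
      warning(length(missing_ids), " individual(s) in CSV absent from VCF: ",
              paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    attr(ind, "missing_from_vcf") <- missing_ids
  }
  ind
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration with `paths`, per-module parameter blocks
#' (`qc`, `sibship`, `mixture`, `reconcile`, `effsize`) and a global `seed`.
#' Missing blocks are filled with defaults that match the published analysis
#' settings (heterozygosity cutoff 0.6, |D| cutoff 7, minimum depth 8x,
#' individual missingness 0.80, MAF 0.05, 1-Mb thinning, genotyping error
#' 0.001, overfitted-mixture cutoff 0.035 with K = 10, pcrit 0.05).
#'
#' @param x path to a YAML/JSON file, or a list.
#' @return A complete configuration list of class `run_config`.
#' @export
read_run_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else {
    x
  }
  defaults <- list(
    seed = 1L,
    min_n_mixture = 50L,
    qc = list(h_max = 0.6, d_max = 7, ind_missing_max = 0.80, min_depth = 8,
              maf_min = 0.05, call_rate_min = 0.80, min_sep_bp = 1e6),
    sibship = list(error_rate = 0.001, fs_threshold = 0, hs_threshold = 10,
                   min_loci = 50, bootstrap_B = 100,
                   run_length = "medium"),
    mixture = list(k_max = 10L, cutoff = 0.035, iter = 10000L, burn = 2000L,
                   thin = 5L, birth_rate = 1),
    reconcile = list(relatedness = "cluster", bands = NULL, events = list()),
    effsize = list(pcrit = 0.05, sf_bootstrap_B = 1000L, n_perm = 100L)
  )
  out <- utils::modifyList(defaults, cfg)
  structure(out, class = c("run_config", "list"))
}

# deterministic fan-out of the global seed to per-module seeds (kept < 2^31)
derive_seed <- function(seed, module) {
  offsets <- c(simulate = 11L, qc = 23L, sibship = 37L, mixture = 53L,
               reconcile = 71L, effsize = 89L, panels = 97L)
  as.integer((as.numeric(seed) * 10007 + offsets[[module]]) %% 2147483647)
}
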