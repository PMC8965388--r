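#' Per-locus QC statistics
#'
#' Computes, for every locus: observed heterozygosity `H` (het calls over
#' non-missing calls), minor allele frequency from called genotypes, call
#' rate, an exact Hardy-Weinberg test p-value, and the heterozygote
#' read-ratio deviation `D` used for paralog screening. `D` pools reads over
#' all heterozygous calls at the locus: with `x` reads supporting the
#' reference allele out of `N` total reads in heterozygotes,
#' `D = (x - N/2) / sqrt(N/4)`, i.e. the normal-approximation z-score against
#' balanced 1:1 sampling. Loci with no heterozygous calls (or no read-count
#' data) get `D = NA` and are never flagged by the |D| rule.
#'
#' @param gt a [genotype_table()]; `ad_ref`/`depth` are used for `D`.
#' @return data.frame with one row per locus: `id`, `chrom`, `pos`,
#'   `target_region`, `h_obs`, `d_stat`, `maf`, `call_rate`, `hwe_p`,
#'   `mean_depth`.
#' @export
compute_locus_stats <- function(gt) {
  g <- gt$geno
  called <- colSums(!is.na(g))
  h_obs <- ifelse(called > 0, colSums(g == 1, na.rm = TRUE) / called, NA_real_)
  maf <- locus_maf(g)
  call_rate <- called / nrow(g)

  d_stat <- rep(NA_real_, ncol(g))
  if (!is.null(gt$ad_ref) && !is.null(gt$depth)) {
    het <- !is.na(g) & g == 1
    x <- colSums(gt$ad_ref * het, na.rm = TRUE)
    N <- colSums(gt$depth * het, na.rm = TRUE)
    ok <- N > 0
    d_stat[ok] <- (x[ok] - N[ok] / 2) / sqrt(N[ok] / 4)
  }

  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    hwe_exact_test(sum(gj == 0, na.rm = TRUE), sum(gj == 1, na.rm = TRUE),
                   sum(gj == 2, na.rm = TRUE))
  }, numeric(1))

  data.frame(
    id = gt$loci$id, chrom = gt$loci$chrom, pos = gt$loci$pos,
    target_region = gt$loci$target_region,
    h_obs = h_obs, d_stat = d_stat, maf = maf, call_rate = call_rate,
    hwe_p = hwe_p,
    mean_depth = if (is.null(gt$depth)) NA_real_ else colMeans(gt$depth)
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on allele counts (Wigginton, Cutler &
#' Abecasis 2005). Reported for screening only; no automatic exclusion is
#' tied to it.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts.
#' @return p-value (1 for monomorphic or empty loci).
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  if (n == 0) return(1)
  n_a <- 2 * n_alt_hom + n_het  # rarer allele resolved below
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1)
  # distribution of het count given allele counts
  hets <- seq(n_a %% 2, n_a, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_a - h) / 2
    hom_com <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) - lgamma(hom_com + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[match(n_het, hets)] + 1e-12]))
}

#' Apply genotype-matrix QC filters
#'
#' Filter order is fixed: (1) genotypes with read depth below `min_depth`
#' are set missing; (2) loci with observed heterozygosity above `h_max` or
#' pooled read-ratio deviation exceeding `d_max` in absolute value are
#' removed (paralog screen); (3) individuals with a missing-genotype fraction
#' strictly greater than `ind_missing_max` are removed. Statistics feeding
#' the locus filter are computed after the depth masking.
#'
#' @param gt a [genotype_table()].
#' @param thresholds list with `h_max` (default 0.6), `d_max` (7),
#'   `ind_missing_max` (0.80), `min_depth` (8).
#' @return list with `gt` (filtered table), `stats` (post-depth-mask locus
#'   stats for the retained input loci), and `report` (data.frame
#'   `unit`, `type`, `reason`, `value`, `threshold` of every exclusion).
#' @export
apply_qc_filters <- function(gt, thresholds = list()) {
  th <- utils::modifyList(
    list(h_max = 0.6, d_max = 7, ind_missing_max = 0.80, min_depth = 8),
    thresholds
  )
  report <- list()

  # 1. depth rule: genotypes with < min_depth reads are treated as missing
  if (!is.null(gt$depth)) {
    low <- !is.na(gt$geno) & gt$depth < th$min_depth
    n_low <- sum(low)
    if (n_low > 0) {
      gt$geno[low] <- NA_integer_
      report[[length(report) + 1]] <- data.frame(
        unit = "genotype", type = "genotype", reason = "depth_below_min",
        value = n_low, threshold = th$min_depth
      )
    }
  }

  stats <- compute_locus_stats(gt)

  # 2. paralog screen on loci
  drop_h <- !is.na(stats$h_obs) & stats$h_obs > th$h_max
  drop_d <- !is.na(stats$d_stat) & abs(stats$d_stat) > th$d_max
  for (j in which(drop_h)) {
    report[[length(report) + 1]] <- data.frame(
      unit = stats$id[j], type = "locus", reason = "heterozygosity_excess",
      value = stats$h_obs[j], threshold = th$h_max
    )
  }
  for (j in which(drop_d & !drop_h)) {
    report[[length(report) + 1]] <- data.frame(
      unit = stats$id[j], type = "locus", reason = "read_ratio_deviation",
      value = stats$d_stat[j], threshold = th$d_max
    )
  }
  keep_loci <- which(!(drop_h | drop_d))
  if (length(keep_loci) == 0) stop("no data survives QC: all loci removed")
  gt <- gt[, keep_loci]

  # 3. individual missingness (strict >)
  miss_frac <- rowMeans(is.na(gt$geno))
  drop_ind <- miss_frac > th$ind_missing_max
  for (i in which(drop_ind)) {
    report[[length(report) + 1]] <- data.frame(
      unit = rownames(gt$geno)[i], type = "individual",
      reason = "missingness_excess", value = miss_frac[i],
      threshold = th$ind_missing_max
    )
  }
  if (all(drop_ind)) stop("no data survives QC: all individuals removed")
  gt <- gt[!drop_ind, ]

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(unit = character(), type = character(), reason = character(),
               value = numeric(), threshold = numeric())
  list(gt = gt, stats = stats, report = report)
}

#' Select SNP panels for pedigree or LD analysis
#'
#' Two panel-selection rules:
#' \describe{
#'   \item{pedigree}{Among loci with MAF >= `maf_min` and call rate >=
#'     `call_rate_min`, scan each chromosome left to right; within each 1-Mb
#'     window anchored at the next available locus, pick the locus
#'     maximizing (MAF, call rate) lexicographically, break exact ties
#'     uniformly at random under `seed`, and require successive picks to be
#'     at least `min_sep_bp` apart (a separation of exactly 1 Mb is
#'     allowed).}
#'   \item{ld}{Within each capture-target region, keep the locus with the
#'     highest call rate (ties random under `seed`); then drop loci with
#'     MAF < `maf_min`. Off-target loci are not eligible.}
#' }
#'
#' @param stats locus stats from [compute_locus_stats()].
#' @param purpose `"pedigree"` or `"ld"`.
#' @param seed integer seed for tie-breaking.
#' @param maf_min,call_rate_min,min_sep_bp thresholds (defaults 0.05, 0.80,
#'   1e6).
#' @return Character vector of selected locus ids (possibly empty, with a
#'   warning).
#' @export
select_snp_panels <- function(stats, purpose = c("pedigree", "ld"), seed = 1L,
                              maf_min = 0.05, call_rate_min = 0.80,
                              min_sep_bp = 1e6) {
  purpose <- match.arg(purpose)
  set.seed(seed)
  if (purpose == "pedigree") {
    el <- stats[!is.na(stats$maf) & stats$maf >= maf_min &
                  stats$call_rate >= call_rate_min, , drop = FALSE]
    if (nrow(el) == 0) {
      warning("no locus satisfies the pedigree-panel criteria; empty panel")
      return(character(0))
    }
    picks <- character(0)
    for (cc in unique(el$chrom)) {
      sub <- el[el$chrom == cc, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      cur <- sub$pos[1]
      repeat {
        cand <- sub[sub$pos >= cur & sub$pos < cur + min_sep_bp, , drop = FALSE]
        if (nrow(cand) == 0) {
          nxt <- sub$pos[sub$pos >= cur + min_sep_bp]
          if (length(nxt) == 0) break
          cur <- nxt[1]
          next
        }
        best <- cand[cand$maf == max(cand$maf), , drop = FALSE]
        best <- best[best$call_rate == max(best$call_rate), , drop = FALSE]
        pick <- best[sample.int(nrow(best), 1), , drop = FALSE]
        picks <- c(picks, pick$id)
        nxt <- sub$pos[sub$pos >= pick$pos + min_sep_bp]
        if (length(nxt) == 0) break
        cur <- nxt[1]
      }
    }
    picks
  } else {
    el <- stats[!is.na(stats$target_region), , drop = FALSE]
    if (nrow(el) == 0) {
      warning("no on-target locus available; empty LD panel")
      return(character(0))
    }
    picks <- unlist(lapply(split(el, el$target_region), function(sub) {
      best <- sub[sub$call_rate == max(sub$call_rate), , drop = FALSE]
      best$id[sample.int(nrow(best), 1)]
    }), use.names = FALSE)
    keep <- stats$maf[match(picks, stats$id)] >= maf_min
    picks <- picks[!is.na(keep) & keep]
    if (length(picks) == 0) {
      warning("no on-target locus passes the MAF criterion; empty LD panel")
    }
    picks
  }
}
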