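# Per-cohort estimators of spawning population size: reproductive-success
# summaries, effective number of breeders by the sibship-frequency (SF) and
# linkage-disequilibrium (LD) methods, the minimum spawner number N_s,
# parentage accumulation curves, and incidence-based richness extrapolation
# of the total spawner number (Chao2 and first-order jackknife).

#' Reproductive-success summary of a cohort
#'
#' Counts offspring per inferred parent within a cohort. `N_s` is the
#' number of distinct contributing parents (the minimum spawner number),
#' `kbar = 2 n / N_s` exactly (every offspring has two parents), and `vk`
#' is the sample variance of per-parent offspring counts over contributing
#' parents (denominator `N_s - 1`).
#'
#' @param ped a `pedigree` (from [link_halfsibs()] or
#'   [reconstruct_pedigree()]), or a data.frame with columns `offspring`,
#'   `parent1`, `parent2`.
#' @param members character vector of cohort member ids (default: all
#'   offspring in the pedigree).
#' @return Object of class `repro_success`: `n`, `N_s`, `kbar`, `vk`,
#'   `counts` (named per-parent offspring counts).
#' @export
repro_summary <- function(ped, members = NULL) {
  pdf <- if (inherits(ped, "pedigree")) ped$pedigree else ped
  if (is.null(members)) members <- pdf$offspring
  pdf <- pdf[pdf$offspring %in% members, , drop = FALSE]
  if (nrow(pdf) == 0) stop("cohort has no members with pedigree entries")
  counts <- table(c(pdf$parent1, pdf$parent2))
  n <- nrow(pdf)
  N_s <- length(counts)
  structure(
    list(n = n, N_s = N_s, kbar = 2 * n / N_s,
         vk = if (N_s > 1) stats::var(as.numeric(counts)) else 0,
         counts = counts),
    class = c("repro_success", "list")
  )
}

#' @export
print.repro_success <- function(x, ...) {
  cat(sprintf("repro_success: n = %d, N_s = %d, kbar = %.2f, Vk = %.2f\n",
              x$n, x$N_s, x$kbar, x$vk))
  invisible(x)
}

#' Effective number of breeders by the sibship-frequency method
#'
#' Demographic reproductive-variance estimator
#' \deqn{N_b = (\bar{k} N_s - 2) / (\bar{k} - 1 + V_k/\bar{k})}
#' computed from a cohort's reproductive-success summary. Confidence
#' intervals, when a pedigree is supplied, come from a percentile bootstrap
#' over offspring (resample cohort members with replacement, recompute the
#' summary and the estimator).
#'
#' @param rs a [repro_summary()] result (or a list with `N_s`, `kbar`,
#'   `vk`).
#' @param ped optional pedigree for the bootstrap CI.
#' @param members cohort members (defaults to all offspring of `ped`).
#' @param B bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return Object of class `nb_estimate` with `method = "SF"`, `point`
#'   (full precision; `NA` when the denominator is non-positive), `ci`
#'   (or NULL), and the inputs. Printed rounded to the nearest breeder.
#' @export
nb_sibship <- function(rs, ped = NULL, members = NULL, B = 1000,
                       conf = 0.95, seed = 1L) {
  point_of <- function(N, kbar, vk) {
    den <- kbar - 1 + vk / kbar
    if (!is.finite(den) || den <= 0) return(NA_real_)
    (kbar * N - 2) / den
  }
  point <- point_of(rs$N_s, rs$kbar, rs$vk)
  ci <- NULL
  if (!is.null(ped)) {
    pdf <- if (inherits(ped, "pedigree")) ped$pedigree else ped
    if (is.null(members)) members <- pdf$offspring
    members <- intersect(members, pdf$offspring)
    set.seed(seed)
    bs <- vapply(seq_len(B), function(b) {
      take <- sample(members, length(members), replace = TRUE)
      sub <- pdf[match(take, pdf$offspring), , drop = FALSE]
      cnt <- table(c(sub$parent1, sub$parent2))
      N <- length(cnt)
      kb <- 2 * nrow(sub) / N
      vk <- if (N > 1) stats::var(as.numeric(cnt)) else 0
      point_of(N, kb, vk)
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
  }
  structure(
    list(method = "SF", point = point, ci = ci, N_s = rs$N_s,
         kbar = rs$kbar, vk = rs$vk),
    class = c("nb_estimate", "list")
  )
}

#' @export
print.nb_estimate <- function(x, ...) {
  pt <- if (is.na(x$point)) "undefined" else
    if (is.infinite(x$point)) "Inf" else sprintf("%d", round(x$point))
  ci <- if (is.null(x$ci)) "" else
    sprintf(" (%s-%s)",
            if (is.finite(x$ci[1])) round(x$ci[1]) else "Inf",
            if (is.finite(x$ci[2])) round(x$ci[2]) else "Inf")
  cat(sprintf("Nb (%s method): %s%s\n", x$method, pt, ci))
  invisible(x)
}

#' Burrows composite r-squared between two loci
#'
#' Composite (genotypic) linkage disequilibrium between two biallelic loci
#' from unphased dosages: the Burrows composite covariance
#' `Delta = sum(g1 g2)/(2S) - 2 p1 p2`, squared and normalized by
#' `(p(1-p) + D_A)` terms, where `D_A` is each locus's departure of
#' homozygote frequency from Hardy-Weinberg. Computed over individuals
#' called at both loci. With `unbiased = FALSE` (default) the estimator is
#' the plain composite correlation squared: exactly 1 for perfectly
#' correlated dosage vectors and with mean ~ 1/S under independence. With
#' `unbiased = TRUE`, `Delta` carries the `S/(S-1)` unbiased-products
#' factor, the form whose independence expectation is `1/S + 3.19/S^2` and
#' which the drift-LD conversion in [nb_ld()] assumes.
#'
#' @param g1,g2 dosage vectors (0/1/2, NA allowed).
#' @param unbiased apply the `S/(S-1)` factor to `Delta` (default FALSE).
#' @return `r2` value, with attributes `S` (complete cases) and `delta`;
#'   `NA` if either locus is monomorphic among complete cases or S < 3.
#' @export
burrows_r2 <- function(g1, g2, unbiased = FALSE) {
  ok <- !is.na(g1) & !is.na(g2)
  S <- sum(ok)
  if (S < 3) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  p1 <- mean(x) / 2; p2 <- mean(y) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  delta <- sum(x * y) / 2 / S - 2 * p1 * p2
  if (unbiased) delta <- delta * S / (S - 1)
  d1 <- mean(x == 2) - p1^2
  d2 <- mean(y == 2) - p2^2
  den <- (p1 * (1 - p1) + d1) * (p2 * (1 - p2) + d2)
  if (den <= 0) return(NA_real_)
  r2 <- delta^2 / den
  attr(r2, "S") <- S
  attr(r2, "delta") <- delta
  r2
}

# mean Burrows r2 over all cross-chromosome locus pairs for a complete-case
# dosage matrix; returns the weighted mean (weights = pair sample size) and
# the harmonic mean S. Fast path via crossproducts when data are complete.
mean_r2_cross_chrom <- function(g, chrom) {
  L <- ncol(g)
  cross <- outer(chrom, chrom, "!=") & upper.tri(matrix(0, L, L))
  if (!any(cross)) stop("no usable cross-chromosome locus pairs")
  if (!anyNA(g)) {
    S <- nrow(g)
    p <- colMeans(g) / 2
    xy <- crossprod(g) / 2 - 2 * S * tcrossprod(p)   # S * Delta (biased)
    delta <- xy / (S - 1)
    d <- colMeans(g == 2) - p^2
    v <- p * (1 - p) + d
    den <- tcrossprod(v)
    r2m <- delta^2 / den
    vals <- r2m[cross]
    ok <- v > 0
    keep <- cross & outer(ok, ok, "&")
    vals <- r2m[keep]
    list(r2 = mean(vals), S = S, n_pairs = sum(keep))
  } else {
    idx <- which(cross, arr.ind = TRUE)
    vals <- numeric(nrow(idx)); w <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- burrows_r2(g[, idx[r, 1]], g[, idx[r, 2]], unbiased = TRUE)
      vals[r] <- v
      w[r] <- if (is.na(v)) 0 else attr(v, "S")
    }
    use <- !is.na(vals)
    if (!any(use)) stop("no usable cross-chromosome locus pairs")
    list(r2 = sum(vals[use] * w[use]) / sum(w[use]),
         S = 1 / mean(1 / w[use]), n_pairs = sum(use))
  }
}

# expected r2 under random mating for a sample of S individuals, and the
# conversion of drift r2 to Nb (Waples 2006 as operationalized in
# NeEstimator): large-S (S >= 30) and small-S constant sets
ld_expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

ld_nb_from_r2prime <- function(r2p, S) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) disc <- 0
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) disc <- 0
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Effective number of breeders by the linkage-disequilibrium method
#'
#' Mean Burrows composite r-squared over all cross-chromosome locus pairs
#' (within-chromosome comparisons are excluded to avoid physical linkage),
#' corrected by the expected sampling value `E[r2|S]`, converted to `Nb`
#' with the standard drift-LD formula, with a delete-one jackknife over
#' individuals for the confidence interval. Loci with minor allele
#' frequency below `pcrit` are excluded.
#'
#' @param gt a [genotype_table()] (or dosage matrix with `chrom` supplied).
#' @param panel optional locus ids to restrict to (e.g. from
#'   [select_snp_panels()]).
#' @param pcrit allele-frequency inclusion criterion (default 0.05).
#' @param chrom chromosome per locus when `gt` is a bare matrix.
#' @param conf confidence level for the jackknife interval (default 0.95).
#' @return Object of class `nb_estimate` with `method = "LD"`: `point`
#'   (+Inf when the corrected r2 is non-positive), `ci`, `S` (harmonic mean
#'   sample size), `r2_mean`, `r2_expected`, `n_pairs`, `pcrit`.
#' @export
nb_ld <- function(gt, panel = NULL, pcrit = 0.05, chrom = NULL,
                  conf = 0.95) {
  if (inherits(gt, "genotype_table")) {
    g <- gt$geno; chrom <- gt$loci$chrom
    if (!is.null(panel)) {
      j <- match(panel, gt$loci$id)
      g <- g[, j, drop = FALSE]; chrom <- chrom[j]
    }
  } else {
    g <- as.matrix(gt)
    stopifnot(!is.null(chrom), length(chrom) == ncol(g))
  }
  stopifnot(pcrit > 0, pcrit < 0.5)
  maf <- locus_maf(g)
  keep <- !is.na(maf) & maf >= pcrit
  g <- g[, keep, drop = FALSE]; chrom <- chrom[keep]
  if (length(unique(chrom)) < 2) stop("no usable cross-chromosome locus pairs")

  est <- mean_r2_cross_chrom(g, chrom)
  r2p <- est$r2 - ld_expected_r2(est$S)
  point <- ld_nb_from_r2prime(r2p, est$S)

  # delete-one jackknife over individuals on the mean r2; the jackknife
  # variance is converted to an effective chi-square degrees of freedom for
  # the (skewed) r2 statistic, following the jackknife CI approach used with
  # the LD method (Jones, Ovenden & Wang 2016)
  n <- nrow(g)
  r2_jack <- vapply(seq_len(n), function(i) {
    gi <- g[-i, , drop = FALSE]
    mi <- locus_maf(gi)
    ki <- !is.na(mi) & mi > 0
    mean_r2_cross_chrom(gi[, ki, drop = FALSE], chrom[ki])$r2
  }, numeric(1))
  jm <- mean(r2_jack)
  jvar <- (n - 1) / n * sum((r2_jack - jm)^2)
  jse <- sqrt(jvar)
  df <- max(2 * est$r2^2 / jvar, 0.1)
  alpha <- 1 - conf
  r2_lo <- est$r2 * df / stats::qchisq(1 - alpha / 2, df)
  r2_hi <- est$r2 * df / stats::qchisq(alpha / 2, df)
  er2 <- ld_expected_r2(est$S)
  ci <- c(ld_nb_from_r2prime(r2_hi - er2, est$S),
          ld_nb_from_r2prime(r2_lo - er2, est$S))

  structure(
    list(method = "LD", point = point, ci = ci, S = est$S,
         r2_mean = est$r2, r2_expected = ld_expected_r2(est$S),
         r2_prime = r2p, n_pairs = est$n_pairs, pcrit = pcrit,
         jack_se = jse),
    class = c("nb_estimate", "list")
  )
}

#' Parentage accumulation curve
#'
#' The pedigree analogue of a species accumulation curve: for random
#' orderings of a cohort's offspring, the cumulative number of distinct
#' inferred parents at each sample size.
#'
#' @param ped pedigree (object or data.frame).
#' @param members cohort member ids (default: all offspring).
#' @param n_perm random orderings (default 100).
#' @param seed integer seed.
#' @return data.frame per step: `n_offspring`, `mean`, `sd`, `q025`,
#'   `median`, `q975`; attribute `perms` holds the full matrix.
#' @export
parent_accumulation <- function(ped, members = NULL, n_perm = 100,
                                seed = 1L) {
  pdf <- if (inherits(ped, "pedigree")) ped$pedigree else ped
  if (is.null(members)) members <- pdf$offspring
  pdf <- pdf[pdf$offspring %in% members, , drop = FALSE]
  if (nrow(pdf) == 0) stop("cohort has no members with pedigree entries")
  n <- nrow(pdf)
  set.seed(seed)
  M <- vapply(seq_len(n_perm), function(b) {
    ord <- sample.int(n)
    p1 <- pdf$parent1[ord]; p2 <- pdf$parent2[ord]
    seen <- cumsum(!duplicated(c(rbind(p1, p2))))  # interleave both parents
    seen[seq_len(n) * 2]
  }, numeric(n))
  M <- matrix(M, nrow = n)
  out <- data.frame(
    n_offspring = seq_len(n),
    mean = rowMeans(M),
    sd = apply(M, 1, stats::sd),
    q025 = apply(M, 1, stats::quantile, 0.025),
    median = apply(M, 1, stats::median),
    q975 = apply(M, 1, stats::quantile, 0.975)
  )
  attr(out, "perms") <- M
  out
}

#' Extrapolated spawner richness (Chao2 and first-order jackknife)
#'
#' Treats each offspring as an incidence sample ("site") in which its two
#' inferred parents occur, and extrapolates the total number of parental
#' genotypes with the incidence-based Chao2 and first-order jackknife
#' estimators with the `(m-1)/m` small-sample correction, where `m` is the
#' cohort size, `q1` the number of parents seen in exactly one offspring
#' and `q2` in exactly two. Standard errors follow the standard
#' incidence-based variance formulas.
#'
#' @param ped pedigree (object or data.frame).
#' @param members cohort member ids (default: all offspring).
#' @return data.frame with rows `chao` and `jackknife1`: `S_obs`, `est`,
#'   `se`, `q1`, `q2`, `m`.
#' @export
richness_estimates <- function(ped, members = NULL) {
  pdf <- if (inherits(ped, "pedigree")) ped$pedigree else ped
  if (is.null(members)) members <- pdf$offspring
  pdf <- pdf[pdf$offspring %in% members, , drop = FALSE]
  m <- nrow(pdf)
  if (m < 2) stop("richness extrapolation needs at least 2 offspring")
  parents <- sort(unique(c(pdf$parent1, pdf$parent2)))
  inc <- matrix(FALSE, m, length(parents),
                dimnames = list(pdf$offspring, parents))
  inc[cbind(seq_len(m), match(pdf$parent1, parents))] <- TRUE
  inc[cbind(seq_len(m), match(pdf$parent2, parents))] <- TRUE
  richness_from_incidence(inc)
}

#' Richness extrapolation from a general incidence matrix
#'
#' The incidence-based Chao2 and first-order jackknife estimators with the
#' `(m-1)/m` small-sample correction, and their standard variance formulas,
#' computed from a sites x species presence matrix ([richness_estimates()]
#' builds the offspring x parent matrix and calls this).
#'
#' @param inc logical or 0/1 matrix, sites (offspring) x species (parents).
#' @return data.frame with rows `chao` and `jackknife1`: `S_obs`, `est`,
#'   `se`, `q1`, `q2`, `m`.
#' @export
richness_from_incidence <- function(inc) {
  inc <- inc > 0
  m <- nrow(inc)
  if (m < 2) stop("richness extrapolation needs at least 2 sites")
  counts <- colSums(inc)
  S_obs <- sum(counts > 0)
  q1 <- sum(counts == 1)
  q2 <- sum(counts == 2)
  ssc <- (m - 1) / m

  if (q2 > 0) {
    chao <- S_obs + ssc * q1^2 / (2 * q2)
    aa <- q1 / q2
    chao_var <- q1 * ssc * (0.5 + ssc * (1 + aa / 4) * aa) * aa
  } else {
    chao <- S_obs + ssc * q1 * (q1 - 1) / 2
    chao_var <- ssc * (ssc * (q1 * (2 * q1 - 1)^2 / 4 - q1^4 / chao / 4) +
                         q1 * (q1 - 1) / 2)
  }
  jack1 <- S_obs + q1 * ssc
  if (q1 > 0) {
    # f_j = number of sites containing j of the singleton species
    per_site <- rowSums(inc[, counts == 1, drop = FALSE])
    jack1_var <- (sum(per_site^2) - q1 / m) * (m - 1) / m
  } else {
    jack1_var <- 0
  }

  data.frame(
    estimator = c("chao", "jackknife1"),
    S_obs = S_obs,
    est = c(chao, jack1),
    se = sqrt(c(chao_var, jack1_var)),
    q1 = q1, q2 = q2, m = m
  )
}
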