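#' Simulation configuration for multi-cohort semelparous spawning scenarios
#'
#' Builds and validates the configuration consumed by [simulate_truth()],
#' [simulate_genotypes()] and [simulate_lengths()]. Defaults describe a
#' moderately sized lamprey-like scenario: semelparous adults that spawn in
#' exactly one year, polygamous mating with skewed reproductive success,
#' biallelic SNPs on multiple chromosomes genotyped with error, missingness
#' and negative-binomial read depth (mean 34x, matching typical RAD-capture
#' on-target coverage), and Gaussian length-at-age.
#'
#' @param n_spawn_years number of spawning years simulated.
#' @param parents_per_year number of adults in each year's spawning pool
#'   (census, not all necessarily contribute offspring).
#' @param mating_design `"random_pairs"` (disjoint monogamous pairs, equal
#'   expected family sizes) or `"polygamous_skewed"` (each offspring draws two
#'   distinct parents with probability proportional to a gamma-distributed
#'   parental weight).
#' @param offspring_per_year larvae produced per spawning year.
#' @param vk_target target variance of per-parent offspring number under
#'   `polygamous_skewed`; the gamma shape of the parental weights is solved
#'   numerically so the expected variance matches.
#' @param n_loci,n_chromosomes number of biallelic SNPs and chromosomes; loci
#'   are placed uniformly along chromosomes of `chrom_length_bp` bases.
#' @param chrom_length_bp chromosome length in bp used for locus placement.
#' @param allele_freq_range range of the uniform distribution the counted
#'   allele frequency is drawn from.
#' @param genotyping_error probability that an observed genotype is replaced
#'   by a random Hardy-Weinberg draw at that locus (default 0.001).
#' @param missing_rate per-genotype missing-call probability.
#' @param depth_mean,depth_size negative-binomial read-depth mean and size
#'   (dispersion) per genotype.
#' @param length_at_age list of `c(mean, sd)` length (mm) per age; element 1
#'   is age 0. Values are free parameters of the stated scenario, anchored to
#'   published larval length histograms only qualitatively.
#' @param collections list of `list(year =, frac =)` sampling events: in
#'   calendar year `year` a fraction `frac` of each extant cohort is sampled.
#' @param stream stream label attached to sampled individuals.
#' @param paralog_pairs number of artificial paralogs: pairs of loci whose
#'   reads are merged into one pseudo-locus to create high-heterozygosity,
#'   read-ratio-deviant outliers for the paralog screen. Off (0) by default.
#' @param seed integer seed; all randomness in the simulator flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_spawn_years = 2,
                       parents_per_year = 50,
                       mating_design = c("polygamous_skewed", "random_pairs"),
                       offspring_per_year = 200,
                       vk_target = 40,
                       n_loci = 200,
                       n_chromosomes = 20,
                       chrom_length_bp = 1e8,
                       allele_freq_range = c(0.05, 0.5),
                       genotyping_error = 0.001,
                       missing_rate = 0.02,
                       depth_mean = 34,
                       depth_size = 5,
                       length_at_age = list(c(45, 6), c(75, 8), c(95, 9)),
                       collections = list(list(year = 2, frac = 0.5)),
                       stream = "sim",
                       paralog_pairs = 0,
                       seed = 1L) {
  mating_design <- match.arg(mating_design)
  cfg <- list(
    n_spawn_years = as.integer(n_spawn_years),
    parents_per_year = as.integer(parents_per_year),
    mating_design = mating_design,
    offspring_per_year = as.integer(offspring_per_year),
    vk_target = vk_target,
    n_loci = as.integer(n_loci),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    allele_freq_range = allele_freq_range,
    genotyping_error = genotyping_error,
    missing_rate = missing_rate,
    depth_mean = depth_mean,
    depth_size = depth_size,
    length_at_age = length_at_age,
    collections = collections,
    stream = stream,
    paralog_pairs = as.integer(paralog_pairs),
    seed = as.integer(seed)
  )
  if (cfg$parents_per_year < 2) stop("parents_per_year must be at least 2")
  if (cfg$genotyping_error < 0 || cfg$genotyping_error >= 1) {
    stop("genotyping_error must be in [0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  stopifnot(length(cfg$allele_freq_range) == 2,
            all(cfg$allele_freq_range > 0), all(cfg$allele_freq_range < 1))
  if (any(vapply(cfg$length_at_age, function(x) x[2], 0) < 0)) {
    stop("length-at-age sd must be non-negative")
  }
  if (cfg$n_spawn_years < 1 || cfg$offspring_per_year < 1) {
    stop("need at least one spawning year and one offspring per year")
  }
  structure(cfg, class = c("sim_config", "list"))
}

# gamma shape for parental weights such that the expected variance of
# per-parent offspring number matches vk_target. For n offspring each drawing
# 2 of N parents with probability ~ w_i / sum(w), k_i ~= kbar * (w_i/wbar)
# plus multinomial noise, giving Var(k) ~= kbar + kbar^2 / shape.
solve_gamma_shape <- function(kbar, vk_target) {
  excess <- vk_target - kbar
  if (excess <= 0) return(1e6)  # essentially equal weights
  f <- function(a) kbar + kbar^2 / a - vk_target
  stats::uniroot(f, c(1e-3, 1e9))$root
}

#' Simulate the breeding truth of a multi-year semelparous scenario
#'
#' Draws, for each spawning year, a disjoint pool of parents (semelparity:
#' no adult appears in two years), a mating structure, and the assignment of
#' each offspring to an unordered parent pair. Parents carry no sex label;
#' any parent may mate with multiple partners under the polygamous design.
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at allele
#' frequencies sampled from `allele_freq_range`.
#'
#' @param config a [sim_config()].
#' @return A list of class `truth_set` with elements `pedigree` (data.frame
#'   `offspring`, `parent1`, `parent2`, `spawn_year`), `parents` (data.frame
#'   `id`, `spawn_year`), `parent_geno` (parents x loci dosage matrix),
#'   `freqs`, `loci`, `repro` (per-year realized `kbar` and `vk` over
#'   contributing parents), and the `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$parents_per_year
  n <- config$offspring_per_year

  ped <- vector("list", config$n_spawn_years)
  repro <- vector("list", config$n_spawn_years)
  parents <- vector("list", config$n_spawn_years)
  for (y in seq_len(config$n_spawn_years)) {
    pid <- sprintf("Y%d_P%03d", y, seq_len(N))
    parents[[y]] <- data.frame(id = pid, spawn_year = y)
    if (config$mating_design == "random_pairs") {
      perm <- sample(pid)
      pairs <- matrix(perm[seq_len(2 * (N %/% 2))], ncol = 2, byrow = TRUE)
      pick <- sample(nrow(pairs), n, replace = TRUE)
      p1 <- pairs[pick, 1]; p2 <- pairs[pick, 2]
    } else {
      kbar_census <- 2 * n / N
      shape <- solve_gamma_shape(kbar_census, config$vk_target)
      w <- stats::rgamma(N, shape = shape, rate = shape)
      p1 <- character(n); p2 <- character(n)
      for (o in seq_len(n)) {
        pr <- sample(pid, 2, replace = FALSE, prob = w)
        p1[o] <- pr[1]; p2[o] <- pr[2]
      }
    }
    # unordered parent pairs: store in sorted order
    swap <- p1 > p2
    tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
    off <- sprintf("Y%d_O%04d", y, seq_len(n))
    ped[[y]] <- data.frame(offspring = off, parent1 = p1, parent2 = p2,
                           spawn_year = y)
    k <- table(c(p1, p2))  # contributing parents only
    repro[[y]] <- data.frame(
      spawn_year = y, n_offspring = n, n_parents = length(k),
      kbar = 2 * n / length(k), vk = stats::var(as.numeric(k))
    )
  }
  pedigree <- do.call(rbind, ped)
  parents <- do.call(rbind, parents)

  # loci and parental genotypes (HWE at simulated frequencies)
  L <- config$n_loci
  chrom <- sort(sample(seq_len(config$n_chromosomes), L, replace = TRUE))
  pos <- integer(L)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(config$chrom_length_bp, length(idx)))
  }
  loci <- data.frame(
    id = sprintf("snp%04d", seq_len(L)),
    chrom = paste0("chr", chrom), pos = pos,
    target_region = sprintf("tag%04d", seq_len(L))
  )
  freqs <- stats::runif(L, config$allele_freq_range[1], config$allele_freq_range[2])
  parent_geno <- matrix(
    stats::rbinom(nrow(parents) * L, 2, rep(freqs, each = nrow(parents))),
    nrow = nrow(parents), dimnames = list(parents$id, loci$id)
  )

  structure(
    list(pedigree = pedigree, parents = parents, parent_geno = parent_geno,
         freqs = freqs, loci = loci, repro = do.call(rbind, repro),
         config = config),
    class = c("truth_set", "list")
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d spawn years, %d offspring, %d parents, %d loci\n",
              max(x$pedigree$spawn_year), nrow(x$pedigree), nrow(x$parents),
              length(x$freqs)))
  print(x$repro, row.names = FALSE)
  invisible(x)
}

#' Simulate offspring genotypes by Mendelian transmission
#'
#' Each offspring receives one allele from each true parent at every locus;
#' the observed call is then perturbed: with probability `genotyping_error`
#' it is replaced by a Hardy-Weinberg draw at that locus, it is missing with
#' probability `missing_rate`, and total read depth is drawn from a negative
#' binomial. Heterozygous calls split reads binomially between alleles, so
#' the read-ratio paralog screen can be exercised. Low-depth genotypes are
#' *not* masked here; that is the QC stage's job.
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param config the same [sim_config()] used to generate `truth`.
#' @return A [genotype_table()] for all simulated offspring, with attribute
#'   `paralog_loci` naming injected pseudo-paralog loci (if any).
#' @export
simulate_genotypes <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  ped <- truth$pedigree
  n <- nrow(ped); L <- config$n_loci
  g1 <- truth$parent_geno[ped$parent1, , drop = FALSE]
  g2 <- truth$parent_geno[ped$parent2, , drop = FALSE]
  # transmitted allele ~ Bernoulli(dosage / 2) per parent
  geno <- matrix(stats::rbinom(n * L, 1, g1 / 2) + stats::rbinom(n * L, 1, g2 / 2),
                 nrow = n, dimnames = list(ped$offspring, truth$loci$id))

  eps <- config$genotyping_error
  if (eps > 0) {
    err <- matrix(stats::runif(n * L) < eps, nrow = n)
    hwe <- matrix(stats::rbinom(n * L, 2, rep(truth$freqs, each = n)), nrow = n)
    geno[err] <- hwe[err]
  }

  depth <- matrix(stats::rnbinom(n * L, mu = config$depth_mean,
                                 size = config$depth_size),
                  nrow = n, dimnames = dimnames(geno))
  # reference-allele reads: dosage counts the ALT allele
  ad_ref <- matrix(0L, n, L, dimnames = dimnames(geno))
  ad_ref[geno == 0] <- depth[geno == 0]
  het <- which(geno == 1)
  ad_ref[het] <- stats::rbinom(length(het), depth[het], 0.5)

  loci <- truth$loci
  paralogs <- character(0)
  if (config$paralog_pairs > 0) {
    # merge reads of locus pairs into the first locus of each pair: observed
    # genotype is het whenever the two underlying loci disagree in allele
    # content, and ref reads pool across both loci
    stopifnot(2 * config$paralog_pairs <= L)
    pick <- sample(L, 2 * config$paralog_pairs)
    a <- pick[seq_len(config$paralog_pairs)]
    b <- pick[config$paralog_pairs + seq_len(config$paralog_pairs)]
    dose <- geno[, a, drop = FALSE] + geno[, b, drop = FALSE]  # 0..4 alt alleles
    merged <- matrix(1L, n, length(a))
    merged[dose == 0] <- 0L
    merged[dose == 4] <- 2L
    geno[, a] <- merged
    depth[, a] <- depth[, a, drop = FALSE] + depth[, b, drop = FALSE]
    ad_ref[, a] <- ad_ref[, a, drop = FALSE] + ad_ref[, b, drop = FALSE]
    keep <- setdiff(seq_len(L), b)
    geno <- geno[, keep, drop = FALSE]
    depth <- depth[, keep, drop = FALSE]
    ad_ref <- ad_ref[, keep, drop = FALSE]
    loci <- loci[keep, , drop = FALSE]
    paralogs <- loci$id[match(truth$loci$id[a], loci$id)]
  }

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow = n)
    geno[miss] <- NA_integer_
    depth[miss] <- 0L
    ad_ref[miss] <- 0L
  }

  out <- genotype_table(geno, loci, depth = depth, ad_ref = ad_ref)
  attr(out, "paralog_loci") <- paralogs
  out
}

#' Simulate larval lengths at sampling collections
#'
#' Each collection samples a fraction of every extant cohort (without
#' replacement, mimicking lethal sampling); an individual's age at a
#' collection is `collection year - spawn year` and its length is drawn from
#' the Gaussian length-at-age entry for that age, truncated at zero.
#'
#' @param truth a `truth_set`.
#' @param config the matching [sim_config()].
#' @return data.frame `id`, `stream`, `collection_year`, `length_mm`,
#'   `true_age`, `true_spawn_year`.
#' @export
simulate_lengths <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  ped <- truth$pedigree
  out <- list()
  sampled <- character(0)
  for (col in config$collections) {
    stopifnot(!is.null(col$year), !is.null(col$frac))
    for (y in sort(unique(ped$spawn_year))) {
      age <- col$year - y
      if (age < 0) next
      pool <- setdiff(ped$offspring[ped$spawn_year == y], sampled)
      take <- round(col$frac * length(pool))
      if (take == 0) next
      ids <- sample(pool, take)
      sampled <- c(sampled, ids)
      if (age + 1 > length(config$length_at_age)) {
        stop(sprintf("no length-at-age entry for realized age %d", age))
      }
      la <- config$length_at_age[[age + 1]]
      len <- pmax(0, stats::rnorm(take, la[1], la[2]))
      out[[length(out) + 1]] <- data.frame(
        id = ids, stream = config$stream, collection_year = col$year,
        length_mm = len, true_age = age, true_spawn_year = y
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate a cohort from an equilibrium random-mating population
#'
#' Forward Wright-Fisher simulation for calibrating the
#' linkage-disequilibrium effective-size estimator under its own idealized
#' model: a constant-size, random-mating population at drift-recombination
#' equilibrium. A population of `n_parents` diploids is bred forward for
#' `generations` generations (each offspring draws two distinct parents
#' uniformly; loci unlinked), so background LD reaches its stationary level
#' (unlinked LD halves each generation, so ~20 generations is ample); the
#' returned cohort of `n_offspring` is then produced by the final parental
#' generation. By contrast, a cohort founded directly by Hardy-Weinberg
#' parents carries only one generation of drift LD (about 3/4 of the
#' equilibrium level is missing), which biases the LD estimator upward by
#' roughly a third.
#'
#' @param n_parents constant population size N (and effective breeder
#'   number of the final cohort, up to the usual N - 1 correction).
#' @param n_offspring cohort size produced by the final generation.
#' @param n_loci,n_chromosomes unlinked SNPs, assigned round-robin to
#'   chromosomes (the LD method uses cross-chromosome pairs only).
#' @param generations burn-in length (default 20).
#' @param freq_range founding allele-frequency range (default 0.1-0.5;
#'   frequencies drift during burn-in, and fixed loci are dropped).
#' @param seed integer seed.
#' @return A [genotype_table()] of the cohort (loci that fixed during
#'   burn-in are dropped).
#' @export
simulate_ld_cohort <- function(n_parents, n_offspring, n_loci = 200,
                               n_chromosomes = 20, generations = 20,
                               freq_range = c(0.1, 0.5), seed = 1L) {
  stopifnot(n_parents >= 3, n_offspring >= 2, n_chromosomes >= 2)
  set.seed(seed)
  L <- n_loci
  p0 <- stats::runif(L, freq_range[1], freq_range[2])
  pop <- matrix(stats::rbinom(n_parents * L, 2, rep(p0, each = n_parents)),
                nrow = n_parents)
  breed <- function(pop, n) {
    N <- nrow(pop)
    p1 <- sample.int(N, n, replace = TRUE)
    p2 <- (p1 + sample.int(N - 1, n, replace = TRUE) - 1L) %% N + 1L
    g1 <- pop[p1, , drop = FALSE]
    g2 <- pop[p2, , drop = FALSE]
    matrix(stats::rbinom(n * L, 1, g1 / 2) + stats::rbinom(n * L, 1, g2 / 2),
           nrow = n)
  }
  for (g in seq_len(generations)) pop <- breed(pop, n_parents)
  off <- breed(pop, n_offspring)
  rownames(off) <- sprintf("eq_O%04d", seq_len(n_offspring))
  keep <- colMeans(off) / 2 > 0 & colMeans(off) / 2 < 1
  loci <- data.frame(
    id = sprintf("snp%04d", seq_len(L)),
    chrom = paste0("chr", rep(seq_len(n_chromosomes), length.out = L)),
    pos = rep(seq_len(ceiling(L / n_chromosomes)) * 1e6,
              each = n_chromosomes, length.out = L)
  )
  genotype_table(off[, keep, drop = FALSE], loci[keep, , drop = FALSE])
}

#' Write simulation fixtures to disk
#'
#' Writes the observable data (VCF v4.2 with GT:DP:AD genotypes and an
#' individuals CSV) under `out_dir/data/`, and the truth tables (pedigree and
#' cohort TSVs) under `out_dir/truth/`. The directory split is a leakage
#' guard: inference stages only ever read `data/`.
#'
#' @param truth a `truth_set`.
#' @param genotypes a [genotype_table()] from [simulate_genotypes()].
#' @param lengths data.frame from [simulate_lengths()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixtures <- function(truth, genotypes, lengths, out_dir) {
  data_dir <- file.path(out_dir, "data")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)

  # only sampled individuals are observable
  gt <- genotypes[unique(lengths$id), ]
  vcf <- file.path(data_dir, "genotypes.vcf")
  write_genotypes_vcf(gt, vcf)

  ind_csv <- file.path(data_dir, "individuals.csv")
  utils::write.csv(
    lengths[, c("id", "stream", "collection_year", "length_mm")],
    ind_csv, row.names = FALSE, quote = FALSE
  )

  ped_tsv <- file.path(truth_dir, "pedigree.tsv")
  utils::write.table(truth$pedigree[, c("offspring", "parent1", "parent2")],
                     ped_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  coh_tsv <- file.path(truth_dir, "cohorts.tsv")
  utils::write.table(
    data.frame(offspring = truth$pedigree$offspring,
               spawn_year = truth$pedigree$spawn_year),
    coh_tsv, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(list(vcf = vcf, individuals = ind_csv, pedigree = ped_tsv,
                 cohorts = coh_tsv))
}
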