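test_that("configuration is validated and simulation is seed-deterministic", {
  expect_error(sim_config(parents_per_year = 1), "parents_per_year")
  expect_error(sim_config(genotyping_error = 1), "genotyping_error")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")

  cfg <- sim_config(n_spawn_years = 2, parents_per_year = 10,
                    offspring_per_year = 30, n_loci = 40, seed = 42)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  g1 <- simulate_genotypes(t1)
  g2 <- simulate_genotypes(t2)
  expect_identical(g1$geno, g2$geno)
  expect_identical(simulate_lengths(t1), simulate_lengths(t2))

  d1 <- file.path(tempdir(), "fx_a"); d2 <- file.path(tempdir(), "fx_b")
  l1 <- simulate_lengths(t1)
  write_fixtures(t1, g1, l1, d1)
  write_fixtures(t2, g2, l1, d2)
  for (f in c("data/genotypes.vcf", "data/individuals.csv",
              "truth/pedigree.tsv", "truth/cohorts.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("semelparity and reproductive-success identities hold", {
  for (design in c("random_pairs", "polygamous_skewed")) {
    cfg <- sim_config(n_spawn_years = 3, parents_per_year = 16,
                      offspring_per_year = 50, mating_design = design,
                      vk_target = 12, n_loci = 20, seed = 7)
    tr <- simulate_truth(cfg)
    # no parent id appears in two spawn years
    year_of <- tapply(tr$parents$spawn_year, tr$parents$id, unique)
    expect_true(all(lengths(year_of) == 1))
    used <- unique(c(tr$pedigree$parent1, tr$pedigree$parent2))
    expect_true(all(used %in% tr$parents$id))
    for (y in 1:3) {
      py <- tr$pedigree[tr$pedigree$spawn_year == y, ]
      counts <- table(c(py$parent1, py$parent2))
      expect_equal(sum(counts), 2 * nrow(py))           # k-bar identity
      expect_equal(tr$repro$kbar[y], 2 * nrow(py) / length(counts))
      expect_true(all(py$parent1 != py$parent2))        # two distinct parents
      # parents of year-y offspring belong to year y's pool (semelparity)
      expect_true(all(tr$parents$spawn_year[match(names(counts),
                                                  tr$parents$id)] == y))
    }
  }

  # with exactly one possible pair, all offspring are full siblings
  cfg2 <- sim_config(n_spawn_years = 1, parents_per_year = 2,
                     offspring_per_year = 10,
                     mating_design = "random_pairs", n_loci = 10, seed = 1)
  tr2 <- simulate_truth(cfg2)
  expect_equal(nrow(unique(tr2$pedigree[, c("parent1", "parent2")])), 1)
})

test_that("the published cohort's mean reproductive success is reproduced when all parents contribute", {
  # 1011 offspring over 100 contributing parents: k-bar = 2*1011/100 = 20.22
  cfg <- sim_config(n_spawn_years = 1, parents_per_year = 100,
                    offspring_per_year = 1011,
                    mating_design = "polygamous_skewed", vk_target = 0,
                    n_loci = 10, seed = 2)
  tr <- simulate_truth(cfg)
  expect_equal(tr$repro$n_parents, 100)  # all contribute under equal weights
  expect_equal(round(tr$repro$kbar, 2), 20.22)
})

test_that("genotype simulation is Mendelian, with a working error model", {
  cfg <- sim_config(n_spawn_years = 1, parents_per_year = 20,
                    offspring_per_year = 60, n_loci = 120,
                    genotyping_error = 0, missing_rate = 0, seed = 3)
  tr <- simulate_truth(cfg)
  gt <- simulate_genotypes(tr)
  g1 <- tr$parent_geno[tr$pedigree$parent1, ]
  g2 <- tr$parent_geno[tr$pedigree$parent2, ]
  lo <- floor(g1 / 2) + floor(g2 / 2)    # minimum transmissible dosage
  hi <- ceiling(g1 / 2) + ceiling(g2 / 2)
  expect_true(all(gt$geno >= lo & gt$geno <= hi))  # zero incompatibilities
  expect_false(anyNA(gt$geno))

  # HWE heterozygosity at p = 0.5
  cfg5 <- sim_config(n_spawn_years = 1, parents_per_year = 60,
                     offspring_per_year = 200, n_loci = 60,
                     allele_freq_range = c(0.5, 0.5),
                     genotyping_error = 0, missing_rate = 0, seed = 4)
  tr5 <- simulate_truth(cfg5)
  gt5 <- simulate_genotypes(tr5)
  expect_lt(abs(mean(gt5$geno == 1) - 0.5), 0.02)

  # eps = 1: offspring genotypes independent of parents, so true sib pairs
  # carry no mean full-sib signal
  cfge <- sim_config(n_spawn_years = 1, parents_per_year = 4,
                     offspring_per_year = 20, n_loci = 200,
                     mating_design = "random_pairs",
                     genotyping_error = 0.999, missing_rate = 0, seed = 5)
  tre <- simulate_truth(cfge)
  gte <- simulate_genotypes(tre)
  rel <- pairwise_llr(gte, allele_freqs = tre$freqs, error_rate = 0.999)
  sib <- split(tre$pedigree$offspring,
               paste(tre$pedigree$parent1, tre$pedigree$parent2))
  keys <- fs_pair_keys(sib)
  pk <- paste(rel$pairs$i, rel$pairs$j, sep = "|")
  true_sib <- rel$pairs[pk %in% keys, ]
  expect_lte(mean(true_sib$ll_fs - true_sib$ll_u), 0.5)
})

test_that("length simulation follows the length-at-age model", {
  cfg <- sim_config(n_spawn_years = 1, parents_per_year = 10,
                    offspring_per_year = 400, n_loci = 10,
                    length_at_age = list(c(75, 6)),
                    collections = list(list(year = 1, frac = 1)), seed = 6)
  tr <- simulate_truth(cfg)
  len <- simulate_lengths(tr)
  expect_equal(nrow(len), 400)
  expect_lt(abs(mean(len$length_mm) - 75), 3 * 6 / sqrt(400))

  cfg0 <- sim_config(n_spawn_years = 1, parents_per_year = 10,
                     offspring_per_year = 50, n_loci = 10,
                     length_at_age = list(c(60, 0)),
                     collections = list(list(year = 1, frac = 1)), seed = 6)
  len0 <- simulate_lengths(simulate_truth(cfg0))
  expect_true(all(len0$length_mm == 60))  # degenerate sd

  cfg_bad <- sim_config(n_spawn_years = 1, parents_per_year = 10,
                        offspring_per_year = 20, n_loci = 10,
                        length_at_age = list(c(60, 5)),
                        collections = list(list(year = 3, frac = 1)),
                        seed = 6)
  expect_error(simulate_lengths(simulate_truth(cfg_bad)), "length-at-age")
})

test_that("fixtures round-trip and keep truth apart from data", {
  cfg <- sim_config(n_spawn_years = 2, parents_per_year = 12,
                    offspring_per_year = 40, n_loci = 50,
                    length_at_age = list(c(45, 5), c(80, 6), c(100, 6)),
                    collections = list(list(year = 2, frac = 0.8)), seed = 8)
  tr <- simulate_truth(cfg)
  g <- simulate_genotypes(tr)
  len <- simulate_lengths(tr)
  out <- file.path(tempdir(), "fx_rt")
  fx <- write_fixtures(tr, g, len, out)

  gt2 <- read_genotypes_vcf(fx$vcf)
  ids <- rownames(gt2$geno)
  expect_setequal(ids, unique(len$id))
  expect_equal(unname(gt2$geno[ids, ]), unname(g$geno[ids, ]))
  expect_equal(unname(gt2$depth[ids, ]), unname(g$depth[ids, ]),
               ignore_attr = TRUE)
  expect_equal(gt2$loci$pos, g$loci$pos)        # 1-based positions usable
  expect_equal(gt2$loci$chrom, g$loci$chrom)    # for the 1-Mb thinning rule
  expect_equal(gt2$loci$target_region, g$loci$target_region)

  # leakage guard: truth tables live outside data/
  expect_true(all(startsWith(c(fx$pedigree, fx$cohorts),
                             file.path(out, "truth"))))
  expect_true(all(startsWith(c(fx$vcf, fx$individuals),
                             file.path(out, "data"))))
})
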