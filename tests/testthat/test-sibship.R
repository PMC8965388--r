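test_that("single-locus pair probabilities match hand enumeration", {
  # both individuals homozygous for the allele at frequency 0.5:
  # P(U) = p^4 = 0.0625; P(FS) = p^4/4 + p^3/2 + p^2/4 = 0.140625
  g <- rbind(a = 2L, b = 2L)
  rel <- pairwise_llr(g, allele_freqs = 0.5, error_rate = 0, min_loci = 1)
  expect_equal(exp(rel$pairs$ll_u), 0.0625)
  expect_equal(exp(rel$pairs$ll_fs), 0.140625)
  # half-sib: p^3/2 + p^4/2
  expect_equal(exp(rel$pairs$ll_hs), 0.5 * 0.125 + 0.5 * 0.0625)

  # each relationship's pair table is a proper distribution (k-weights sum 1)
  tab <- lampreyNb:::sib_tables(c(0.2, 0.5, 0.37), 0.01)
  for (W in list(tab$logU, tab$logFS, tab$logHS)) {
    expect_equal(colSums(exp(W)), rep(1, 3))
  }
})

test_that("pairwise likelihoods separate duplicates, sibs and unrelated", {
  # several families so sample allele-frequency estimates are stable
  tr <- make_family_truth(sizes = c(5, 5, 5, 5, 5), seed = 21)
  cfg <- sim_config(n_loci = 200, genotyping_error = 0.001,
                    missing_rate = 0, seed = 21)
  gt <- simulate_genotypes(tr, cfg)
  g <- gt$geno
  g <- rbind(g, dup = g[1, ])  # duplicated genotype vector
  rel <- pairwise_llr(g, error_rate = 0.001)
  p <- rel$pairs
  dup_row <- p[p$i == rownames(g)[1] & p$j == "dup", ]
  expect_gt(dup_row$ll_fs, dup_row$ll_hs)
  expect_gt(dup_row$ll_fs, dup_row$ll_u)

  across <- p[substr(p$i, 1, 3) == "F01" & substr(p$j, 1, 3) == "F02", ]
  expect_lt(mean(across$ll_fs - across$ll_u), 0)
  within <- p[substr(p$i, 1, 3) == "F01" & substr(p$j, 1, 3) == "F01", ]
  expect_true(all(within$ll_fs > within$ll_u))

  # pairs below min_loci are unclassifiable
  g[2, 1:150] <- NA
  rel2 <- pairwise_llr(g, error_rate = 0.001, min_loci = 100)
  p2 <- rel2$pairs
  expect_false(any(p2$classifiable[p2$i == rownames(g)[2] |
                                     p2$j == rownames(g)[2]]))
})

test_that("full-sib partition recovers simulated families exactly", {
  tr <- make_family_truth(sizes = rep(5, 10), n_loci = 300, seed = 22)
  cfg <- sim_config(n_loci = 300, genotyping_error = 0.001,
                    missing_rate = 0, seed = 22)
  gt <- simulate_genotypes(tr, cfg)
  rel <- pairwise_llr(gt, error_rate = 0.001)
  fams <- partition_fullsib(rel)
  truth <- split(tr$pedigree$offspring, tr$family)
  expect_setequal(fs_pair_keys(fams), fs_pair_keys(truth))

  # infinite threshold: no edges, every offspring a singleton
  singles <- partition_fullsib(rel, threshold = Inf, refine = FALSE)
  expect_equal(lengths(singles), rep(1L, nrow(gt$geno)))

  # a spuriously merged pair of families is split again by refinement:
  # drop the threshold so low that cross-family edges appear
  loose <- partition_fullsib(rel, threshold = -30, refine = FALSE)
  merged <- any(vapply(loose, function(f)
    length(unique(tr$family[match(f, tr$pedigree$offspring)])) > 1,
    logical(1)))
  expect_true(merged)
  refined <- partition_fullsib(rel, threshold = -30, refine = TRUE)
  expect_setequal(fs_pair_keys(refined), fs_pair_keys(truth))
})

test_that("parental genotype reconstruction matches enumeration", {
  # six offspring all homozygous reference at one locus, p = 0.5
  fam <- matrix(0L, 6, 1)
  rp <- reconstruct_parents(fam, allele_freqs = 0.5, error_rate = 0)
  expect_equal(rp$map_class, "0/0")
  # posterior ratio vs the runner-up (0/1): prior 2pq*p^2 times (1/2)^6
  post <- rp$posterior[, 1]
  expect_equal(unname(post["0/0"] / post["0/1"]),
               (0.25 * 0.25) / (2 * 0.25 * 0.5 * (0.5)^6))

  # offspring dosages {0,1,2} in one family force het x het parents
  fam2 <- matrix(c(0L, 1L, 2L), 3, 1)
  rp2 <- reconstruct_parents(fam2, allele_freqs = 0.5, error_rate = 0)
  expect_equal(rp2$map_class, "1/1")
  expect_equal(unname(rp2$posterior["1/1", 1]), 1)

  # posterior entropy grows with the mistyping rate
  set.seed(23)
  fam3 <- matrix(rbinom(8 * 30, 2, 0.4), 8, 30)
  ent <- vapply(c(0.001, 0.05, 0.2), function(e) {
    post <- reconstruct_parents(fam3, allele_freqs = rep(0.4, 30),
                                error_rate = e)$posterior
    mean(-colSums(ifelse(post > 0, post * log(post), 0)))
  }, numeric(1))
  expect_true(all(diff(ent) > 0))

  # all-missing locus: uninformative, posterior equals the pair prior
  fam4 <- matrix(NA_integer_, 4, 1)
  rp4 <- reconstruct_parents(fam4, allele_freqs = 0.3, error_rate = 0.001)
  expect_true(rp4$uninformative[1])
  expect_equal(sum(rp4$posterior[, 1]), 1)
})

test_that("half-sib linking finds true shared parents and resists false ones", {
  # two families of 6 sharing one parent, among unrelated families
  tr <- make_family_truth(sizes = rep(6, 6), shares = list(c(1, 2)),
                          n_loci = 300, seed = 24)
  cfg <- sim_config(n_loci = 300, genotyping_error = 0.001,
                    missing_rate = 0, seed = 24)
  gt <- simulate_genotypes(tr, cfg)
  rel <- pairwise_llr(gt, error_rate = 0.001)
  fams <- partition_fullsib(rel)
  ped <- link_halfsibs(rel, fams)
  expect_equal(ped$n_parents, 11)  # 12 slots, one shared
  # the shared parent joins families 1 and 2
  fam_idx <- vapply(ped$families, function(f)
    unique(tr$family[match(f, tr$pedigree$offspring)])[1], numeric(1))
  p1 <- ped$family_parents[fam_idx == 1, ]
  p2 <- ped$family_parents[fam_idx == 2, ]
  expect_length(intersect(p1, p2), 1)

  # disjoint families: no links in at least 9 of 10 seeded replicates
  clean <- vapply(1:10, function(s) {
    trd <- make_family_truth(sizes = rep(5, 6), n_loci = 200, seed = 100 + s)
    cfgd <- sim_config(n_loci = 200, genotyping_error = 0.001,
                       missing_rate = 0, seed = 100 + s)
    gtd <- simulate_genotypes(trd, cfgd)
    reld <- pairwise_llr(gtd, error_rate = 0.001)
    pd <- link_halfsibs(reld, partition_fullsib(reld))
    pd$n_parents == 12
  }, logical(1))
  expect_gte(sum(clean), 9)

  # a single family yields exactly two parents (population allele
  # frequencies supplied: a lone family cannot estimate its own)
  tr1 <- make_family_truth(sizes = 5, n_loci = 100, seed = 25)
  cfg1 <- sim_config(n_loci = 100, genotyping_error = 0.001,
                     missing_rate = 0, seed = 25)
  rel1 <- pairwise_llr(simulate_genotypes(tr1, cfg1),
                       allele_freqs = tr1$freqs, error_rate = 0.001)
  ped1 <- link_halfsibs(rel1, partition_fullsib(rel1))
  expect_equal(ped1$n_parents, 2)
})

test_that("family clusters are pedigree components with bootstrap support", {
  # offspring1-2 share parent X, offspring2-3 share parent Y -> one cluster
  ped_df <- data.frame(offspring = c("o1", "o2", "o3"),
                       parent1 = c("X", "X", "Y"),
                       parent2 = c("A", "Y", "B"))
  ped <- structure(list(pedigree = ped_df,
                        families = list("o1", "o2", "o3"),
                        family_parents = cbind(c("X", "X", "Y"),
                                               c("A", "Y", "B")),
                        n_parents = 4),
                   class = c("pedigree", "list"))
  cl <- family_clusters(ped)
  expect_equal(length(unique(cl$cluster_id)), 1)

  ped_df2 <- data.frame(offspring = c("o1", "o2", "o3", "o4"),
                        parent1 = c("A", "A", "C", "C"),
                        parent2 = c("B", "B", "D", "D"))
  ped2 <- structure(list(pedigree = ped_df2,
                         families = list(c("o1", "o2"), c("o3", "o4")),
                         family_parents = cbind(c("A", "C"), c("B", "D")),
                         n_parents = 4),
                    class = c("pedigree", "list"))
  cl2 <- family_clusters(ped2)
  expect_equal(length(unique(cl2$cluster_id)), 2)
  expect_true(all(cl2$support == 1))  # single-family clusters

  # strong simulated signal: linked cluster survives locus bootstrap
  tr <- make_family_truth(sizes = rep(8, 3), shares = list(c(1, 2)),
                          n_loci = 300, seed = 26)
  cfg <- sim_config(n_loci = 300, genotyping_error = 0.001,
                    missing_rate = 0, seed = 26)
  rel <- pairwise_llr(simulate_genotypes(tr, cfg), error_rate = 0.001)
  ped3 <- link_halfsibs(rel, partition_fullsib(rel))
  cl3 <- family_clusters(ped3, rel = rel, B = 15, seed = 3)
  linked <- tapply(cl3$support, cl3$cluster_id, unique)
  expect_gte(max(unlist(linked)), 0.9)
  expect_error(family_clusters(ped3, rel = rel, B = 0), "B must be")
})

test_that("the pedigree identity sum(parent counts) = 2 n holds end-to-end", {
  tr <- make_family_truth(sizes = c(3, 4, 5, 6), shares = list(c(1, 3)),
                          n_loci = 200, seed = 27)
  cfg <- sim_config(n_loci = 200, genotyping_error = 0.001,
                    missing_rate = 0.02, seed = 27)
  ped <- reconstruct_pedigree(simulate_genotypes(tr, cfg), seed = 1)
  counts <- table(c(ped$pedigree$parent1, ped$pedigree$parent2))
  expect_equal(sum(counts), 2 * nrow(ped$pedigree))
  rs <- repro_summary(ped)
  expect_equal(rs$kbar * rs$N_s, 2 * rs$n)
})
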