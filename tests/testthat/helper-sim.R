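# Shared fixture builders (everything is generated in code at test time).

# adjusted Rand index between two labelings
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_i <- sa * sb / choose(n, 2)
  (si - exp_i) / ((sa + sb) / 2 - exp_i)
}

# hand-built truth set: explicit full-sib families with optional shared
# parents, compatible with simulate_genotypes(). `shares` is a list of
# c(family_a, family_b) pairs that share one parent.
make_family_truth <- function(sizes, shares = list(), n_loci = 200,
                              seed = 1, spawn_year = NULL,
                              freq_range = c(0.05, 0.5)) {
  set.seed(seed)
  n_fam <- length(sizes)
  if (is.null(spawn_year)) spawn_year <- rep(1L, n_fam)
  # parent slots: 2 per family, then collapse shared ones
  slot_parent <- matrix(paste0("P", seq_len(2 * n_fam)), ncol = 2,
                        byrow = TRUE)
  for (s in shares) {
    slot_parent[s[2], 1] <- slot_parent[s[1], 1]
  }
  parents <- sort(unique(as.vector(slot_parent)))
  freqs <- runif(n_loci, freq_range[1], freq_range[2])
  parent_geno <- matrix(
    rbinom(length(parents) * n_loci, 2, rep(freqs, each = length(parents))),
    nrow = length(parents), dimnames = list(parents, NULL)
  )
  ped <- do.call(rbind, lapply(seq_len(n_fam), function(f) {
    data.frame(
      offspring = sprintf("F%02d_O%02d", f, seq_len(sizes[f])),
      parent1 = slot_parent[f, 1], parent2 = slot_parent[f, 2],
      spawn_year = spawn_year[f]
    )
  }))
  loci <- data.frame(
    id = sprintf("snp%04d", seq_len(n_loci)),
    chrom = paste0("chr", rep(1:20, length.out = n_loci)),
    pos = rep(seq_len(ceiling(n_loci / 20)) * 2e6, each = 20,
              length.out = n_loci),
    target_region = sprintf("tag%04d", seq_len(n_loci))
  )
  colnames(parent_geno) <- loci$id
  structure(
    list(pedigree = ped,
         parents = data.frame(id = parents, spawn_year = 1L),
         parent_geno = parent_geno, freqs = freqs, loci = loci,
         family = rep(seq_len(n_fam), sizes)),
    class = c("truth_set", "list")
  )
}

# unordered pair keys of within-family pairs, for recall/precision
fs_pair_keys <- function(groups) {
  unlist(lapply(groups, function(f) {
    f <- sort(f)
    if (length(f) > 1) apply(utils::combn(f, 2), 2, paste, collapse = "|")
  }))
}

# reduced MCMC settings used throughout the tests to stay inside the time
# budget; chains this short are ample for the well-separated test data
test_mcmc <- list(iter = 1200L, burn = 300L, thin = 3L)
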