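# Sibship and pedigree reconstruction from offspring SNP genotypes.
#
# The model: unordered diploid parent pairs, Mendelian transmission,
# and a single-parameter mistyping model in which an observed genotype is,
# with probability `error_rate`, replaced by a random Hardy-Weinberg draw at
# that locus. Relationship classes are characterized by the usual
# identity-coefficient mixtures over the number of parents shared:
# full sibs (1/4, 1/2, 1/4), half sibs (1/2, 1/2, 0), unrelated (1, 0, 0)
# for (0, 1, 2) shared-parent-derived allele paths.

# Mendelian transmission table: P(offspring dosage | parental dosages).
# Dimensions [gm + 1, gf + 1, g + 1] for dosages in 0..2.
mendel_table <- function() {
  M <- array(0, c(3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) {
    pa <- gm / 2; pb <- gf / 2
    M[gm + 1, gf + 1, 1] <- (1 - pa) * (1 - pb)
    M[gm + 1, gf + 1, 2] <- pa * (1 - pb) + (1 - pa) * pb
    M[gm + 1, gf + 1, 3] <- pa * pb
  }
  M
}

# Per-locus probability machinery shared by all sibship operations.
# freqs = frequency of the counted (alternate) allele; eps = mistyping rate.
# Returns per-locus log pair-probability tables for FS/HS/U (9 x L, row index
# 3*g_i + g_j + 1), log emission-integrated offspring tables for each ordered
# parental pair (as a 9 x 3L matrix for fast gathering), the log HWE genotype
# priors, and the log ordered-pair priors.
sib_tables <- function(freqs, eps) {
  L <- length(freqs)
  hwe <- rbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2)  # 3 x L
  M <- mendel_table()

  logU <- logFS <- logHS <- matrix(NA_real_, 9, L)
  # offspring emission table: rows = ordered parental combo (3*gm + gf + 1),
  # columns = (locus - 1)*3 + observed genotype + 1
  logO <- matrix(NA_real_, 9, 3 * L)
  for (l in seq_len(L)) {
    p <- freqs[l]
    pi_l <- hwe[, l]
    E <- (1 - eps) * diag(3) + eps * matrix(pi_l, 3, 3, byrow = TRUE)
    # shared-allele pair table S1[g, h] = sum_a f_a T_a(g) T_a(h)
    T1 <- c(0, 1 - p, p)        # shared allele is the counted allele
    T0 <- c(1 - p, p, 0)        # shared allele is the other allele
    S1 <- p * tcrossprod(T1) + (1 - p) * tcrossprod(T0)
    U <- tcrossprod(pi_l)
    FS <- 0.25 * U + 0.5 * S1 + 0.25 * diag(pi_l)
    HS <- 0.5 * U + 0.5 * S1
    logU[, l] <- log(crossprod(E, U %*% E))
    logFS[, l] <- log(crossprod(E, FS %*% E))
    logHS[, l] <- log(crossprod(E, HS %*% E))
    # P(obs g | gm, gf) integrated over the true genotype and the emission
    for (g in 0:2) {
      Pg <- M[, , 1] * E[1, g + 1] + M[, , 2] * E[2, g + 1] +
        M[, , 3] * E[3, g + 1]
      logO[, (l - 1) * 3 + g + 1] <- log(as.vector(t(Pg)))  # row = 3*gm+gf+1
    }
  }
  logpi <- log(hwe)
  logprior9 <- logpi[rep(1:3, each = 3), , drop = FALSE] +
    logpi[rep(1:3, times = 3), , drop = FALSE]  # row = 3*gm + gf + 1
  list(freqs = freqs, eps = eps, hwe = hwe, logpi = logpi,
       logU = logU, logFS = logFS, logHS = logHS,
       logO = cbind(logO, 0), logprior9 = logprior9, L = L)
}

# column-wise log-sum-exp of a matrix (hot path: no apply)
colLSE <- function(X) {
  m <- X[1, ]
  if (nrow(X) > 1) for (r in 2:nrow(X)) m <- pmax(m, X[r, ])
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    Xs <- X[, ok, drop = FALSE]
    out[ok] <- m[ok] + log(colSums(exp(Xs - rep(m[ok], each = nrow(X)))))
  }
  out
}

#' Pairwise relationship log-likelihoods
#'
#' Computes, for every pair of individuals, the log-likelihood of their
#' genotypes under full-sib, half-sib and unrelated hypotheses, using only
#' loci called in both individuals. Monomorphic loci carry no information
#' and are dropped. Allele frequencies default to estimates from the
#' offspring sample itself (parents are unsampled).
#'
#' @param gt a [genotype_table()] or a dosage matrix (individuals x loci).
#' @param allele_freqs optional per-locus counted-allele frequencies.
#' @param error_rate mistyping rate (default 0.001).
#' @param min_loci pairs with fewer overlapping called loci are marked
#'   unclassifiable (default 50).
#' @return An object of class `rel_likelihoods`: pairwise matrices `ll_fs`,
#'   `ll_hs`, `ll_u`, `n_loci`, a long-format `pairs` data.frame (`i`, `j`,
#'   log-likelihoods, `n_loci`, `classifiable`), and the genotype matrix and
#'   locus tables reused by downstream sibship operations.
#' @export
pairwise_llr <- function(gt, allele_freqs = NULL, error_rate = 0.001,
                         min_loci = 50) {
  g <- if (inherits(gt, "genotype_table")) gt$geno else as.matrix(gt)
  stopifnot(error_rate >= 0)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(allele_freqs) & allele_freqs > 0 & allele_freqs < 1
  g <- g[, poly, drop = FALSE]
  freqs <- allele_freqs[poly]
  tab <- sib_tables(freqs, error_rate)

  n <- nrow(g)
  ind <- lapply(0:2, function(v) {
    I <- matrix(0, n, ncol(g)); I[!is.na(g) & g == v] <- 1; I
  })
  pair_ll <- function(W) {  # W: 9 x L log table
    LL <- matrix(0, n, n)
    for (a in 1:3) for (b in 1:3) {
      r <- (a - 1) * 3 + b
      LL <- LL + (ind[[a]] * matrix(W[r, ], n, ncol(g), byrow = TRUE)) %*%
        t(ind[[b]])
    }
    LL
  }
  ll_fs <- pair_ll(tab$logFS)
  ll_hs <- pair_ll(tab$logHS)
  ll_u <- pair_ll(tab$logU)
  called <- ind[[1]] + ind[[2]] + ind[[3]]
  n_loci <- tcrossprod(called)

  ut <- which(upper.tri(n_loci), arr.ind = TRUE)
  pairs <- data.frame(
    i = rownames(g)[ut[, 1]], j = rownames(g)[ut[, 2]],
    ll_fs = ll_fs[ut], ll_hs = ll_hs[ut], ll_u = ll_u[ut],
    n_loci = n_loci[ut]
  )
  pairs$classifiable <- pairs$n_loci >= min_loci
  structure(
    list(pairs = pairs, ll_fs = ll_fs, ll_hs = ll_hs, ll_u = ll_u,
         n_loci = n_loci, ids = rownames(g), geno = g, tables = tab,
         error_rate = error_rate, min_loci = min_loci),
    class = c("rel_likelihoods", "list")
  )
}

#' @export
print.rel_likelihoods <- function(x, ...) {
  cat(sprintf("rel_likelihoods: %d individuals, %d polymorphic loci, %d pairs (%d classifiable)\n",
              length(x$ids), x$tables$L, nrow(x$pairs), sum(x$pairs$classifiable)))
  invisible(x)
}

# log-likelihood of a putative full-sib family: per locus, the Mendelian
# likelihood of all members integrated over the unordered parental genotype
# pair under HWE priors. members = integer indices into rel$ids.
family_loglik_terms <- function(rel, members) {
  tab <- rel$tables
  L <- tab$L
  S <- matrix(0, 9, L)
  for (o in members) {
    gv <- rel$geno[o, ]
    cols <- ifelse(is.na(gv), 3L * L + 1L, (seq_len(L) - 1L) * 3L + gv + 1L)
    S <- S + tab$logO[, cols, drop = FALSE]
  }
  S
}

family_loglik <- function(rel, members) {
  if (length(members) == 0) return(0)
  S <- family_loglik_terms(rel, members) + rel$tables$logprior9
  sum(colLSE(S))
}

# log h_F(g_shared, l): family likelihood with one parent fixed at dosage
# g_shared and the other integrated over HWE. 3 x L matrix.
family_logh <- function(rel, members) {
  S <- family_loglik_terms(rel, members)
  logpi <- rel$tables$logpi
  t(vapply(1:3, function(gm) {
    rows <- (gm - 1) * 3 + (1:3)
    colLSE(S[rows, , drop = FALSE] + logpi)
  }, numeric(rel$tables$L)))
}

#' Partition offspring into full-sib families
#'
#' Builds a graph with an edge between every classifiable pair whose
#' full-sib log-likelihood exceeds the better of half-sib and unrelated by
#' more than `threshold`; connected components seed the partition, which is
#' then refined greedily: single offspring are moved between families
#' (including to a new singleton) whenever the move increases the summed
#' joint family likelihood (each family's Mendelian likelihood integrated
#' over its unordered parental genotype pair).
#'
#' @param rel a [pairwise_llr()] result.
#' @param threshold full-sib edge log-likelihood margin (default 0).
#' @param refine run the greedy joint-likelihood refinement (default TRUE).
#' @param max_passes maximum refinement sweeps over all offspring.
#' @return List of character vectors, one per family (singletons allowed),
#'   in a deterministic order.
#' @export
partition_fullsib <- function(rel, threshold = 0, refine = TRUE,
                              max_passes = 5) {
  p <- rel$pairs
  edge <- p$classifiable & (p$ll_fs - pmax(p$ll_hs, p$ll_u)) > threshold
  gr <- igraph::graph_from_data_frame(
    p[edge, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = rel$ids)
  )
  comp <- igraph::components(gr)$membership[rel$ids]
  fams <- split(seq_along(rel$ids), comp)

  if (refine && length(rel$ids) > 1) {
    logprior9 <- rel$tables$logprior9
    # per-offspring log-emission term (9 x L), summed per family
    terms <- lapply(seq_along(rel$ids), function(o)
      family_loglik_terms(rel, o))
    Sf <- lapply(fams, function(m) Reduce(`+`, terms[m]))
    lse <- function(S) sum(colLSE(S + logprior9))
    ll <- vapply(Sf, lse, numeric(1))
    fam_of <- integer(length(rel$ids))
    for (f in seq_along(fams)) fam_of[fams[[f]]] <- f
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (o in seq_along(rel$ids)) {
        a <- fam_of[o]
        singleton_a <- length(fams[[a]]) == 1
        S_a_wo <- Sf[[a]] - terms[[o]]
        ll_a_wo <- if (singleton_a) 0 else lse(S_a_wo)
        best_gain <- 1e-9; best_b <- NA
        for (b in seq_along(fams)) {
          if (b == a || length(fams[[b]]) == 0) next
          gain <- (ll_a_wo + lse(Sf[[b]] + terms[[o]])) - (ll[[a]] + ll[[b]])
          if (gain > best_gain) { best_gain <- gain; best_b <- b }
        }
        if (!singleton_a) {  # moving out to a brand-new singleton family
          gain <- (ll_a_wo + lse(terms[[o]])) - ll[[a]]
          if (gain > best_gain) { best_gain <- gain; best_b <- 0 }
        }
        if (!is.na(best_b)) {
          fams[[a]] <- setdiff(fams[[a]], o)
          Sf[[a]] <- S_a_wo
          ll[[a]] <- ll_a_wo
          if (best_b == 0) {
            fams[[length(fams) + 1]] <- o
            Sf[[length(fams)]] <- terms[[o]]
            ll <- c(ll, lse(terms[[o]]))
            fam_of[o] <- length(fams)
          } else {
            fams[[best_b]] <- c(fams[[best_b]], o)
            Sf[[best_b]] <- Sf[[best_b]] + terms[[o]]
            ll[[best_b]] <- lse(Sf[[best_b]])
            fam_of[o] <- best_b
          }
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    fams <- fams[lengths(fams) > 0]
  }
  fams <- fams[order(vapply(fams, min, numeric(1)))]
  lapply(unname(fams), function(m) rel$ids[sort(m)])
}

#' Reconstruct parental genotypes of a full-sib family
#'
#' For each locus, the posterior over the six unordered parental genotype
#' pair classes, proportional to the Hardy-Weinberg prior on the pair times
#' the product of member genotype probabilities under the mistyping model.
#'
#' @param geno dosage matrix (or [genotype_table()]) of the family members.
#' @param allele_freqs per-locus counted-allele frequencies.
#' @param error_rate mistyping rate.
#' @return List with `posterior` (6 x L matrix over classes
#'   `"0/0","0/1","0/2","1/1","1/2","2/2"` of parental dosage pairs),
#'   `map_class`, `map_prob` (per-locus argmax and its posterior), and
#'   `uninformative` (loci where every member is missing, where the
#'   posterior equals the prior).
#' @export
reconstruct_parents <- function(geno, allele_freqs = NULL,
                                error_rate = 0.001) {
  g <- if (inherits(geno, "genotype_table")) geno$geno else as.matrix(geno)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(g, na.rm = TRUE) / 2
  tab <- sib_tables(allele_freqs, error_rate)
  rel <- list(geno = g, tables = tab)
  S <- family_loglik_terms(rel, seq_len(nrow(g))) + tab$logprior9
  # fold ordered pairs (gm, gf) to unordered classes
  ord_pairs <- cbind(rep(0:2, each = 3), rep(0:2, times = 3))
  cls <- apply(ord_pairs, 1, function(r) paste(sort(r), collapse = "/"))
  classes <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  W <- exp(sweep(S, 2, apply(S, 2, max)))
  post <- rowsum(W, cls)[classes, , drop = FALSE]
  post <- sweep(post, 2, colSums(post), "/")
  map_i <- apply(post, 2, which.max)
  list(
    posterior = post,
    map_class = classes[map_i],
    map_prob = post[cbind(map_i, seq_len(ncol(post)))],
    uninformative = colSums(!is.na(g)) == 0,
    classes = classes
  )
}

#' Link families through shared (half-sib) parents
#'
#' Greedy agglomerative linking of parent "slots" (each family has two).
#' A candidate link between two slot-clusters is scored by the gain in a
#' composite log-likelihood: the likelihood of all involved families with
#' one shared parent genotype integrated jointly across them (each family's
#' other parent integrated freely over Hardy-Weinberg) versus fully
#' independent parents. The best-scoring valid merge is accepted while the
#' gain exceeds `threshold`; a merge is invalid if it would force the two
#' parents of one family to coincide. Final slot-clusters become the global
#' parent ids.
#'
#' @param rel a [pairwise_llr()] result.
#' @param families full-sib partition from [partition_fullsib()].
#' @param threshold minimum log-likelihood gain to accept a shared parent
#'   (default 10, calibrated so false links are rare across the thousands of
#'   family pairs a pooled stream analysis tests).
#' @return An object of class `pedigree`: data.frame `pedigree`
#'   (`offspring`, `parent1`, `parent2`), `families`, `family_parents`
#'   (matrix of the two parent ids per family), and bookkeeping reused by
#'   [family_clusters()].
#' @export
link_halfsibs <- function(rel, families, threshold = 10) {
  stopifnot(length(families) >= 1)
  Fn <- length(families)
  idx <- lapply(families, function(f) match(f, rel$ids))
  logh <- lapply(idx, function(m) family_logh(rel, m))
  famll <- vapply(idx, function(m) family_loglik(rel, m), numeric(1))
  logpi <- rel$tables$logpi

  # slots: 2 per family; clusters of slots, each cluster = one shared parent.
  # Cached per cluster: its family set, the sum of family log-h matrices, and
  # its composite score sum_l log sum_gs pi(gs) prod_F h_F(gs, l); a
  # singleton cluster scores exactly its family log-likelihood.
  slot_fam <- rep(seq_len(Fn), each = 2)
  cl_of <- seq_along(slot_fam)
  cl_fams <- lapply(slot_fam, identity)
  cl_sumlogh <- logh[slot_fam]
  cl_score <- famll[slot_fam]
  active <- rep(TRUE, length(slot_fam))

  union_score <- function(a, b) {
    sum(colLSE(logpi + cl_sumlogh[[a]] + cl_sumlogh[[b]]))
  }
  gain_ab <- function(a, b) {
    fa <- cl_fams[[a]]; fb <- cl_fams[[b]]
    if (length(intersect(fa, fb)) > 0) return(-Inf)
    # two distinct full-sib families may share at most one parent: if some
    # family pair across the clusters already shares a parent elsewhere,
    # this merge would collapse both parent slots and is rejected
    for (f in fa) {
      cf <- cl_of[c(2 * f - 1, 2 * f)]
      for (g in fb) {
        if (any(cf %in% cl_of[c(2 * g - 1, 2 * g)])) return(-Inf)
      }
    }
    union_score(a, b) - cl_score[[a]] - cl_score[[b]]
  }

  K <- length(slot_fam)
  gains <- matrix(-Inf, K, K)
  for (a in seq_len(K)) for (b in seq_len(a - 1L)) {
    gains[a, b] <- gain_ab(a, b)
  }
  repeat {
    if (max(gains) <= threshold) break
    w <- which(gains == max(gains), arr.ind = TRUE)[1, ]
    a <- w[1]; b <- w[2]
    cl_score[[a]] <- union_score(a, b)
    cl_fams[[a]] <- c(cl_fams[[a]], cl_fams[[b]])
    cl_sumlogh[[a]] <- cl_sumlogh[[a]] + cl_sumlogh[[b]]
    cl_of[cl_of == b] <- a
    active[b] <- FALSE
    gains[b, ] <- -Inf; gains[, b] <- -Inf
    # recompute gains for every cluster touching a family of the merged
    # cluster: both scores and share-validity can change for them
    affected <- which(active & vapply(cl_fams, function(s)
      length(intersect(s, cl_fams[[a]])) > 0, logical(1)))
    for (x in affected) {
      for (y in which(active)) {
        if (y == x) next
        gains[max(x, y), min(x, y)] <- gain_ab(max(x, y), min(x, y))
      }
    }
  }

  act <- which(active)
  parent_id <- setNames(sprintf("P%03d", seq_along(act)), act)
  fam_parents <- t(vapply(seq_len(Fn), function(f) {
    parent_id[as.character(cl_of[c(2 * f - 1, 2 * f)])]
  }, character(2)))
  ped <- do.call(rbind, lapply(seq_len(Fn), function(f) {
    data.frame(offspring = families[[f]],
               parent1 = unname(fam_parents[f, 1]),
               parent2 = unname(fam_parents[f, 2]))
  }))
  structure(
    list(pedigree = ped, families = families, family_parents = fam_parents,
         n_parents = length(act)),
    class = c("pedigree", "list")
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d offspring, %d full-sib families, %d inferred parents\n",
              nrow(x$pedigree), length(x$families), x$n_parents))
  invisible(x)
}

#' Family clusters and locus-bootstrap support
#'
#' A family cluster is a connected component of the offspring-parent
#' bipartite graph: offspring joined through chains of shared parents, not
#' necessarily siblings. Support for each multi-family cluster is the
#' fraction of `B` locus-bootstrap replicates (loci resampled with
#' replacement; full-sib partition and half-sib linking rerun on the
#' cluster's members) in which the members remain a single component.
#' Singleton-family clusters have support 1 by definition.
#'
#' @param ped a [link_halfsibs()] pedigree.
#' @param rel the [pairwise_llr()] object used to build it (needed for
#'   bootstrap; omit to skip support computation).
#' @param B bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param fs_threshold,hs_threshold thresholds passed through to the rerun.
#' @return data.frame `cluster_id`, `offspring_id`, `support`.
#' @export
family_clusters <- function(ped, rel = NULL, B = 100, seed = 1L,
                            fs_threshold = 0, hs_threshold = 10) {
  if (!is.null(rel) && B < 1) stop("B must be at least 1")
  edges <- rbind(
    data.frame(from = ped$pedigree$offspring, to = ped$pedigree$parent1),
    data.frame(from = ped$pedigree$offspring, to = ped$pedigree$parent2)
  )
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  memb <- igraph::components(gr)$membership
  off_memb <- memb[ped$pedigree$offspring]
  cl_ids <- sort(unique(off_memb))
  cluster_id <- match(off_memb, cl_ids)

  fam_of <- rep(seq_along(ped$families), lengths(ped$families))
  names(fam_of) <- unlist(ped$families)
  support <- rep(NA_real_, length(cl_ids))
  for (k in seq_along(cl_ids)) {
    members <- ped$pedigree$offspring[cluster_id == k]
    n_fam <- length(unique(fam_of[members]))
    if (n_fam == 1 || is.null(rel)) {
      support[k] <- if (n_fam == 1) 1 else NA_real_
      next
    }
    set.seed(seed + k)
    ok <- 0
    gsub <- rel$geno[members, , drop = FALSE]
    for (b in seq_len(B)) {
      loc <- sample.int(ncol(gsub), replace = TRUE)
      rb <- pairwise_llr(gsub[, loc, drop = FALSE],
                         allele_freqs = rel$tables$freqs[loc],
                         error_rate = rel$error_rate,
                         min_loci = rel$min_loci)
      fb <- partition_fullsib(rb, threshold = fs_threshold, max_passes = 2)
      pb <- link_halfsibs(rb, fb, threshold = hs_threshold)
      eb <- rbind(
        data.frame(from = pb$pedigree$offspring, to = pb$pedigree$parent1),
        data.frame(from = pb$pedigree$offspring, to = pb$pedigree$parent2)
      )
      gb <- igraph::graph_from_data_frame(eb, directed = FALSE)
      mb <- igraph::components(gb)$membership[members]
      if (length(unique(mb)) == 1) ok <- ok + 1
    }
    support[k] <- ok / B
  }
  data.frame(
    cluster_id = paste0("FC", cluster_id),
    offspring_id = ped$pedigree$offspring,
    support = support[cluster_id]
  )
}

#' Reconstruct a pedigree from genotypes in one call
#'
#' Convenience driver chaining [pairwise_llr()], [partition_fullsib()],
#' [link_halfsibs()] and [family_clusters()].
#'
#' @param gt a [genotype_table()] or dosage matrix.
#' @param error_rate,fs_threshold,hs_threshold,min_loci model and decision
#'   parameters (defaults 0.001, 0, 5, 50).
#' @param run_length `"medium"` (2 refinement passes) or `"long"` (6).
#' @param bootstrap_B locus-bootstrap replicates for cluster support; 0
#'   skips support computation.
#' @param seed integer seed for bootstrap and tie-breaking.
#' @return A `pedigree` object with an added `clusters` data.frame and the
#'   `rel` object kept for reuse.
#' @export
reconstruct_pedigree <- function(gt, error_rate = 0.001, fs_threshold = 0,
                                 hs_threshold = 10, min_loci = 50,
                                 run_length = c("medium", "long"),
                                 bootstrap_B = 0, seed = 1L) {
  run_length <- match.arg(run_length)
  passes <- if (run_length == "medium") 2 else 6
  rel <- pairwise_llr(gt, error_rate = error_rate, min_loci = min_loci)
  fams <- partition_fullsib(rel, threshold = fs_threshold,
                            max_passes = passes)
  ped <- link_halfsibs(rel, fams, threshold = hs_threshold)
  ped$clusters <- family_clusters(
    ped, rel = if (bootstrap_B > 0) rel else NULL,
    B = max(bootstrap_B, 1), seed = seed,
    fs_threshold = fs_threshold, hs_threshold = hs_threshold
  )
  ped$rel <- rel
  ped
}
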