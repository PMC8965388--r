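mk_assign <- function(labels, clusters, lengths = NULL) {
  data.frame(id = sprintf("o%03d", seq_along(labels)),
             mixture_label = labels, cluster_id = clusters,
             length_mm = if (is.null(lengths)) rep(NA_real_, length(labels))
                         else lengths)
}

test_that("the cluster-by-cohort crosstab flags spanning clusters", {
  a <- mk_assign(c(1, 1, 1, 2, 2, 1, 2), c("A", "A", "A", "B", "B", "C", "C"),
                 lengths = c(40, 42, 41, 80, 82, 55, 70))
  ct <- crosstab_clusters_cohorts(a)
  expect_equal(sum(ct$table["A", ] > 0), 1)      # wholly in one cohort
  expect_true(ct$cluster_summary$spanning[ct$cluster_summary$cluster_id == "C"])
  expect_false(ct$cluster_summary$spanning[ct$cluster_summary$cluster_id == "A"])
  expect_equal(ct$cluster_summary$median_length[
    ct$cluster_summary$cluster_id == "A"], 41)

  empty <- crosstab_clusters_cohorts(mk_assign(integer(0), character(0)))
  expect_equal(nrow(empty$cluster_summary), 0)
})

test_that("genuinely spanning clusters merge cohorts, strays are corrected", {
  # cluster X spans cohorts 1 and 2 with 4 members each -> merge; cluster Z
  # sits in cohort 3 alone -> stays separate
  a <- mk_assign(c(rep(1, 6), rep(2, 6), rep(3, 5)),
                 c(rep("X", 4), "Y", "Y", rep("X", 4), "W", "W", rep("Z", 5)))
  r <- reconcile_cohorts(a)
  expect_equal(length(unique(r$final_cohort)), 2)
  expect_equal(length(unique(r$final_cohort[a$mixture_label %in% 1:2])), 1)
  expect_false(any(r$final_cohort[a$mixture_label == 3] %in%
                     r$final_cohort[a$mixture_label == 1]))

  # a single stray is reassigned to its cluster's cohort, without merging
  a2 <- mk_assign(c(rep(1, 9), 2, rep(2, 8)),
                  c(rep("X", 10), rep("Y", 8)))
  r2 <- reconcile_cohorts(a2)
  expect_equal(length(unique(r2$final_cohort)), 2)
  expect_equal(r2$final_cohort[10], r2$final_cohort[1])  # stray follows X

  # no spanning clusters: identity up to relabeling
  a3 <- mk_assign(c(1, 1, 2, 2), c("X", "X", "Y", "Y"))
  r3 <- reconcile_cohorts(a3)
  expect_equal(length(unique(r3$final_cohort)), 2)
})

test_that("merging is transitive and idempotent", {
  # chain: cluster X spans cohorts 1-2, cluster Y spans 2-3 -> all merged
  a <- mk_assign(c(rep(1, 4), rep(2, 8), rep(3, 4)),
                 c(rep("X", 8), rep("Y", 8)))
  r <- reconcile_cohorts(a)
  expect_equal(length(unique(r$final_cohort)), 1)
  # brute-force oracle: connected components of the label graph whose edges
  # are label pairs sharing a cluster (each side of the split is large
  # enough here that every shared cluster counts as genuinely spanning)
  edges <- do.call(rbind, lapply(split(a$mixture_label, a$cluster_id),
                                 function(l) t(utils::combn(unique(l), 2))))
  gr <- igraph::graph_from_data_frame(as.data.frame(edges),
                                      directed = FALSE,
                                      vertices = data.frame(name = 1:3))
  expect_equal(igraph::components(gr)$no,
               length(unique(r$final_cohort)))

  r2 <- reconcile_cohorts(transform(r, mixture_label = final_cohort))
  expect_equal(r2$final_cohort, r$final_cohort)  # idempotent

  # invariant: every cluster wholly inside one final cohort
  set.seed(41)
  for (s in 1:5) {
    labels <- sample(1:3, 40, replace = TRUE)
    clusters <- sample(LETTERS[1:8], 40, replace = TRUE)
    rr <- reconcile_cohorts(mk_assign(labels, clusters))
    per_cluster <- tapply(rr$final_cohort, rr$cluster_id,
                          function(x) length(unique(x)))
    expect_true(all(per_cluster == 1))
  }
})

test_that("cohorts link across collections through shared families", {
  # family X spans both collections' first cohorts; the second cohort of
  # each collection (clusters V, W) has no cross-collection relatives
  a <- rbind(
    data.frame(id = paste0("a", 1:8), collection_year = 2017,
               mixture_label = c(rep(1, 4), rep(2, 4)),
               cluster_id = c(rep("X", 4), rep("V", 4)),
               length_mm = rnorm(8, 75, 3)),
    data.frame(id = paste0("b", 1:8), collection_year = 2018,
               mixture_label = c(rep(1, 4), rep(2, 4)),
               cluster_id = c(rep("X", 4), rep("W", 4)),
               length_mm = rnorm(8, 90, 3))
  )
  lk <- link_across_collections(a)
  linked <- lk$assignments
  expect_equal(length(unique(linked$final_cohort[linked$cluster_id == "X"])), 1)
  # growth proxy: median length shift of the unified cohort is positive
  un <- unique(linked$final_cohort[linked$cluster_id == "X"])
  gr <- lk$growth[lk$growth$final_cohort == un, ]
  expect_gt(diff(gr$median_length[order(gr$collection_year)]), 0)
  # cohorts without cross-collection relatives stay collection-local
  expect_false(unique(linked$final_cohort[linked$cluster_id == "V"]) ==
                 unique(linked$final_cohort[linked$cluster_id == "W"]))

  # a single collection passes through unchanged
  single <- a[a$collection_year == 2017, ]
  lk1 <- link_across_collections(single)
  expect_equal(length(unique(lk1$assignments$final_cohort)),
               length(unique(reconcile_cohorts(single)$final_cohort)))
})

test_that("spawn-year labeling respects length bands and treatment events", {
  bands <- list(age1 = c(30, 55), age2 = c(60, 90))
  events <- list(list(type = "treatment", year = 2015),
                 list(type = "barrier", year = 2016))
  cs <- data.frame(final_cohort = c("C1", "C2"),
                   collection_year = c(2017, 2017),
                   median_length = c(75, 45))
  sy <- assign_spawn_years(cs, bands, events)
  expect_equal(sy$spawn_year[sy$final_cohort == "C1"], 2015)
  expect_equal(sy$spawn_year[sy$final_cohort == "C2"], 2016)
  expect_true(all(sy$status == "assigned"))

  # overlapping bands and no constraints: ambiguous, candidates listed
  bands2 <- list(age1 = c(30, 80), age2 = c(60, 90))
  sy2 <- assign_spawn_years(cs[1, ], bands2, list())
  expect_equal(sy2$status, "ambiguous")
  expect_equal(sy2$candidates, "2015,2016")

  # no feasible year
  sy3 <- assign_spawn_years(data.frame(final_cohort = "C9",
                                       collection_year = 2017,
                                       median_length = 200),
                            bands, events)
  expect_equal(sy3$status, "infeasible")
})
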