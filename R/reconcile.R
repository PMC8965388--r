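# Pedigree-guided reconciliation of length-based cohort assignments.
#
# For a semelparous species, full- and half-sib relationships cannot span
# spawning years, so every family cluster must sit inside one cohort.
# Clusters genuinely split across mixture cohorts trigger a cohort merge
# (the mixture oversplit one true cohort); occasional stray members are
# reassigned to their cluster's majority cohort.

#' Cross-tabulate family clusters against mixture cohorts
#'
#' @param assignments data.frame with columns `id`, `mixture_label`,
#'   `cluster_id`, and optionally `length_mm`.
#' @return List: `table` (cluster x mixture-cohort contingency matrix),
#'   `cluster_summary` (per-cluster n, median and IQR of length when
#'   available, and a `spanning` flag for clusters present in two or more
#'   mixture cohorts).
#' @export
crosstab_clusters_cohorts <- function(assignments) {
  a <- assignments[!is.na(assignments$cluster_id), , drop = FALSE]
  if (nrow(a) == 0) {
    return(list(table = table(character(0), character(0)),
                cluster_summary = data.frame(cluster_id = character(0),
                                             n = integer(0),
                                             spanning = logical(0))))
  }
  tab <- table(cluster = a$cluster_id, cohort = a$mixture_label)
  spanning <- rowSums(tab > 0) >= 2
  cs <- data.frame(
    cluster_id = rownames(tab),
    n = as.integer(rowSums(tab)),
    spanning = as.logical(spanning)
  )
  if (!is.null(a$length_mm)) {
    med <- tapply(a$length_mm, a$cluster_id, stats::median)
    iqr <- tapply(a$length_mm, a$cluster_id, stats::IQR)
    cs$median_length <- as.numeric(med[cs$cluster_id])
    cs$iqr_length <- as.numeric(iqr[cs$cluster_id])
  }
  list(table = tab, cluster_summary = cs)
}

#' Merge mixture cohorts connected through family clusters
#'
#' Because siblings cannot span spawning years, a family cluster with
#' members in two mixture cohorts signals a cohort-assignment problem. Two
#' situations are distinguished:
#' \itemize{
#'   \item \emph{Genuinely spanning cluster} - the minority side of the
#'     split has at least `span_min_count` members and at least
#'     `span_min_frac` of the cluster: the mixture has oversplit one true
#'     cohort, and the affected mixture cohorts are merged (union-find, so
#'     merging is transitive across chains of spanning clusters).
#'   \item \emph{Stray members} - a smaller minority is indistinguishable
#'     from individual misassignment in the length-overlap zone: the strays
#'     are reassigned to their cluster's majority cohort instead of
#'     triggering a merge.
#' }
#' After reconciliation every family cluster sits wholly inside one final
#' cohort, and the operation is idempotent. Individuals without a cluster
#' keep the cohort of their mixture label.
#'
#' @param assignments data.frame with `id`, `mixture_label`, `cluster_id`.
#' @param span_min_count,span_min_frac minimum minority-side size (4) and
#'   fraction (0.25) for a split cluster to count as genuinely spanning.
#' @return The input with a `final_cohort` column added (labels
#'   `"C1", "C2", ...` ordered by the smallest mixture label they contain).
#' @export
reconcile_cohorts <- function(assignments, span_min_count = 4,
                              span_min_frac = 0.25) {
  labs <- sort(unique(assignments$mixture_label))
  parent <- seq_along(labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  cl <- assignments$cluster_id
  cluster_rows <- split(which(!is.na(cl)), cl[!is.na(cl)])
  for (rows in cluster_rows) {
    counts <- table(assignments$mixture_label[rows])
    if (length(counts) < 2) next
    minority <- sum(counts) - max(counts)
    if (minority >= span_min_count &&
        minority / sum(counts) >= span_min_frac) {
      ks <- match(names(counts)[counts >= min(span_min_count, max(counts))],
                  labs)
      if (length(ks) > 1) for (k in ks[-1]) union2(ks[1], k)
    }
  }
  roots <- vapply(seq_along(labs), find, integer(1))
  final_of_label <- setNames(paste0("C", match(roots, sort(unique(roots)))),
                             labs)
  assignments$final_cohort <-
    unname(final_of_label[as.character(assignments$mixture_label)])
  # every cluster collapses onto its (merged) majority cohort; this corrects
  # stray members without splitting any mixture cohort that survived merging
  for (rows in cluster_rows) {
    fc <- assignments$final_cohort[rows]
    tab <- sort(table(fc), decreasing = TRUE)
    assignments$final_cohort[rows] <- names(tab)[1]
  }
  assignments
}

#' Link cohorts across collections through a shared pedigree
#'
#' When the same stream is sampled in several years and the pedigree spans
#' collections, cohorts from different collections are merged whenever a
#' family cluster has members in both; unified cohorts get shared labels
#' and a per-cohort median length shift between collections is reported as
#' a growth proxy. Cohorts with no cross-collection relatives stay
#' collection-local.
#'
#' @param assignments data.frame with `id`, `collection_year`,
#'   `mixture_label`, `cluster_id`, optionally `length_mm`; the
#'   `final_cohort` column from [reconcile_cohorts()] is recomputed here on
#'   collection-qualified labels, so assignments from separate
#'   per-collection mixture runs can share label values safely.
#' @return List: `assignments` (with `final_cohort` spanning collections)
#'   and `growth` (per unified cohort and collection year, n and median
#'   length).
#' @export
link_across_collections <- function(assignments) {
  a <- assignments
  a$mixture_label <- paste(a$collection_year, a$mixture_label, sep = ":")
  a <- reconcile_cohorts(a)
  assignments$final_cohort <- a$final_cohort
  growth <- NULL
  if (!is.null(assignments$length_mm)) {
    growth <- stats::aggregate(
      length_mm ~ final_cohort + collection_year, data = assignments,
      FUN = stats::median
    )
    names(growth)[names(growth) == "length_mm"] <- "median_length"
    nn <- stats::aggregate(length_mm ~ final_cohort + collection_year,
                           data = assignments, FUN = length)
    growth$n <- nn$length_mm
    growth <- growth[order(growth$final_cohort, growth$collection_year), ]
  }
  list(assignments = assignments, growth = growth)
}

#' Assign spawn years to final cohorts
#'
#' Maps each final cohort to the feasible spawn years consistent with
#' (a) user-supplied length-at-age bands (external benchmarks; the package
#' ships none) and (b) constraint events: a lampricide `treatment` in year
#' `y` removes all earlier spawn years from consideration (larvae spawned
#' before the treatment did not survive it), while a `barrier` event is
#' recorded as context but imposes no hard constraint.
#'
#' @param cohort_summary data.frame with `final_cohort`, `collection_year`,
#'   `median_length` (e.g. built from [link_across_collections()] growth
#'   output, using the latest collection of each cohort).
#' @param bands named list: `bands$age2 = c(60, 90)` means a cohort whose
#'   median length falls in [60, 90] mm is compatible with age 2 at
#'   collection.
#' @param events list of `list(type =, year =)` entries.
#' @return data.frame `final_cohort`, `spawn_year` (NA when not unique),
#'   `status` (`"assigned"`, `"ambiguous"`, `"infeasible"`), `candidates`
#'   (comma-separated feasible years).
#' @export
assign_spawn_years <- function(cohort_summary, bands, events = list()) {
  treat_years <- vapply(
    Filter(function(e) identical(e$type, "treatment"), events),
    function(e) as.numeric(e$year), numeric(1)
  )
  min_spawn <- if (length(treat_years)) max(treat_years) else -Inf
  ages <- as.integer(sub("^age", "", names(bands)))
  out <- lapply(seq_len(nrow(cohort_summary)), function(i) {
    med <- cohort_summary$median_length[i]
    cy <- cohort_summary$collection_year[i]
    ok_age <- ages[vapply(bands, function(b) med >= b[1] & med <= b[2],
                          logical(1))]
    cand <- sort(unique(cy - ok_age))
    cand <- cand[cand >= min_spawn]
    if (length(cand) == 1) {
      data.frame(final_cohort = cohort_summary$final_cohort[i],
                 spawn_year = cand, status = "assigned",
                 candidates = as.character(cand))
    } else if (length(cand) > 1) {
      data.frame(final_cohort = cohort_summary$final_cohort[i],
                 spawn_year = NA_real_, status = "ambiguous",
                 candidates = paste(cand, collapse = ","))
    } else {
      data.frame(final_cohort = cohort_summary$final_cohort[i],
                 spawn_year = NA_real_, status = "infeasible",
                 candidates = "")
    }
  })
  do.call(rbind, out)
}
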