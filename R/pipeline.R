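# Pipeline driver: QC -> pedigree (per stream, collections pooled) ->
# length mixtures (per stream x collection) -> pedigree-guided cohort
# reconciliation -> per-cohort effective-size estimation.

#' Run the full larval-cohort assessment pipeline
#'
#' Mirrors the per-stream workflow of a field assessment: genotype QC and
#' panel selection, sibship/pedigree reconstruction with the stream's
#' collections pooled, Gaussian mixture cohort inference separately per
#' stream and collection year (skipped below `min_n_mixture` individuals,
#' which then form a single cohort), reconciliation of mixture cohorts
#' against family clusters within and across collections, and per-cohort
#' estimates: `N_s`, k-bar, `V_k`, `N_b` (SF and LD), parentage
#' accumulation, and Chao2/jackknife extrapolated spawner richness.
#'
#' @param config a [read_run_config()] list (or path): must provide
#'   `paths$vcf`, `paths$individuals`, `paths$out`.
#' @return Invisibly, a list with all stage outputs; files are written
#'   under `paths$out`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  stopifnot(!is.null(cfg$paths$vcf), !is.null(cfg$paths$individuals),
            !is.null(cfg$paths$out))
  out_dir <- cfg$paths$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  gt <- read_genotypes_vcf(cfg$paths$vcf)
  ind <- read_individual_table(cfg$paths$individuals,
                               vcf_ids = rownames(gt$geno))

  qc <- apply_qc_filters(gt, cfg$qc)
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stats <- compute_locus_stats(qc$gt)
  utils::write.table(stats, file.path(out_dir, "locus_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  panel_ped <- select_snp_panels(stats, "pedigree",
                                 seed = derive_seed(cfg$seed, "panels"),
                                 maf_min = cfg$qc$maf_min,
                                 call_rate_min = cfg$qc$call_rate_min,
                                 min_sep_bp = cfg$qc$min_sep_bp)
  panel_ld <- select_snp_panels(stats, "ld",
                                seed = derive_seed(cfg$seed, "panels") + 1L,
                                maf_min = cfg$qc$maf_min)

  ind <- ind[ind$id %in% rownames(qc$gt$geno), , drop = FALSE]
  streams <- sort(unique(ind$stream))
  all_assign <- list(); all_tab1 <- list(); all_tab2 <- list()
  all_acc <- list(); peds <- list()

  for (st in streams) {
    sub <- ind[ind$stream == st, , drop = FALSE]
    ids <- unique(sub$id)
    gts <- qc$gt[ids, if (length(panel_ped)) panel_ped else TRUE]
    ped <- reconstruct_pedigree(
      gts, error_rate = cfg$sibship$error_rate,
      fs_threshold = cfg$sibship$fs_threshold,
      hs_threshold = cfg$sibship$hs_threshold,
      min_loci = cfg$sibship$min_loci,
      run_length = cfg$sibship$run_length,
      bootstrap_B = 0, seed = derive_seed(cfg$seed, "sibship")
    )
    peds[[st]] <- ped
    utils::write.table(ped$pedigree,
                       file.path(out_dir, paste0("pedigree_", st, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ped$clusters,
                       file.path(out_dir, paste0("clusters_", st, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # merge trigger for reconciliation: family clusters (default) or
    # full-sib families only (the sensitivity mode; the source analysis
    # reports both give the same result)
    cl_of <- if (identical(cfg$reconcile$relatedness, "fullsib")) {
      setNames(paste0("FS", rep(seq_along(ped$families),
                                lengths(ped$families))),
               unlist(ped$families))
    } else {
      setNames(ped$clusters$cluster_id, ped$clusters$offspring_id)
    }

    # mixtures per collection year
    assign_st <- list()
    for (cy in sort(unique(sub$collection_year))) {
      cc <- sub[sub$collection_year == cy, , drop = FALSE]
      mcmc <- list(iter = cfg$mixture$iter, burn = cfg$mixture$burn,
                   thin = cfg$mixture$thin)
      if (nrow(cc) < cfg$min_n_mixture) {
        message("stream ", st, " collection ", cy, ": n = ", nrow(cc),
                " below the mixture minimum; treated as a single cohort")
        labels <- rep(1L, nrow(cc))
        sel <- NULL
      } else {
        sd0 <- derive_seed(cfg$seed, "mixture") + cy
        kp1 <- posterior_k_overfitted(cc$length_mm, k_max = cfg$mixture$k_max,
                                      cutoff = cfg$mixture$cutoff,
                                      mcmc = mcmc, seed = sd0)
        kp2 <- posterior_k_bdmcmc(cc$length_mm, k_max = cfg$mixture$k_max,
                                  birth_rate = cfg$mixture$birth_rate,
                                  mcmc = mcmc, seed = sd0 + 1L)
        sel <- select_k_and_assign(cc$length_mm, kp1, kp2, mcmc = mcmc,
                                   seed = sd0 + 2L)
        labels <- sel$labels
        all_tab1[[paste(st, cy)]] <- data.frame(
          stream = st, collection_year = cy,
          K = seq_along(kp1$prob),
          overfitted = as.numeric(kp1$prob),
          bd_mcmc = as.numeric(kp2$prob),
          chosen = seq_along(kp1$prob) == sel$K
        )
      }
      assign_st[[as.character(cy)]] <- data.frame(
        id = cc$id, stream = st, collection_year = cy,
        length_mm = cc$length_mm, mixture_label = labels,
        cluster_id = unname(cl_of[cc$id])
      )
    }
    a <- do.call(rbind, assign_st)
    # reconcile within collections, then across
    lk <- link_across_collections(a)
    a <- lk$assignments
    all_assign[[st]] <- a

    # spawn-year labels when benchmarks are configured
    spawn <- NULL
    if (!is.null(cfg$reconcile$bands) && length(cfg$reconcile$bands)) {
      growth <- lk$growth
      last <- growth[!duplicated(growth$final_cohort, fromLast = TRUE), ]
      spawn <- assign_spawn_years(
        data.frame(final_cohort = last$final_cohort,
                   collection_year = last$collection_year,
                   median_length = last$median_length),
        bands = cfg$reconcile$bands, events = cfg$reconcile$events
      )
      a$spawn_year <- spawn$spawn_year[match(a$final_cohort,
                                             spawn$final_cohort)]
      all_assign[[st]] <- a
    }

    # per-cohort estimators
    for (coh in sort(unique(a$final_cohort))) {
      members <- a$id[a$final_cohort == coh]
      rs <- repro_summary(ped, members)
      sf <- nb_sibship(rs, ped = ped, members = members,
                       B = cfg$effsize$sf_bootstrap_B,
                       seed = derive_seed(cfg$seed, "effsize"))
      ld <- tryCatch(
        nb_ld(qc$gt[intersect(members, rownames(qc$gt$geno)),
                    if (length(panel_ld)) panel_ld else TRUE],
              pcrit = cfg$effsize$pcrit),
        error = function(e) NULL
      )
      rich <- richness_estimates(ped, members)
      acc <- parent_accumulation(ped, members,
                                 n_perm = cfg$effsize$n_perm,
                                 seed = derive_seed(cfg$seed, "effsize") + 1L)
      acc$stream <- st; acc$cohort <- coh
      all_acc[[paste(st, coh)]] <- acc
      all_tab2[[paste(st, coh)]] <- data.frame(
        stream = st, cohort = coh, n = rs$n,
        kbar = round(rs$kbar, 2), vk = round(rs$vk, 2),
        nb_ld = if (is.null(ld)) NA else round(ld$point),
        nb_ld_lo = if (is.null(ld)) NA else round(ld$ci[1]),
        nb_ld_hi = if (is.null(ld)) NA else round(ld$ci[2]),
        nb_sf = round(sf$point), nb_sf_lo = round(sf$ci[1]),
        nb_sf_hi = round(sf$ci[2]),
        N_s = rs$N_s,
        ns_chao = round(rich$est[1], 1), ns_chao_se = round(rich$se[1], 1),
        ns_jack = round(rich$est[2], 1), ns_jack_se = round(rich$se[2], 1)
      )
    }
  }

  assignments <- do.call(rbind, all_assign)
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tab1 <- if (length(all_tab1)) do.call(rbind, all_tab1) else NULL
  if (!is.null(tab1)) {
    utils::write.table(tab1, file.path(out_dir, "k_selection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tab2 <- do.call(rbind, all_tab2)
  utils::write.table(tab2, file.path(out_dir, "cohort_estimates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  acc <- do.call(rbind, all_acc)
  utils::write.table(acc, file.path(out_dir, "accumulation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "lampreyNb",
    version = as.character(utils::packageVersion("lampreyNb")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "paths")],
    inputs = list(
      vcf = unname(tools::md5sum(cfg$paths$vcf)),
      individuals = unname(tools::md5sum(cfg$paths$individuals))
    ),
    panels = list(pedigree = panel_ped, ld = panel_ld)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(qc = qc, stats = stats, panels = manifest$panels,
                 pedigrees = peds, assignments = assignments,
                 k_selection = tab1, cohort_estimates = tab2,
                 accumulation = acc))
}

# --- minimal command-line front end -----------------------------------------

cli_opts <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      out[[key]] <- if (i < length(args) && !grepl("^--", args[i + 1])) {
        i <- i + 1; args[i]
      } else TRUE
    }
    i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture set from a simulation config),
#' `qc`, `sibship`, `cohorts`, `reconcile`, `estimate` (stage-by-stage, each
#' reading the previous stage's files), and `run` (the full pipeline).
#' Typical use from a shell:
#' \preformatted{Rscript -e 'lampreyNb::lamprey_cli()' run --config cfg.yaml --out out/}
#'
#' @param args character vector (default: `commandArgs(trailingOnly=TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
lamprey_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: lamprey_cli <simulate|qc|sibship|cohorts|reconcile|estimate|run> [--config F] [--vcf F] [--csv F] [--seed N] [--out D]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- cli_opts(args[-1])
  seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
  out <- if (is.null(opt$out)) "." else opt$out

  if (cmd == "simulate") {
    sim <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
    sim$seed <- seed
    cfgs <- do.call(sim_config, sim)
    tr <- simulate_truth(cfgs)
    gt <- simulate_genotypes(tr)
    len <- simulate_lengths(tr)
    files <- write_fixtures(tr, gt, len, out)
    return(invisible(files))
  }
  if (cmd == "run") {
    cfg <- read_run_config(opt$config)
    if (!is.null(opt$out)) cfg$paths$out <- opt$out
    cfg$seed <- seed
    return(invisible(run_pipeline(cfg)))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else
    read_run_config(list(seed = seed))
  if (cmd == "qc") {
    gt <- read_genotypes_vcf(opt$vcf)
    qc <- apply_qc_filters(gt, cfg$qc)
    utils::write.table(qc$report, file.path(out, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(compute_locus_stats(qc$gt),
                       file.path(out, "locus_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(qc))
  }
  if (cmd == "sibship") {
    gt <- read_genotypes_vcf(opt$vcf)
    qc <- apply_qc_filters(gt, cfg$qc)
    ped <- reconstruct_pedigree(qc$gt, error_rate = cfg$sibship$error_rate,
                                fs_threshold = cfg$sibship$fs_threshold,
                                hs_threshold = cfg$sibship$hs_threshold,
                                min_loci = cfg$sibship$min_loci,
                                bootstrap_B = cfg$sibship$bootstrap_B,
                                seed = seed)
    utils::write.table(ped$pedigree, file.path(out, "pedigree.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ped$clusters, file.path(out, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(ped))
  }
  if (cmd == "cohorts") {
    ind <- read_individual_table(opt$csv)
    mcmc <- list(iter = cfg$mixture$iter, burn = cfg$mixture$burn,
                 thin = cfg$mixture$thin)
    res <- lapply(split(ind, paste(ind$stream, ind$collection_year)),
                  function(cc) {
                    kp1 <- posterior_k_overfitted(cc$length_mm,
                                                  k_max = cfg$mixture$k_max,
                                                  cutoff = cfg$mixture$cutoff,
                                                  mcmc = mcmc, seed = seed)
                    kp2 <- posterior_k_bdmcmc(cc$length_mm,
                                              k_max = cfg$mixture$k_max,
                                              mcmc = mcmc, seed = seed + 1L)
                    sel <- select_k_and_assign(cc$length_mm, kp1, kp2,
                                               mcmc = mcmc, seed = seed + 2L)
                    data.frame(id = cc$id, stream = cc$stream,
                               collection_year = cc$collection_year,
                               mixture_label = sel$labels)
                  })
    res <- do.call(rbind, res)
    utils::write.table(res, file.path(out, "mixture_labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(res))
  }
  if (cmd == "reconcile") {
    a <- utils::read.delim(opt$csv)  # assignments with cluster_id
    lk <- link_across_collections(a)
    utils::write.table(lk$assignments, file.path(out, "assignments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(lk))
  }
  if (cmd == "estimate") {
    a <- utils::read.delim(opt$csv)
    ped <- utils::read.delim(opt$pedigree)
    rows <- lapply(sort(unique(a$final_cohort)), function(coh) {
      members <- a$id[a$final_cohort == coh]
      rs <- repro_summary(ped, members)
      sf <- nb_sibship(rs, ped = ped, members = members,
                       B = cfg$effsize$sf_bootstrap_B, seed = seed)
      rich <- richness_estimates(ped, members)
      data.frame(cohort = coh, n = rs$n, N_s = rs$N_s,
                 kbar = round(rs$kbar, 2), vk = round(rs$vk, 2),
                 nb_sf = round(sf$point),
                 ns_chao = round(rich$est[1], 1),
                 ns_jack = round(rich$est[2], 1))
    })
    res <- do.call(rbind, rows)
    utils::write.table(res, file.path(out, "cohort_estimates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(res))
  }
  stop("unknown subcommand: ", cmd)
}
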