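#' Pipeline configuration
#'
#' Bundles every stage's parameters with one master seed.  Per-stage seeds
#' are derived from the master seed by a fixed counter scheme, so any stage
#' can be reproduced independently and a re-run with the same configuration
#' produces byte-identical outputs.
#'
#' @param seed Master seed.
#' @param model A [pop_model()]; its seed is overridden from `seed`.
#' @param qc A [qc_thresholds()].
#' @param hmm An [hmm_config()].
#' @param n_sib_pairs Extra full-sib drone pairs appended to the Algerian
#'   training set so the family filter has work to do.
#' @param family_threshold,close_kin_cutoff Kinship cuts (defaults 0.30 and
#'   0.10).
#' @param prune_window,prune_overlap,prune_r2,prune_maf LD-pruning stage.
#' @param aim_r2 Strengthened LD threshold for the AIM candidate pool.
#' @param aim_runs,aim_trees,aim_top_k AIM ranking stage.
#' @param null_panels,null_runs Random-panel null (reduced by default; the
#'   full null is 1000 panels x 50 runs).
#' @param classify_runs Repeats for the selected-panel classification.
#' @param matings_per_cross,hybrid_runs Hybrid stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            model = pop_model(),
                            qc = qc_thresholds(),
                            hmm = hmm_config(),
                            n_sib_pairs = 2,
                            family_threshold = 0.30,
                            close_kin_cutoff = 0.10,
                            prune_window = 1749, prune_overlap = 0.10,
                            prune_r2 = 0.30, prune_maf = 0.01,
                            aim_r2 = 0.13,
                            aim_runs = 100, aim_trees = 100, aim_top_k = 48,
                            null_panels = 50, null_runs = 5,
                            classify_runs = 50,
                            matings_per_cross = 40, hybrid_runs = 10) {
  model$seed <- derive_seed(seed, 101L)
  hmm$seed <- derive_seed(seed, 102L)
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(tbl, out_dir, name, manifest, stage) {
  path <- file.path(out_dir, name)
  readr::write_tsv(tbl, path, progress = FALSE)
  bind_rows(manifest, tibble(stage = stage, file = name,
                             md5 = unname(tools::md5sum(path))))
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> site/sample QC -> LD pruning -> kinship and family filter ->
#' PCA, two-cluster assignment and genetic-geographic correlations -> AIM
#' candidates -> four-configuration panel selection -> random-panel null ->
#' hybrid cohorts and classification experiments.  Every stage writes its
#' table(s) under `out_dir`; a manifest of md5 checksums is written last,
#' so two runs with the same configuration can be compared byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with each stage's in-memory results and the manifest
#'   tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble(stage = character(), file = character(),
                     md5 = character())
  recmap <- recomb_map(config$model$chrom_lengths, config$hmm$rec_rate)

  # -- simulate -------------------------------------------------------------
  ds <- generate_dataset(config$model)
  gm <- ds$gm
  if (config$n_sib_pairs > 0) {
    p_alg <- ds$truth$freqs[, "ALG"]
    sib_calls <- NULL; sib_meta <- list()
    for (s in seq_len(config$n_sib_pairs)) {
      fam <- queen_family(p_alg, gm$variants, recmap, n_drones = 2,
                          seed = derive_seed(config$seed, 400L + s))
      sib_calls <- rbind(sib_calls, fam$drones)
      sib_meta[[s]] <- tibble(
        id = sprintf("ALG_sib%02d_%s", s, c("a", "b")),
        group = "ALG", split = "train", subspecies = "intermissa",
        latitude = mean(config$model$lat_range),
        longitude = mean(config$model$lon_range), altitude = 800
      )
    }
    sib_gm <- genotype_matrix(sib_calls, gm$variants, bind_rows(sib_meta))
    sib_gm$samples$call_rate <- 1
    gm <- bind_sample_sets(gm, sib_gm)
  }
  manifest <- write_stage(gm$samples, out_dir, "samples.tsv", manifest,
                          "simulate")
  manifest <- write_stage(gm$variants, out_dir, "variants.tsv", manifest,
                          "simulate")

  # -- qc --------------------------------------------------------------------
  sq <- site_qc(gm, config$qc)
  gm <- sample_qc(sq$gm)
  manifest <- write_stage(sq$report, out_dir, "site_qc_report.tsv",
                          manifest, "qc")

  # -- prune ----------------------------------------------------------------
  pruned_ids <- ld_prune(gm, window_n = config$prune_window,
                         overlap_frac = config$prune_overlap,
                         r2_max = config$prune_r2,
                         maf_min = config$prune_maf)
  pruned <- gm[, pruned_ids]
  manifest <- write_stage(tibble(id = pruned_ids), out_dir,
                          "pruned_snps.tsv", manifest, "prune")

  # -- kinship / family filter (Algerian samples) ---------------------------
  alg_ix <- which(pruned$samples$group == "ALG")
  K <- kinship_matrix(pruned[alg_ix, ], config$hmm)
  fam <- family_components(K, threshold = config$family_threshold,
                           call_rates = call_rates(pruned[alg_ix, ]))
  keep_ids <- c(fam$retained_ids,
                pruned$samples$id[pruned$samples$group != "ALG"])
  filtered <- pruned[match(keep_ids, pruned$samples$id), ]
  manifest <- write_stage(K$pairs, out_dir, "kinship_pairs.tsv",
                          manifest, "kinship")
  manifest <- write_stage(fam$families, out_dir, "families.tsv",
                          manifest, "kinship")

  # -- structure & correlations (Algerian samples) --------------------------
  alg_gm <- filtered[which(filtered$samples$group == "ALG"), ]
  pca_alg <- pca_genotypes(alg_gm, n_pc = min(7, n_samples(alg_gm) - 1))
  clusters <- cluster2(pca_alg, alg_gm$samples,
                       seed = derive_seed(config$seed, 103L))
  tab1 <- corr_pc_coords(pca_alg, alg_gm$samples, n_pc = 7)
  gen_d <- pc_distance(pca_alg)
  geo_d <- geo_distance(alg_gm$samples)
  Ka <- kinship_matrix(alg_gm, config$hmm)
  tab2 <- bind_rows(
    mutate(corr_dist(gen_d, geo_d, clusters), measure = "pc_distance"),
    mutate(corr_dist(Ka, geo_d, clusters), measure = "kinship")
  )
  ck <- close_kin(Ka, cutoff = config$close_kin_cutoff,
                  meta = mutate(alg_gm$samples,
                                cluster = unname(clusters[.data$id])))
  manifest <- write_stage(tidy(pca_alg), out_dir, "pca_scores.tsv",
                          manifest, "structure")
  manifest <- write_stage(tab1, out_dir, "corr_pc_coords.tsv",
                          manifest, "structure")
  manifest <- write_stage(tab2, out_dir, "corr_distances.tsv",
                          manifest, "structure")
  manifest <- write_stage(ck$pairs, out_dir, "close_kin.tsv",
                          manifest, "structure")

  # -- AIM selection --------------------------------------------------------
  originals <- filtered[which(filtered$samples$group %in% c("ALG", "M", "C")), ]
  train_gm <- originals[which(originals$samples$split == "train"), ]
  test_gm <- originals[which(originals$samples$split == "test"), ]
  cand <- candidate_snps(originals, r2_max = config$aim_r2,
                         window_n = config$prune_window,
                         overlap_frac = config$prune_overlap,
                         maf_min = config$prune_maf)
  aim <- select_aim_panels(train_gm, test_gm, cand,
                           n_runs = config$aim_runs,
                           top_k = config$aim_top_k,
                           n_trees = config$aim_trees,
                           seed = derive_seed(config$seed, 104L))
  manifest <- write_stage(aim$validation, out_dir, "panel_validation.tsv",
                          manifest, "aim")
  manifest <- write_stage(tidy(aim$best), out_dir, "best_panel.tsv",
                          manifest, "aim")

  # -- selected-panel classification and random-panel null ------------------
  sel_cl <- classify_samples(train_gm, test_gm, aim$best,
                             n_runs = config$classify_runs,
                             n_trees = config$aim_trees,
                             seed = derive_seed(config$seed, 105L))
  null <- random_panel_null(train_gm, test_gm, cand, selected = sel_cl,
                            n_panels = config$null_panels,
                            n_runs = config$null_runs,
                            n_trees = config$aim_trees,
                            seed = derive_seed(config$seed, 106L))
  manifest <- write_stage(tidy(sel_cl), out_dir, "selected_panel_probs.tsv",
                          manifest, "null")
  manifest <- write_stage(null$null, out_dir, "random_panel_null.tsv",
                          manifest, "null")

  # -- hybrids --------------------------------------------------------------
  plan_tr <- cross_plan(config$matings_per_cross,
                        seed = derive_seed(config$seed, 107L))
  plan_te <- cross_plan(config$matings_per_cross,
                        seed = derive_seed(config$seed, 108L))
  alg_tr <- train_gm[which(train_gm$samples$group == "ALG"), cand]
  eur_tr <- train_gm[which(train_gm$samples$group != "ALG"), cand]
  alg_te <- test_gm[which(test_gm$samples$group == "ALG"), cand]
  eur_te <- test_gm[which(test_gm$samples$group != "ALG"), cand]
  coh_tr <- make_cohort(alg_tr, eur_tr, plan_tr, recmap, split = "train")
  coh_te <- make_cohort(alg_te, eur_te, plan_te, recmap, split = "test")
  hyb <- hybrid_experiment(train_gm[, cand], test_gm[, cand],
                           coh_tr, coh_te, aim$best, all_ids = cand,
                           n_runs = config$hybrid_runs,
                           n_trees = config$aim_trees,
                           seed = derive_seed(config$seed, 109L))
  manifest <- write_stage(coh_tr$labels, out_dir, "hybrids_train.tsv",
                          manifest, "hybrids")
  manifest <- write_stage(coh_te$labels, out_dir, "hybrids_test.tsv",
                          manifest, "hybrids")
  manifest <- write_stage(hyb$report, out_dir, "hybrid_report.tsv",
                          manifest, "hybrids")

  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  list(genotypes = filtered, kinship = K, families = fam,
       pca = pca_alg, clusters = clusters,
       corr_pc_coords = tab1, corr_distances = tab2, close_kin = ck,
       aim = aim, selected_classification = sel_cl, null = null,
       hybrids = hyb, manifest = manifest)
}
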