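#' Cross plan for hybrid simulation
#'
#' F1 and three successive backcrosses to the Algerian background, for each
#' European lineage, with a fixed number of random matings per cross drawn
#' among all possible unique parent combinations.
#'
#' @param matings_per_cross Offspring per cross type per lineage (default
#'   40, giving 4 x 2 x 40 = 320 hybrids per dataset split and 640 total
#'   over two splits).
#' @param crosses Cross types in pedigree order.
#' @param lineages European source lineages.
#' @param seed Integer seed.
#' @return List of class `cross_plan`.
#' @export
cross_plan <- function(matings_per_cross = 40,
                       crosses = c("F1", "BC1", "BC2", "BC3"),
                       lineages = c("M", "C"), seed = 1L) {
  structure(list(matings_per_cross = matings_per_cross, crosses = crosses,
                 lineages = lineages, seed = as.integer(seed)),
            class = "cross_plan")
}

# sample n unique (a, b) combinations without replacement
sample_combos <- function(n_a, n_b, n) {
  total <- as.double(n_a) * n_b
  if (total < n) abort("pool smaller than required unique combinations")
  pick <- sample.int(total, n)
  cbind(a = ((pick - 1) %% n_a) + 1, b = ((pick - 1) %/% n_a) + 1)
}

#' Simulate a hybrid cohort
#'
#' F1 hybrids pair one European drone haplotype with one Algerian drone
#' haplotype (drones are haploid, so their genomes are used directly as
#' gametes); each backcross BC(n+1) pairs a recombinant gamete of a BC(n)
#' (or F1) individual — produced by [meiosis()] — with a fresh random
#' Algerian haplotype.  Every genome carries per-site European-ancestry
#' labels through the meioses, so a BC(n) individual's expected European
#' ancestry is 2^-(n+1) by construction.
#'
#' @param alg_gm Haploid Algerian [genotype_matrix()] (one dataset split).
#' @param eur_gm Haploid European reference matrix with `group` labels
#'   matching `plan$lineages`.
#' @param plan A [cross_plan()].
#' @param recmap A [recomb_map()].
#' @param split Split tag recorded on the offspring (e.g. "train").
#' @return Object of class `hybrid_cohort`: haplotype and ancestry arrays,
#'   a `labels` tibble (id, cross, lineage, split, parents, true European
#'   ancestry fraction) and the variant table.
#' @export
make_cohort <- function(alg_gm, eur_gm, plan = cross_plan(), recmap,
                        split = "train") {
  set.seed(derive_seed(plan$seed, 41L))
  stopifnot(identical(alg_gm$variants$id, eur_gm$variants$id))
  v <- alg_gm$variants
  m <- nrow(v)
  alg_haps <- alg_gm$calls
  n_alg <- nrow(alg_haps)

  hap1 <- hap2 <- anc1 <- anc2 <- NULL
  labels <- list()
  for (lin in plan$lineages) {
    eur_ix <- which(eur_gm$samples$group == lin)
    if (length(eur_ix) == 0) abort(sprintf("no %s samples in eur_gm", lin))
    eur_haps <- eur_gm$calls[eur_ix, , drop = FALSE]
    prev_h1 <- prev_h2 <- prev_a1 <- prev_a2 <- NULL
    for (cx in plan$crosses) {
      nm <- plan$matings_per_cross
      if (cx == "F1") {
        combos <- sample_combos(nrow(eur_haps), n_alg, nm)
        h1 <- eur_haps[combos[, "a"], , drop = FALSE]
        a1 <- matrix(TRUE, nm, m)
        parent1 <- eur_gm$samples$id[eur_ix][combos[, "a"]]
      } else {
        combos <- sample_combos(nrow(prev_h1), n_alg, nm)
        h1 <- matrix(0L, nm, m); a1 <- matrix(FALSE, nm, m)
        parent1 <- character(nm)
        for (k in seq_len(nm)) {
          pk <- combos[k, "a"]
          g <- meiosis(prev_h1[pk, ], prev_h2[pk, ], v, recmap)
          h1[k, ] <- g$hap
          a1[k, ] <- ifelse(g$src == 1L, prev_a1[pk, ], prev_a2[pk, ])
          parent1[k] <- sprintf("%s%s_%s_%02d", prev_cx, lin, split, pk)
        }
      }
      h2 <- alg_haps[combos[, "b"], , drop = FALSE]
      a2 <- matrix(FALSE, nm, m)
      ids <- sprintf("%s%s_%s_%02d", cx, lin, split, seq_len(nm))
      labels[[length(labels) + 1]] <- tibble(
        id = ids, cross = cx, lineage = lin, split = split,
        parent1 = parent1, parent2 = alg_gm$samples$id[combos[, "b"]],
        eur_ancestry = rowMeans((a1 + a2) / 2)
      )
      hap1 <- rbind(hap1, h1); hap2 <- rbind(hap2, h2)
      anc1 <- rbind(anc1, a1); anc2 <- rbind(anc2, a2)
      prev_h1 <- h1; prev_h2 <- h2; prev_a1 <- a1; prev_a2 <- a2
      prev_cx <- cx
    }
  }
  labels <- bind_rows(labels)
  structure(list(hap1 = hap1, hap2 = hap2, anc1 = anc1, anc2 = anc2,
                 labels = labels, variants = v),
            class = "hybrid_cohort")
}

#' @method print hybrid_cohort
#' @export
print.hybrid_cohort <- function(x, ...) {
  cat(sprintf("<hybrid_cohort> %d hybrids (%s)\n", nrow(x$labels),
              paste(unique(x$labels$split), collapse = "/")))
  print(table(x$labels$cross, x$labels$lineage))
  invisible(x)
}

#' Convert a hybrid cohort to a diploid genotype matrix
#'
#' @param cohort A [make_cohort()] result.
#' @return A [genotype_matrix()] with ploidy 2; `group` is `HYB_<cross><lineage>`.
#' @export
cohort_genotypes <- function(cohort) {
  lb <- cohort$labels
  samples <- tibble(
    id = lb$id, group = paste0("HYB_", lb$cross, lb$lineage),
    subspecies = "hybrid", latitude = NA_real_, longitude = NA_real_,
    altitude = NA_real_, split = lb$split
  )
  genotype_matrix(cohort$hap1 + cohort$hap2, cohort$variants, samples,
                  ploidy = rep(2L, nrow(lb)))
}

# Stack two genotype matrices over identical variants.
bind_sample_sets <- function(gm1, gm2) {
  stopifnot(identical(gm1$variants$id, gm2$variants$id))
  common <- intersect(names(gm1$samples), names(gm2$samples))
  genotype_matrix(
    rbind(gm1$calls, gm2$calls), gm1$variants,
    bind_rows(gm1$samples[common], gm2$samples[common]),
    ploidy = c(gm1$ploidy, gm2$ploidy),
    het_counts = pmax(gm1$het_counts, gm2$het_counts)
  )
}

#' Classification experiments on simulated hybrids
#'
#' Three experiments on one panel of SNPs.  A: classifiers trained on the
#' original training samples only are applied to the test-split hybrids —
#' the per-cross P(Algerian) distributions show how backcrossing toward the
#' Algerian background pulls hybrids across the decision boundary.  B: the
#' training set additionally contains the train-split hybrids labelled
#' non-Algerian (mimicking known recent admixture in the reference data);
#' accuracy and per-class misassignment are recorded over repeated runs on
#' the combined test set.  C: experiment B repeated with all candidate SNPs
#' instead of the panel.
#'
#' @param train_gm,test_gm Original (haploid) training and test matrices.
#' @param cohort_train,cohort_test [make_cohort()] results for the two
#'   splits.
#' @param panel An `aim_panel` or character vector of variant ids.
#' @param all_ids Candidate-SNP ids used by experiment C (skipped if NULL).
#' @param n_runs Repeated classifier trainings (default 50).
#' @param n_trees Trees per forest.
#' @param seed Master seed.
#' @param alg_label Algerian group label.
#' @return List of class `hybrid_experiment`: `report` (tibble: experiment,
#'   class, n, mean_p_alg, misassignment), `accuracy` (per experiment), and
#'   the per-sample tables.
#' @export
hybrid_experiment <- function(train_gm, test_gm, cohort_train, cohort_test,
                              panel, all_ids = NULL, n_runs = 50,
                              n_trees = 100, seed = 1L,
                              alg_label = "ALG") {
  ids <- if (inherits(panel, "aim_panel")) panel$snps$id else panel
  hyb_train <- cohort_genotypes(cohort_train)
  hyb_test <- cohort_genotypes(cohort_test)
  if (length(intersect(hyb_train$samples$id, hyb_test$samples$id)) > 0)
    abort("hybrid id overlap between train and test splits (label leakage)")

  merged_train <- bind_sample_sets(train_gm, hyb_train)
  merged_test <- bind_sample_sets(test_gm, hyb_test)

  class_of <- function(gm)
    ifelse(gm$samples$group == alg_label, "ALG",
           ifelse(grepl("^HYB_", gm$samples$group),
                  sub("^HYB_", "", gm$samples$group), gm$samples$group))

  run_one <- function(tr_gm, te_gm, feat_ids, exp_tag, seed_off) {
    cl <- classify_samples(tr_gm, te_gm, feat_ids, n_runs = n_runs,
                           n_trees = n_trees,
                           seed = derive_seed(seed, seed_off),
                           alg_label = alg_label)
    per <- cl$samples
    per$class <- class_of(te_gm)
    rep_tbl <- per %>%
      group_by(.data$class) %>%
      summarise(n = n(), mean_p_alg = mean(.data$p_alg),
                misassignment = mean(!.data$correct)) %>%
      mutate(experiment = exp_tag, .before = 1)
    list(report = rep_tbl, samples = per, accuracy = cl$accuracy)
  }

  A <- run_one(train_gm, hyb_test, ids, "A_originals_panel", 51L)
  B <- run_one(merged_train, merged_test, ids, "B_with_hybrids_panel", 52L)
  out <- list(A = A, B = B)
  if (!is.null(all_ids))
    out$C <- run_one(merged_train, merged_test, all_ids,
                     "C_with_hybrids_allsnps", 53L)
  report <- bind_rows(lapply(out, `[[`, "report"))
  structure(list(
    report = report,
    accuracy = vapply(out, `[[`, numeric(1), "accuracy"),
    samples = lapply(out, `[[`, "samples")
  ), class = "hybrid_experiment")
}

#' @method print hybrid_experiment
#' @export
print.hybrid_experiment <- function(x, ...) {
  cat("<hybrid_experiment>\n")
  print(as.data.frame(x$report))
  invisible(x)
}

#' @method tidy hybrid_experiment
#' @export
tidy.hybrid_experiment <- function(x, ...) x$report
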