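#' Panel-selection configuration
#'
#' One of four configurations crossing the tree split criterion (Gini
#' impurity vs entropy) with the ranking method: `freq_top` ranks SNPs by
#' how often they appear in a run's top `per_run_top` importances over
#' `n_runs` repeated forest fits, `mean_importance` by their mean
#' importance over the runs.  The shorthand tags are GI1 (gini, freq_top),
#' GI2 (gini, mean), EN1 (entropy, freq_top) and EN2 (entropy, mean).
#'
#' @param criterion `"gini"` or `"entropy"`.
#' @param ranking `"freq_top"` or `"mean_importance"`.
#' @param n_runs Number of repeated forest fits (default 100).
#' @param per_run_top Size of each run's top list (default 96).
#' @param top_k_per_setting SNPs kept per population setting (default 48).
#' @param n_trees Trees per forest (default 100, pinned for
#'   reproducibility).
#' @param seed Master seed; run seeds are derived from it.
#' @return List of class `panel_config`.
#' @export
panel_config <- function(criterion = c("gini", "entropy"),
                         ranking = c("freq_top", "mean_importance"),
                         n_runs = 100, per_run_top = 96,
                         top_k_per_setting = 48, n_trees = 100,
                         seed = 1L) {
  criterion <- match.arg(criterion)
  ranking <- match.arg(ranking)
  stopifnot(top_k_per_setting * 2 >= 96)
  tag <- paste0(ifelse(criterion == "gini", "GI", "EN"),
                ifelse(ranking == "freq_top", "1", "2"))
  structure(list(criterion = criterion, ranking = ranking,
                 n_runs = n_runs, per_run_top = per_run_top,
                 top_k_per_setting = top_k_per_setting,
                 n_trees = n_trees, seed = as.integer(seed), tag = tag),
            class = "panel_config")
}

#' AIM candidate SNPs
#'
#' Variants with no missing genotype, then LD-pruned at a strengthened
#' threshold (default r-squared 0.13) — the candidate pool from which
#' ancestry-informative markers are ranked.
#'
#' @param gm A [genotype_matrix()].
#' @param r2_max LD threshold (default 0.13).
#' @param window_n,overlap_frac,maf_min Passed to [ld_prune()].
#' @param panel_size Used only to require at least `2 * panel_size`
#'   candidates.
#' @return Character vector of candidate variant ids.
#' @export
candidate_snps <- function(gm, r2_max = 0.13, window_n = 1749,
                           overlap_frac = 0.10, maf_min = 0.01,
                           panel_size = 96) {
  no_miss <- colSums(is.na(gm$calls)) == 0
  sub <- gm[, which(no_miss)]
  ids <- ld_prune(sub, window_n = window_n, overlap_frac = overlap_frac,
                  r2_max = r2_max, maf_min = maf_min)
  if (length(ids) < 2 * panel_size)
    abort(sprintf("only %d candidate SNPs; need at least %d",
                  length(ids), 2 * panel_size))
  ids
}

# Repeated-forest importance matrix: n_runs x n_features.
run_importances <- function(X, labels, criterion, n_runs, n_trees, seed) {
  imp <- matrix(0, nrow = n_runs, ncol = ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (r in seq_len(n_runs)) {
    imp[r, ] <- fit_importance(X, labels, criterion, n_trees,
                               seed = derive_seed(seed, 100L + r))
  }
  imp
}

# Rank SNPs from a stored importance matrix under one ranking method.
rank_from_importances <- function(imp, ranking, per_run_top) {
  ids <- colnames(imp)
  mean_imp <- colMeans(imp)
  if (ranking == "freq_top") {
    score <- integer(ncol(imp))
    for (r in seq_len(nrow(imp))) {
      top <- order(imp[r, ], decreasing = TRUE)[seq_len(per_run_top)]
      score[top] <- score[top] + 1L
    }
    ord <- order(-score, -mean_imp, seq_along(ids))
  } else {
    score <- rep(NA_integer_, ncol(imp))
    ord <- order(-mean_imp, seq_along(ids))
  }
  tibble(id = ids[ord],
         rank = seq_along(ids),
         freq_top = score[ord],
         mean_importance = mean_imp[ord])
}

#' Rank candidate SNPs by repeated random-forest importance
#'
#' Fits `n_runs` forests with the configured split criterion on the
#' dosage-fraction features against binary labels (Algerian vs
#' non-Algerian), records each run's impurity importances, and ranks the
#' SNPs by the configured method.  Importance matrices are cached on the
#' result so both ranking methods of one criterion can reuse the same runs.
#'
#' @param gm Training [genotype_matrix()] restricted to candidate SNPs.
#' @param labels Binary label vector (two classes required).
#' @param cfg A [panel_config()].
#' @param importances Optional precomputed importance matrix (to share runs
#'   across ranking methods).
#' @return Tibble `id, rank, freq_top, mean_importance` with the importance
#'   matrix in `attr(, "importances")`.
#' @export
rank_snps <- function(gm, labels, cfg = panel_config(),
                      importances = NULL) {
  if (length(unique(labels)) < 2) abort("labels contain a single class")
  X <- dosage(gm)
  if (is.null(importances))
    importances <- run_importances(X, labels, cfg$criterion, cfg$n_runs,
                                   cfg$n_trees, cfg$seed)
  ranked <- rank_from_importances(importances, cfg$ranking,
                                  cfg$per_run_top)
  attr(ranked, "importances") <- importances
  ranked
}

#' Assemble a 96-SNP panel from two per-setting rankings
#'
#' Takes the top `top_k` SNPs of the Algerian-vs-M ranking and the top
#' `top_k` of the Algerian-vs-C ranking.  When a SNP appears in both top
#' lists the union falls short of `2 * top_k`; the panel is then completed
#' by advancing alternately down both rankings (M first) past rank `top_k`
#' until it holds `panel_size` unique SNPs.
#'
#' @param ranked_M,ranked_C Ranking tibbles from [rank_snps()].
#' @param top_k SNPs per setting (default 48).
#' @param panel_size Final panel size (default 96).
#' @param tag Configuration tag carried on the result.
#' @return Object of class `aim_panel`: tibble `id, setting, rank` plus the
#'   tag; exactly `panel_size` unique variants.
#' @export
build_panel <- function(ranked_M, ranked_C, top_k = 48, panel_size = 96,
                        tag = "panel") {
  if (nrow(ranked_M) < panel_size || nrow(ranked_C) < panel_size)
    abort("rankings too short to build the panel")
  take <- function(ranked, setting, k)
    tibble(id = ranked$id[k], setting = setting, rank = k)
  sel <- bind_rows(take(ranked_M, "M", seq_len(top_k)),
                   take(ranked_C, "C", seq_len(top_k)))
  sel <- sel[!duplicated(sel$id), ]
  ptr <- c(M = top_k, C = top_k)
  nxt <- "M"
  while (nrow(sel) < panel_size) {
    ptr[nxt] <- ptr[nxt] + 1L
    ranked <- if (nxt == "M") ranked_M else ranked_C
    if (ptr[nxt] > nrow(ranked)) abort("ran out of ranked SNPs")
    cand <- ranked$id[ptr[nxt]]
    if (!cand %in% sel$id)
      sel <- bind_rows(sel, tibble(id = cand, setting = nxt,
                                   rank = unname(ptr[nxt])))
    nxt <- if (nxt == "M") "C" else "M"
  }
  structure(list(snps = sel, tag = tag, panel_size = panel_size),
            class = "aim_panel")
}

#' @method print aim_panel
#' @export
print.aim_panel <- function(x, ...) {
  cat(sprintf("<aim_panel %s> %d SNPs (%d from M setting, %d from C)\n",
              x$tag, nrow(x$snps), sum(x$snps$setting == "M"),
              sum(x$snps$setting == "C")))
  invisible(x)
}

#' @method tidy aim_panel
#' @export
tidy.aim_panel <- function(x, ...) x$snps

#' Validate a panel by test-set PCA distances
#'
#' PCA of the test samples restricted to the panel SNPs; plain Euclidean
#' pairwise distances on the top two PCs; the two objectives are the mean
#' within-Algerian pair distance (to minimise) and the mean
#' Algerian-vs-European pair distance (to maximise), with standard errors.
#'
#' @param panel An [build_panel()] result (or character vector of ids).
#' @param test_gm Test-split [genotype_matrix()] with a `group` column.
#' @param alg_label Group label of the Algerian class (default "ALG").
#' @return One-row tibble: tag, within/between means, standard errors and
#'   the between/within ratio.
#' @export
validate_panel_pca <- function(panel, test_gm, alg_label = "ALG") {
  ids <- if (inherits(panel, "aim_panel")) panel$snps$id else panel
  tag <- if (inherits(panel, "aim_panel")) panel$tag else "panel"
  missing_ids <- setdiff(ids, test_gm$variants$id)
  if (length(missing_ids) > 0)
    abort(sprintf("%d panel SNP(s) absent from the test matrix",
                  length(missing_ids)))
  grp <- test_gm$samples$group
  if (!any(grp == alg_label) || !any(grp != alg_label))
    abort("test set must contain Algerian and non-Algerian samples")
  res <- pca_genotypes(test_gm[, ids], n_pc = 2)
  sc <- cbind(res$scores$PC1, res$scores$PC2)
  D <- as.matrix(dist(sc))
  is_alg <- grp == alg_label
  ut <- upper.tri(D)
  within <- D[ut & outer(is_alg, is_alg, "&")]
  between <- D[ut & (outer(is_alg, !is_alg, "&") |
                       outer(!is_alg, is_alg, "&"))]
  tibble(
    tag = tag,
    within_mean = mean(within), within_se = sd(within) / sqrt(length(within)),
    between_mean = mean(between),
    between_se = sd(between) / sqrt(length(between)),
    ratio = mean(between) / mean(within)
  )
}

#' Select the best panel from validation results
#'
#' Picks the panel maximising the between/within PC-distance ratio, a
#' formalisation of "maximise Algerian-European separation while keeping
#' the Algerian cluster tight".  Ties break by configuration order GI1,
#' GI2, EN1, EN2.
#'
#' @param panels Named list of `aim_panel` objects.
#' @param validations Tibble of [validate_panel_pca()] rows (one per
#'   panel, `tag` matching the list names).
#' @return List with `best` (the chosen `aim_panel`) and `comparison` (the
#'   validation table ordered as compared).
#' @export
select_panel <- function(panels, validations) {
  order_pref <- c("GI1", "GI2", "EN1", "EN2")
  validations$pref <- match(validations$tag, order_pref,
                            nomatch = length(order_pref) + 1)
  cmp <- validations[order(-validations$ratio, validations$pref), ]
  best_tag <- cmp$tag[1]
  list(best = panels[[best_tag]], comparison = select(cmp, -"pref"))
}

#' Repeated-forest classification of test samples
#'
#' Trains `n_runs` probability forests on the panel features of the
#' training samples and averages the per-sample probability of the
#' Algerian class over runs; a sample's label is the class with the higher
#' mean probability.
#'
#' @param train_gm,test_gm [genotype_matrix()] objects with `group`
#'   metadata.
#' @param panel An `aim_panel` or character vector of variant ids.
#' @param n_runs Number of repeated fits (default 50).
#' @param n_trees Trees per forest.
#' @param seed Master seed.
#' @param alg_label Label of the Algerian class.
#' @return Object of class `aim_classification`: per-sample tibble
#'   (`id, group, p_alg, label, correct`), `accuracy`, `min_p_alg_alg`
#'   (minimum P(ALG) over Algerian test samples) and `max_p_alg_non`
#'   (maximum over non-Algerian).
#' @export
classify_samples <- function(train_gm, test_gm, panel, n_runs = 50,
                             n_trees = 100, seed = 1L,
                             alg_label = "ALG") {
  ids <- if (inherits(panel, "aim_panel")) panel$snps$id else panel
  for (g in list(train_gm, test_gm)) {
    missing_ids <- setdiff(ids, g$variants$id)
    if (length(missing_ids) > 0)
      abort(sprintf("%d panel SNP(s) absent from matrix", length(missing_ids)))
  }
  Xtr <- dosage(train_gm[, ids])
  Xte <- dosage(test_gm[, ids])
  ytr <- ifelse(train_gm$samples$group == alg_label, "ALG", "nonALG")
  yte <- ifelse(test_gm$samples$group == alg_label, "ALG", "nonALG")
  pmat <- matrix(0, nrow = nrow(Xte), ncol = n_runs)
  for (r in seq_len(n_runs)) {
    pmat[, r] <- forest_prob(Xtr, ytr, Xte, n_trees,
                             seed = derive_seed(seed, 200L + r),
                             positive = "ALG")
  }
  p_alg <- rowMeans(pmat)
  label <- ifelse(p_alg >= 0.5, "ALG", "nonALG")
  samples <- tibble(
    id = test_gm$samples$id, group = test_gm$samples$group,
    truth = yte, p_alg = p_alg, label = label,
    correct = label == yte
  )
  structure(list(
    samples = samples,
    accuracy = mean(samples$correct),
    min_p_alg_alg = suppressWarnings(min(p_alg[yte == "ALG"])),
    max_p_alg_non = suppressWarnings(max(p_alg[yte == "nonALG"])),
    n_runs = n_runs
  ), class = "aim_classification")
}

#' @method print aim_classification
#' @export
print.aim_classification <- function(x, ...) {
  cat(sprintf(
    "<aim_classification> accuracy %.3f over %d runs; min P(ALG|ALG)=%.2f max P(ALG|non)=%.2f\n",
    x$accuracy, x$n_runs, x$min_p_alg_alg, x$max_p_alg_non))
  invisible(x)
}

#' @method tidy aim_classification
#' @export
tidy.aim_classification <- function(x, ...) x$samples

#' @method glance aim_classification
#' @export
glance.aim_classification <- function(x, ...) {
  tibble(accuracy = x$accuracy, min_p_alg_alg = x$min_p_alg_alg,
         max_p_alg_non = x$max_p_alg_non, n_runs = x$n_runs)
}

#' Empirical random-panel null distribution
#'
#' Samples `n_panels` panels of `panel_size` SNPs without replacement from
#' the candidate set, classifies the test samples with each
#' ([classify_samples()] with `n_runs` repeats), and records the three
#' summary parameters: mean accuracy, minimum P(ALG) over Algerian test
#' samples, and maximum P(ALG) over non-Algerian test samples.  The
#' selected panel's empirical percentile is reported for each parameter.
#'
#' @param train_gm,test_gm Genotype matrices.
#' @param candidate_ids Candidate SNP ids to sample panels from.
#' @param selected Optional `aim_classification` of the selected panel, for
#'   percentiles.
#' @param n_panels Number of random panels (default 1000; use a reduced
#'   null for quick runs).
#' @param panel_size SNPs per panel (default 96).
#' @param n_runs Classifier repeats per panel (default 50).
#' @param n_trees Trees per forest.
#' @param seed Master seed.
#' @return List with `null` (tibble, one row per panel) and `percentiles`
#'   (one-row tibble, NA when no selected panel given).
#' @export
random_panel_null <- function(train_gm, test_gm, candidate_ids,
                              selected = NULL, n_panels = 1000,
                              panel_size = 96, n_runs = 50,
                              n_trees = 100, seed = 1L) {
  set.seed(derive_seed(seed, 31L))
  rows <- vector("list", n_panels)
  for (b in seq_len(n_panels)) {
    ids <- sample(candidate_ids, panel_size)
    cl <- classify_samples(train_gm, test_gm, ids, n_runs = n_runs,
                           n_trees = n_trees,
                           seed = derive_seed(seed, 300L + b))
    rows[[b]] <- tibble(panel = b, accuracy = cl$accuracy,
                        min_p_alg_alg = cl$min_p_alg_alg,
                        max_p_alg_non = cl$max_p_alg_non)
  }
  null <- bind_rows(rows)
  percentiles <- tibble(accuracy = NA_real_, min_p_alg_alg = NA_real_,
                        max_p_alg_non = NA_real_)
  if (!is.null(selected)) {
    percentiles <- tibble(
      accuracy = mean(null$accuracy <= selected$accuracy),
      min_p_alg_alg = mean(null$min_p_alg_alg <= selected$min_p_alg_alg),
      max_p_alg_non = mean(null$max_p_alg_non >= selected$max_p_alg_non)
    )
  }
  list(null = null, percentiles = percentiles)
}

#' Run the four-configuration AIM selection end to end
#'
#' Ranks candidates under both split criteria, derives the four panels
#' (GI1, GI2, EN1, EN2) with the 48+48 rule, validates each by test-set
#' PCA distances and selects the best by between/within ratio.
#'
#' @param train_gm Training genotype matrix (originals only).
#' @param test_gm Test genotype matrix.
#' @param candidate_ids From [candidate_snps()].
#' @param n_runs,per_run_top,top_k,n_trees,seed Configuration shared across
#'   the four panels.
#' @param alg_label Algerian group label.
#' @return List: `panels` (named list of `aim_panel`), `rankings` (named
#'   list per tag and setting), `validation` (tibble), `best`.
#' @export
select_aim_panels <- function(train_gm, test_gm, candidate_ids,
                              n_runs = 100, per_run_top = 96, top_k = 48,
                              n_trees = 100, seed = 1L,
                              alg_label = "ALG") {
  grp <- train_gm$samples$group
  is_alg <- grp == alg_label
  sub_M <- train_gm[which(is_alg | grp == "M"), candidate_ids]
  sub_C <- train_gm[which(is_alg | grp == "C"), candidate_ids]
  lab_M <- ifelse(sub_M$samples$group == alg_label, "ALG", "nonALG")
  lab_C <- ifelse(sub_C$samples$group == alg_label, "ALG", "nonALG")

  panels <- list(); rankings <- list()
  for (crit in c("gini", "entropy")) {
    imp_M <- run_importances(dosage(sub_M), lab_M, crit, n_runs, n_trees,
                             derive_seed(seed, ifelse(crit == "gini", 1L, 2L)))
    imp_C <- run_importances(dosage(sub_C), lab_C, crit, n_runs, n_trees,
                             derive_seed(seed, ifelse(crit == "gini", 3L, 4L)))
    for (rk in c("freq_top", "mean_importance")) {
      cfg <- panel_config(crit, rk, n_runs = n_runs,
                          per_run_top = per_run_top,
                          top_k_per_setting = top_k, n_trees = n_trees,
                          seed = seed)
      rM <- rank_from_importances(imp_M, rk, per_run_top)
      rC <- rank_from_importances(imp_C, rk, per_run_top)
      panels[[cfg$tag]] <- build_panel(rM, rC, top_k = top_k,
                                       panel_size = 96, tag = cfg$tag)
      rankings[[cfg$tag]] <- list(M = rM, C = rC)
    }
  }
  validation <- bind_rows(lapply(panels, validate_panel_pca,
                                 test_gm = test_gm,
                                 alg_label = alg_label))
  sel <- select_panel(panels, validation)
  list(panels = panels, rankings = rankings,
       validation = sel$comparison, best = sel$best)
}
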