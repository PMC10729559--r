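#' Principal component analysis of a genotype matrix
#'
#' Smartpca-style normalisation: each variant's dosage fractions are
#' centred by their mean and scaled by `sqrt(p(1-p))` with `p` the observed
#' alternate-allele frequency; missing calls are mean-imputed before
#' scaling; the normalised matrix is then decomposed by SVD.  Zero-variance
#' variants are dropped with a notice.  Percent variance uses all nonzero
#' eigenvalues in the denominator.
#'
#' @param gm A [genotype_matrix()].
#' @param n_pc Number of components to keep.
#' @return Object of class `aim_pca`: `scores` (tibble, `id` plus `PC1..n`),
#'   `eigenvalues` (all of them), `pct_variance` (for the kept PCs), and
#'   `variant_ids` used.
#' @export
pca_genotypes <- function(gm, n_pc = 10) {
  if (n_samples(gm) < 2) abort("PCA needs at least 2 samples")
  X <- dosage(gm)
  p <- allele_freq(gm)
  mu <- colMeans(X, na.rm = TRUE)
  keep <- !is.na(p) & p > 0 & p < 1 & apply(X, 2, function(col) {
    v <- var(col, na.rm = TRUE); !is.na(v) && v > 0
  })
  if (!all(keep))
    inform(sprintf("dropping %d zero-variance variant(s) before PCA",
                   sum(!keep)))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < n_pc) n_pc <- ncol(X)
  mu <- mu[keep]; p <- p[keep]
  X <- sweep(X, 2, mu, "-")
  X[is.na(X)] <- 0                      # mean imputation after centering
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(X)
  n <- nrow(X)
  ev <- sv$d^2 / (n - 1)
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(
    scores = bind_cols(tibble(id = gm$samples$id), as_tibble(scores)),
    eigenvalues = ev,
    pct_variance = 100 * ev[seq_len(n_pc)] / sum(ev),
    variant_ids = gm$variants$id[keep],
    meta = gm$samples
  ), class = "aim_pca")
}

#' @method print aim_pca
#' @export
print.aim_pca <- function(x, ...) {
  cat(sprintf("<aim_pca> %d samples, %d PCs; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$scores), ncol(x$scores) - 1,
              x$pct_variance[1], x$pct_variance[2]))
  invisible(x)
}

#' @method tidy aim_pca
#' @export
tidy.aim_pca <- function(x, ...) x$scores

#' @method glance aim_pca
#' @export
glance.aim_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_variants = length(x$variant_ids),
         pct_var_pc1 = x$pct_variance[1],
         pct_var_pc2 = x$pct_variance[2])
}

#' Eigenvalue-weighted two-PC genetic distance
#'
#' Pairwise genetic distance on the first two principal components, the
#' first coordinate weighted by the eigenvalue ratio:
#' `d_ij = sqrt((w (PC1_i - PC1_j))^2 + (PC2_i - PC2_j)^2)` with
#' `w = lambda1 / lambda2`.  `weight_on = "squared"` instead multiplies the
#' squared PC1 term by `w` (the alternative reading of the same recipe).
#'
#' @param res An [pca_genotypes()] result.
#' @param weight_on Where the weight enters: on the coordinate difference
#'   (default) or on its square.
#' @return Symmetric matrix of distances with sample-id dimnames.
#' @export
pc_distance <- function(res, weight_on = c("coordinate", "squared")) {
  weight_on <- match.arg(weight_on)
  if (ncol(res$scores) - 1 < 2) abort("pc_distance needs at least 2 PCs")
  l1 <- res$eigenvalues[1]; l2 <- res$eigenvalues[2]
  if (l2 <= 0) abort("second eigenvalue is zero")
  w <- l1 / l2
  pc1 <- res$scores$PC1; pc2 <- res$scores$PC2
  d1 <- outer(pc1, pc1, "-"); d2 <- outer(pc2, pc2, "-")
  D <- if (weight_on == "coordinate") sqrt((w * d1)^2 + d2^2)
       else sqrt(w * d1^2 + d2^2)
  dimnames(D) <- list(res$scores$id, res$scores$id)
  D
}

#' Great-circle distance (Haversine)
#'
#' Haversine distance on a sphere of radius 6371 km.  Vectorised over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    abort("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    abort("longitude outside [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Pairwise geographic distance matrix
#'
#' @param meta Tibble with `id`, `latitude`, `longitude`.
#' @return Symmetric matrix of km distances (NA where coordinates missing).
#' @export
geo_distance <- function(meta) {
  n <- nrow(meta)
  D <- matrix(NA_real_, n, n, dimnames = list(meta$id, meta$id))
  ok <- !is.na(meta$latitude) & !is.na(meta$longitude)
  ix <- which(ok)
  if (length(ix) >= 2) {
    sub <- meta[ix, ]
    M <- geosphere::distm(cbind(sub$longitude, sub$latitude),
                          fun = function(a, b)
                            geosphere::distHaversine(a, b, r = 6371000))
    D[ix, ix] <- M / 1000
  }
  diag(D) <- ifelse(ok, 0, NA_real_)
  D
}

significance_stars <- function(p) {
  case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
            TRUE ~ "")
}

#' Correlations between principal components and spatial coordinates
#'
#' Pearson correlation of each of the top `n_pc` PCs against latitude,
#' longitude and altitude, with two-sided p-values from the t transform on
#' n-2 degrees of freedom and significance stars at 5%/1%/0.1%.
#'
#' @param res An [pca_genotypes()] result.
#' @param meta Tibble with `id`, `latitude`, `longitude`, `altitude`.
#' @param n_pc Number of PCs to test (default 7).
#' @return Tibble: pc, coordinate, n, r, r2, p, stars.
#' @export
corr_pc_coords <- function(res, meta, n_pc = 7) {
  sc <- res$scores
  meta <- meta[match(sc$id, meta$id), ]
  if (sum(!is.na(meta$latitude)) < 3)
    abort("need at least 3 samples with coordinates")
  n_pc <- min(n_pc, ncol(sc) - 1)
  rows <- list()
  for (k in seq_len(n_pc)) {
    for (coord in c("latitude", "longitude", "altitude")) {
      x <- sc[[paste0("PC", k)]]
      y <- meta[[coord]]
      ok <- !is.na(x) & !is.na(y)
      ct <- suppressWarnings(cor.test(x[ok], y[ok]))
      rows[[length(rows) + 1]] <- tibble(
        pc = k, coordinate = coord, n = sum(ok),
        r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
        p = ct$p.value, stars = significance_stars(ct$p.value)
      )
    }
  }
  bind_rows(rows)
}

#' Correlation between genetic (dis)similarity and geographic distance
#'
#' Pearson correlation over sample pairs, for the whole pair set and for
#' the within-West, within-East and between-cluster pair masks when cluster
#' labels are supplied.  Genetic input can be a distance matrix (positive
#' correlation expected under isolation by distance) or a kinship matrix
#' (negative correlation expected).  Groups with fewer than 3 pairs are
#' skipped with a notice.
#'
#' @param gen_d Symmetric matrix (genetic distance or kinship), dimnames =
#'   sample ids.
#' @param geo_d Symmetric matrix of geographic distances, same ids.
#' @param clusters Optional named vector of cluster labels (`W`/`E`).
#' @return Tibble: group, n, r, r2, p, stars.
#' @export
corr_dist <- function(gen_d, geo_d, clusters = NULL) {
  if (inherits(gen_d, "kinship_matrix")) gen_d <- gen_d$K
  ids <- rownames(gen_d)
  geo_d <- geo_d[ids, ids]
  ut <- upper.tri(gen_d)
  masks <- list(all = ut)
  if (!is.null(clusters)) {
    cl <- clusters[ids]
    same <- outer(cl, cl, "==")
    for (g in sort(unique(cl)))
      masks[[paste0("within-", g)]] <- ut & same &
        outer(cl == g, cl == g, "&")
    masks[["between"]] <- ut & !same
  }
  rows <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]] & !is.na(gen_d) & !is.na(geo_d)
    if (sum(m) < 3) {
      inform(sprintf("group '%s' has fewer than 3 pairs; skipped", nm))
      next
    }
    ct <- suppressWarnings(cor.test(gen_d[m], geo_d[m]))
    rows[[length(rows) + 1]] <- tibble(
      group = nm, n = sum(m), r = unname(ct$estimate),
      r2 = unname(ct$estimate)^2, p = ct$p.value,
      stars = significance_stars(ct$p.value)
    )
  }
  bind_rows(rows)
}

#' Two-cluster assignment from PC1
#'
#' K-means with k = 2 on the first principal component (50 seeded restarts,
#' best inertia), used as a stand-in for a model-based two-way admixture
#' clustering, which PC1 captures.  The cluster whose members have the
#' lower mean longitude is labelled `W`.
#'
#' @param res An [pca_genotypes()] result.
#' @param meta Tibble with `id` and `longitude`.
#' @param seed Integer seed for the restarts.
#' @return Named character vector of labels (`W`/`E`) indexed by sample id.
#' @export
cluster2 <- function(res, meta, seed = 1L) {
  pc1 <- res$scores$PC1
  if (length(unique(pc1)) < 2)
    abort("degenerate PC1: no variance to cluster")
  set.seed(derive_seed(seed, 21L))
  km <- kmeans(pc1, centers = 2, nstart = 50)
  meta <- meta[match(res$scores$id, meta$id), ]
  mean_lon <- tapply(meta$longitude, km$cluster, mean, na.rm = TRUE)
  w_cluster <- as.integer(names(which.min(mean_lon)))
  labels <- ifelse(km$cluster == w_cluster, "W", "E")
  setNames(labels, res$scores$id)
}
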