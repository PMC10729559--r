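test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(61)
  calls <- matrix(rbinom(20 * 50, 1L, runif(50, 0.2, 0.8)), nrow = 20,
                  byrow = TRUE)
  gm <- toy_gm(calls)
  res <- suppressMessages(pca_genotypes(gm, n_pc = 5))
  # oracle: normalise the same way, eigendecompose the covariance
  X <- dosage(gm)[, gm$variants$id %in% res$variant_ids]
  p <- colMeans(X)
  Xn <- sweep(sweep(X, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  ev_oracle <- eigen(Xn %*% t(Xn) / (nrow(Xn) - 1))$values
  k <- length(res$eigenvalues)
  expect_equal(res$eigenvalues[1:5], ev_oracle[1:5], tolerance = 1e-8)
  # scores orthogonal
  S <- as.matrix(res$scores[, -1])
  G <- crossprod(S)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_lte(sum(res$pct_variance), 100 + 1e-9)
})

test_that("PC1 separates two strongly differentiated populations", {
  model <- pop_model(n_variants = 800, fst_lineage = 0.2, seed = 62,
                     n_train = c(ALG = 25, M = 25, C = 0),
                     n_test = c(ALG = 0, M = 0, C = 0))
  gm <- generate_dataset(model)$gm
  res <- suppressMessages(pca_genotypes(gm, n_pc = 4))
  grp <- gm$samples$group
  expect_equal(max(res$pct_variance), res$pct_variance[1])
  # complete linear separation of groups on PC1
  rng_alg <- range(res$scores$PC1[grp == "ALG"])
  rng_m <- range(res$scores$PC1[grp == "M"])
  expect_true(rng_alg[2] < rng_m[1] || rng_m[2] < rng_alg[1])
})

test_that("pc_distance implements the eigenvalue-weighted formula", {
  mk <- function(pc1, pc2, l1, l2) {
    structure(list(
      scores = tibble::tibble(id = letters[seq_along(pc1)],
                              PC1 = pc1, PC2 = pc2),
      eigenvalues = c(l1, l2)), class = "aim_pca")
  }
  # identical scores -> 0
  r <- mk(c(1, 1), c(2, 2), 3, 1)
  expect_equal(unname(pc_distance(r)["a", "b"]), 0)
  # lambda1 = lambda2 -> plain Euclidean
  r2 <- mk(c(0, 3), c(0, 4), 2, 2)
  expect_equal(unname(pc_distance(r2)["a", "b"]), 5)
  # ratio 2, dPC1 = 1, dPC2 = 0 -> 2
  r3 <- mk(c(0, 1), c(1, 1), 4, 2)
  expect_equal(unname(pc_distance(r3)["a", "b"]), 2)
  # squared-weight variant: sqrt(w * dPC1^2)
  expect_equal(unname(pc_distance(r3, weight_on = "squared")["a", "b"]),
               sqrt(2))
  r0 <- mk(c(0, 1), c(0, 1), 1, 0)
  expect_error(pc_distance(r0), "eigenvalue")
})

test_that("haversine agrees with the spherical law of cosines", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(90, 0, -90, 0), pi * 6371, tolerance = 1e-6)
  # independent oracle: spherical law of cosines
  slc <- function(lat1, lon1, lat2, lon2) {
    to_r <- pi / 180
    6371 * acos(pmin(1, sin(lat1 * to_r) * sin(lat2 * to_r) +
      cos(lat1 * to_r) * cos(lat2 * to_r) * cos((lon2 - lon1) * to_r)))
  }
  expect_equal(haversine_km(0, 0, 0, 1), slc(0, 0, 0, 1), tolerance = 1e-6)
  expect_equal(haversine_km(36.7, 3.1, 35.2, 8.1), slc(36.7, 3.1, 35.2, 8.1),
               tolerance = 1e-6)
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("PC-coordinate correlation table flags real and null signal", {
  set.seed(63)
  n <- 60
  lon <- runif(n, 0, 10)
  res <- structure(list(scores = tibble::tibble(
    id = sprintf("s%02d", 1:n), PC1 = lon, PC2 = rnorm(n))),
    class = "aim_pca")
  meta <- tibble::tibble(id = res$scores$id, latitude = runif(n, 30, 37),
                         longitude = lon, altitude = runif(n, 0, 1500))
  tab <- corr_pc_coords(res, meta, n_pc = 2)
  r_lon <- tab[tab$pc == 1 & tab$coordinate == "longitude", ]
  expect_equal(r_lon$r, 1, tolerance = 1e-12)
  expect_lt(r_lon$p, 1e-10)
  expect_equal(r_lon$stars, "***")
  # permuted coordinates: small correlations on PC2
  r_null <- tab[tab$pc == 2, ]
  expect_true(all(abs(r_null$r) < 0.4))
  expect_error(corr_pc_coords(res, meta[1:2, ]), "at least 3")
})

test_that("pair masks partition the 5151 pairs of 102 samples", {
  set.seed(64)
  n <- 102
  ids <- sprintf("s%03d", 1:n)
  lon <- runif(n, 0, 8)
  cl <- setNames(ifelse(lon > 4, "E", "W"), ids)
  gen <- abs(outer(lon, lon, "-")) + matrix(runif(n * n, 0, .5), n)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0
  dimnames(gen) <- list(ids, ids)
  geo <- abs(outer(lon, lon, "-")) * 100
  dimnames(geo) <- list(ids, ids)
  tab <- corr_dist(gen, geo, clusters = cl)
  expect_equal(tab$n[tab$group == "all"], n * (n - 1) / 2)  # 5151
  expect_equal(sum(tab$n[tab$group != "all"]),
               tab$n[tab$group == "all"])
  # brute-force recount of the between mask
  expect_equal(tab$n[tab$group == "between"],
               sum(outer(cl == "W", cl == "E", "&")))
  # isolation by distance: positive r; kinship-style input: negative
  expect_gt(tab$r[tab$group == "all"], 0.5)
  kin <- max(gen) - gen; diag(kin) <- 1; dimnames(kin) <- dimnames(gen)
  tab2 <- corr_dist(kin, geo, clusters = cl)
  expect_lt(tab2$r[tab2$group == "all"], -0.5)
  # gen == geo -> r exactly 1
  tab3 <- corr_dist(geo, geo)
  expect_equal(tab3$r, 1, tolerance = 1e-12)
})

test_that("two-cluster assignment splits PC1 and aligns with longitude", {
  # bimodal PC1: exact split
  pc1 <- c(rnorm(20, -5, .2), rnorm(20, 5, .2))
  res <- structure(list(scores = tibble::tibble(
    id = sprintf("s%02d", 1:40), PC1 = pc1)), class = "aim_pca")
  meta <- tibble::tibble(id = res$scores$id,
                         longitude = c(runif(20, 0, 2), runif(20, 6, 8)))
  lab <- cluster2(res, meta, seed = 1)
  expect_true(all(lab[1:20] == "W") && all(lab[21:40] == "E"))
  expect_identical(lab, cluster2(res, meta, seed = 1))  # restart determinism
  # on the default cline simulation, labels track longitude > 90%
  model <- pop_model(n_variants = 1200, fst_intra_alg = 0.05,
                     cline_steepness = 3,
                     n_train = c(ALG = 80, M = 0, C = 0),
                     n_test = c(ALG = 0, M = 0, C = 0), seed = 65)
  ds <- generate_dataset(model)
  res2 <- suppressMessages(pca_genotypes(ds$gm, n_pc = 2))
  lab2 <- cluster2(res2, ds$gm$samples, seed = 2)
  truth <- ifelse(ds$truth$ancestry$ancestry_e > 0.5, "E", "W")
  expect_gt(mean(lab2 == truth), 0.9)
  bad <- structure(list(scores = tibble::tibble(id = "x", PC1 = 0)),
                   class = "aim_pca")
  expect_error(cluster2(bad, meta), "degenerate")
})
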