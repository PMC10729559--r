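test_that("forward likelihood equals the exhaustive path-sum oracle", {
  set.seed(41)
  cases <- list(
    list(T = 3, chrom = c(1L, 1L, 1L)),
    list(T = 8, chrom = rep(1L, 8)),
    list(T = 12, chrom = rep(1:2, each = 6))   # includes a chain restart
  )
  for (cs in cases) {
    v <- tibble::tibble(chrom = cs$chrom,
                        pos = ave(seq_len(cs$T), cs$chrom,
                                  FUN = function(x)
                                    cumsum(sample(1e4:1e6, length(x)))))
    p <- runif(cs$T, 0.1, 0.9)
    g1 <- rbinom(cs$T, 1L, p); g2 <- rbinom(cs$T, 1L, p)
    for (f0 in c(0.2, 0.5, 0.8)) {
      cfg <- hmm_config(max_em_iters = 1, f_init = f0, k_init = 2)
      fit <- pair_ibd(g1, g2, v, p, cfg)
      oracle <- brute_force_loglik(g1, g2, v, p, f = f0, k = 2,
                                   rho = cfg$rec_rate,
                                   eps = cfg$genotype_error)
      expect_equal(fit$loglik, oracle, tolerance = 1e-9)
    }
  }
})

test_that("self comparison and unrelated pairs sit at the f extremes", {
  model <- pop_model(n_variants = 3000, seed = 42)
  fr <- draw_freqs(model)
  p <- fr$freqs[, "ALG"]
  cfg <- hmm_config()
  set.seed(43)
  g <- simulate_drone(p)
  expect_gte(pair_ibd(g, g, v = fr$variants, freqs = p, cfg)$f_viterbi, 0.99)
  f_unrel <- vapply(1:50, function(i) {
    a <- simulate_drone(p); b <- simulate_drone(p)
    pair_ibd(a, b, fr$variants, p, cfg)$f_viterbi
  }, numeric(1))
  expect_lte(mean(f_unrel), 0.05)
})

test_that("missing sites are skipped and monomorphic input errors", {
  model <- pop_model(n_variants = 500, seed = 44)
  fr <- draw_freqs(model)
  p <- fr$freqs[, "ALG"]
  set.seed(45)
  g1 <- simulate_drone(p); g2 <- g1
  g1[1:100] <- NA
  fit <- pair_ibd(g1, g2, fr$variants, p, hmm_config())
  expect_equal(fit$n_sites_used, 400)
  expect_error(pair_ibd(rep(0L, 500), rep(0L, 500), fr$variants,
                        rep(0, 500), hmm_config()),
               "informative")
  fit_low <- pair_ibd(g1[1:140], g2[1:140], fr$variants[1:140, ],
                      p[1:140], hmm_config())
  expect_true(fit_low$low_confidence)
})

test_that("f is stable across site-subsample seeds", {
  model <- pop_model(n_variants = 12000, seed = 46)
  fr <- draw_freqs(model)
  p <- fr$freqs[, "ALG"]
  pr <- make_related_pair(p, fr$variants, rm16, degree = 2, mode = "tract",
                          seed = 47)
  fs <- vapply(1:3, function(s) {
    set.seed(s)
    ix <- sort(sample(12000, 8000))
    pair_ibd(pr$g1[ix], pr$g2[ix], fr$variants[ix, ], p[ix],
             hmm_config())$f_viterbi
  }, numeric(1))
  expect_lt(max(fs) - min(fs), 0.04)   # within +/- 0.02 of a common value
})

test_that("Viterbi segments recover planted tracts of 1 Mb and larger", {
  model <- pop_model(n_variants = 20000, seed = 48)
  fr <- draw_freqs(model)
  p <- fr$freqs[, "ALG"]
  jac <- vapply(1:5, function(i) {
    pr <- make_related_pair(p, fr$variants, rm16, degree = 2,
                            mode = "tract", seed = 480 + i)
    fit <- pair_ibd(pr$g1, pr$g2, fr$variants, p, hmm_config())
    est_mask <- rep(FALSE, nrow(fr$variants))
    for (k in seq_len(nrow(fit$segments))) {
      s <- fit$segments[k, ]
      est_mask[fr$variants$chrom == s$chrom &
                 fr$variants$pos >= s$start &
                 fr$variants$pos <= s$end] <- TRUE
    }
    # score only against planted tracts >= 1 Mb
    big <- pr$tracts[pr$tracts$end - pr$tracts$start >= 1e6, ]
    true_mask <- rep(FALSE, nrow(fr$variants))
    for (k in seq_len(nrow(big))) {
      true_mask[fr$variants$chrom == big$chrom[k] &
                  fr$variants$pos >= big$start[k] &
                  fr$variants$pos <= big$end[k]] <- TRUE
    }
    sum(est_mask & true_mask) / sum(true_mask)
  }, numeric(1))
  expect_gte(mean(jac), 0.80)
})

test_that("kinship matrices are symmetric with a planted pair on top", {
  model <- pop_model(n_variants = 4000, seed = 49)
  fr <- draw_freqs(model)
  p <- fr$freqs[, "ALG"]
  set.seed(50)
  calls <- t(replicate(8, simulate_drone(p)))
  pr <- make_related_pair(p, fr$variants, rm16, degree = 1, mode = "tract",
                          seed = 51)
  calls <- rbind(calls, pr$g1, pr$g2)
  gm <- toy_gm(calls, chrom = fr$variants$chrom, pos = fr$variants$pos)
  K <- kinship_matrix(gm, hmm_config(subsample_frac = 0.5))
  expect_true(isSymmetric(K$K))
  expect_equal(unname(diag(K$K)), rep(1, 10))
  off <- K$K; diag(off) <- NA
  expect_equal(which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ] |>
                 sort() |> unname(), c(9, 10))
  # unrelated entries are small
  expect_lt(max(off[1:8, 1:8], na.rm = TRUE), 0.1)
})

test_that("family components follow transitive closure and call-rate rule", {
  ids <- c("A", "B", "C", "D")
  K <- matrix(0.02, 4, 4, dimnames = list(ids, ids))
  diag(K) <- 1
  K["A", "B"] <- K["B", "A"] <- 0.45
  K["B", "C"] <- K["C", "B"] <- 0.45
  K["A", "C"] <- K["C", "A"] <- 0.05
  fam <- family_components(K, threshold = 0.30,
                           call_rates = c(A = 0.97, B = 0.99, C = 0.98,
                                          D = 0.90))
  expect_setequal(fam$retained_ids, c("B", "D"))
  expect_equal(length(unique(stats::na.omit(fam$families$family))), 1)
  # tie on call rate -> lexicographically first id
  fam2 <- family_components(K, threshold = 0.30,
                            call_rates = c(A = 0.99, B = 0.99, C = 0.99,
                                           D = 0.90))
  expect_true("A" %in% fam2$retained_ids)
})

test_that("a 26-member family keeps exactly one sample", {
  ids <- sprintf("m%02d", 1:30)
  K <- matrix(0.01, 30, 30, dimnames = list(ids, ids)); diag(K) <- 1
  K[1:26, 1:26] <- 0.5; diag(K) <- 1
  cr <- setNames(runif(30, 0.95, 1), ids)
  fam <- family_components(K, threshold = 0.30, call_rates = cr)
  expect_equal(sum(fam$retained_ids %in% ids[1:26]), 1)
  expect_setequal(setdiff(fam$retained_ids, ids[1:26]), ids[27:30])
  # retained member is the call-rate argmax (brute force)
  expect_equal(intersect(fam$retained_ids, ids[1:26]),
               names(which.max(cr[1:26])))
})

test_that("close-kin reporting lists pairs above cutoff with distances", {
  ids <- c("a", "b", "c")
  K <- matrix(0.01, 3, 3, dimnames = list(ids, ids)); diag(K) <- 1
  K["a", "b"] <- K["b", "a"] <- 0.125     # third degree: above 0.10
  meta <- tibble::tibble(id = ids, latitude = c(36, 35, NA),
                         longitude = c(3, 5, NA),
                         cluster = c("E", "E", "W"))
  ck <- close_kin(K, cutoff = 0.10, meta = meta)
  expect_equal(nrow(ck$pairs), 1)
  expect_equal(ck$pairs$sample1, "a")
  expect_equal(ck$pairs$kinship, 0.125)
  expect_equal(ck$pairs$distance_km,
               haversine_km(36, 3, 35, 5), tolerance = 1e-9)
  expect_equal(ck$cluster_counts$n[ck$cluster_counts$pair_type == "within-E"], 1L)
  # nothing above cutoff -> empty report
  K2 <- matrix(0.02, 3, 3, dimnames = list(ids, ids)); diag(K2) <- 1
  expect_equal(nrow(close_kin(K2, meta = meta)$pairs), 0)
})
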