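#' IBD HMM configuration
#'
#' Parameters of the two-state hidden Markov model used to detect
#' identity-by-descent segments between pairs of haploid genomes, with the
#' honey-bee settings as defaults: 16 chromosomes and a recombination rate
#' of 9.04e-7 per bp per generation.
#'
#' @param nchrom Number of chromosomes.
#' @param rec_rate Recombination rate per bp per generation.
#' @param genotype_error Per-allele genotyping error probability.
#' @param max_em_iters EM iteration cap (default 5).
#' @param em_tol Convergence tolerance on both f and k.
#' @param k_init,f_init Initial generation parameter and IBD fraction.
#' @param subsample_frac Fraction of polymorphic sites used by
#'   [kinship_matrix()] (default 0.05, mirroring the ~5% SNP subset used at
#'   full genome scale).
#' @param min_informative Pairs analysed at fewer informative sites than
#'   this are flagged low-confidence.
#' @param seed Integer seed for the site subsample.
#' @return List of class `hmm_config`.
#' @export
hmm_config <- function(nchrom = 16, rec_rate = 9.04e-7,
                       genotype_error = 0.001, max_em_iters = 5,
                       em_tol = 1e-3, k_init = 1.0, f_init = 0.5,
                       subsample_frac = 0.05, min_informative = 50,
                       seed = 1L) {
  stopifnot(rec_rate > 0, genotype_error >= 0, genotype_error < 0.5,
            f_init >= 0, f_init <= 1, subsample_frac > 0,
            subsample_frac <= 1)
  structure(as.list(environment()), class = "hmm_config")
}

# Emission probabilities for one pair at alternate-allele frequencies p.
# e(a|t) = 1-eps if a == t else eps;  m(a) = sum_t p_t e(a|t).
# DBD emits m(a1) m(a2); IBD emits sum_t p_t e(a1|t) e(a2|t).
pair_emissions <- function(g1, g2, p, eps) {
  e_of <- function(a, t) ifelse(a == t, 1 - eps, eps)
  m1 <- p * e_of(g1, 1L) + (1 - p) * e_of(g1, 0L)
  m2 <- p * e_of(g2, 1L) + (1 - p) * e_of(g2, 0L)
  e_dbd <- m1 * m2
  e_ibd <- p * e_of(g1, 1L) * e_of(g2, 1L) +
    (1 - p) * e_of(g1, 0L) * e_of(g2, 0L)
  list(ibd = e_ibd, dbd = e_dbd)
}

#' Pairwise IBD estimation between two haploid genomes
#'
#' Fits the two-state IBD/DBD HMM by scaled forward-backward EM and decodes
#' the Viterbi path.  The kinship statistic is `f_viterbi`, the fraction of
#' informative sites assigned to the IBD state on the most probable path;
#' the mean posterior IBD probability (`f_posterior`) and the
#' generation-scale parameter `k_hat` are also reported.  Sites missing in
#' either sample are skipped but still contribute their physical gap to the
#' transition distances; monomorphic sites are uninformative and dropped;
#' the chain restarts at each chromosome start.
#'
#' @param g1,g2 Haploid 0/1 genotype vectors (NA = missing).
#' @param variants Tibble with `chrom`, `pos` (sorted).
#' @param freqs Per-site alternate-allele frequencies of the analysis panel.
#' @param cfg An [hmm_config()].
#' @return List of class `pair_ibd`: `f_viterbi`, `f_posterior`, `k_hat`,
#'   `loglik`, `n_sites_used`, `low_confidence`, and `segments`
#'   (tibble chrom/start/end of Viterbi IBD runs).
#' @export
pair_ibd <- function(g1, g2, variants, freqs, cfg = hmm_config()) {
  keep <- !is.na(g1) & !is.na(g2) & !is.na(freqs) &
    freqs > 0 & freqs < 1
  if (!any(keep)) abort("no informative (polymorphic, non-missing) sites")
  g1 <- g1[keep]; g2 <- g2[keep]
  p <- freqs[keep]
  v <- variants[keep, , drop = FALSE]
  T_ <- length(g1)
  new_chrom <- c(TRUE, diff(v$chrom) != 0)
  gap <- c(0, diff(v$pos))
  gap[new_chrom] <- 0

  em <- pair_emissions(g1, g2, p, cfg$genotype_error)
  fit <- ibd_hmm_core(em$ibd, em$dbd, gap, new_chrom,
                      cfg$rec_rate, cfg$f_init, cfg$k_init,
                      cfg$max_em_iters, cfg$em_tol)
  path <- fit$path
  seg <- viterbi_segments(path, v)
  structure(list(
    f_viterbi = fit$f_viterbi,
    f_posterior = fit$f_posterior,
    k_hat = fit$k,
    loglik = fit$loglik,
    n_sites_used = T_,
    low_confidence = T_ < cfg$min_informative,
    segments = seg
  ), class = "pair_ibd")
}

viterbi_segments <- function(path, v) {
  out <- list()
  for (ch in unique(v$chrom)) {
    ix <- which(v$chrom == ch)
    r <- rle(path[ix] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = v$pos[ix[starts[k]]],
        end = v$pos[ix[ends[k]]]
      )
    }
  }
  if (length(out) == 0)
    tibble(chrom = integer(), start = integer(), end = integer())
  else bind_rows(out)
}

#' @method print pair_ibd
#' @export
print.pair_ibd <- function(x, ...) {
  cat(sprintf(
    "<pair_ibd> f_viterbi=%.3f f_posterior=%.3f k_hat=%.2f sites=%d%s\n",
    x$f_viterbi, x$f_posterior, x$k_hat, x$n_sites_used,
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Pairwise IBD kinship matrix
#'
#' Runs [pair_ibd()] on every pair of (haploid) samples over a seeded random
#' subsample of `subsample_frac` of the polymorphic sites.
#'
#' @param gm A [genotype_matrix()] of haploid samples.
#' @param cfg An [hmm_config()].
#' @return List of class `kinship_matrix`: `K` (symmetric `f_viterbi`
#'   matrix, unit diagonal), `pairs` (tibble with one row per pair) and the
#'   ids of the sites used.
#' @export
kinship_matrix <- function(gm, cfg = hmm_config()) {
  if (any(gm$ploidy != 1L)) abort("kinship_matrix expects haploid samples")
  p <- allele_freq(gm)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (length(poly) == 0) abort("no polymorphic sites")
  set.seed(derive_seed(cfg$seed, 11L))
  n_keep <- max(1L, round(length(poly) * cfg$subsample_frac))
  sites <- sort(sample(poly, n_keep))
  v <- gm$variants[sites, , drop = FALSE]
  ps <- p[sites]
  n <- n_samples(gm)
  K <- diag(1, n)
  rownames(K) <- colnames(K) <- gm$samples$id
  rows <- list()
  for (i in seq_len(n - 1)) {
    gi <- gm$calls[i, sites]
    for (j in seq((i + 1), n)) {
      fit <- pair_ibd(gi, gm$calls[j, sites], v, ps, cfg)
      K[i, j] <- K[j, i] <- fit$f_viterbi
      rows[[length(rows) + 1]] <- tibble(
        sample1 = gm$samples$id[i], sample2 = gm$samples$id[j],
        n_sites = fit$n_sites_used, k_hat = fit$k_hat,
        f_viterbi = fit$f_viterbi, f_posterior = fit$f_posterior,
        low_confidence = fit$low_confidence
      )
    }
  }
  structure(list(K = K, pairs = bind_rows(rows), sites = v$id),
            class = "kinship_matrix")
}

#' @method print kinship_matrix
#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d samples, %d pairs, %d sites\n",
              nrow(x$K), nrow(x$pairs), length(x$sites)))
  invisible(x)
}

#' Tidy a kinship matrix into its pair table
#'
#' @param x A `kinship_matrix`.
#' @param ... Unused.
#' @method tidy kinship_matrix
#' @export
tidy.kinship_matrix <- function(x, ...) x$pairs

#' Family detection and one-per-family retention
#'
#' Builds a graph with an edge for every pair whose kinship exceeds
#' `threshold` (default 30%, separating full-sib drone pairs at ~50% IBD
#' from the unrelated background); connected components of two or more
#' samples are putative queen families.  Within each family only the sample
#' with the best call rate is retained (ties: lexicographically first id);
#' singletons are always retained.
#'
#' @param K A `kinship_matrix` or plain symmetric matrix with dimnames.
#' @param threshold Kinship cut for family edges (default 0.30).
#' @param call_rates Named call-rate vector (defaults to 1 for all).
#' @return List with `families` (tibble id/family/retained) and
#'   `retained_ids`.
#' @export
family_components <- function(K, threshold = 0.30, call_rates = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  ids <- rownames(K)
  if (is.null(call_rates)) call_rates <- setNames(rep(1, length(ids)), ids)
  A <- (K > threshold)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  fam <- tibble(id = ids, family = comp,
                call_rate = unname(call_rates[ids]))
  fam <- fam %>%
    group_by(.data$family) %>%
    mutate(family_size = n(),
           retained = .data$id ==
             .data$id[order(-.data$call_rate, .data$id)][1]) %>%
    ungroup()
  fam$family[fam$family_size == 1] <- NA_integer_
  list(families = fam, retained_ids = fam$id[fam$retained])
}

#' Close-kin pair report
#'
#' Lists every pair with kinship above `cutoff` (default 10%, a conservative
#' bound below the ~12.5% expectation of a third-degree relationship),
#' annotated with the great-circle distance between the samples' sites and,
#' when cluster labels are supplied, the pair's cluster composition and
#' per-cluster counts.
#'
#' @param K A `kinship_matrix` or plain symmetric matrix with dimnames.
#' @param cutoff Kinship cutoff (default 0.10).
#' @param meta Tibble with `id`, `latitude`, `longitude` and optionally
#'   `cluster`.
#' @return List with `pairs` (tibble) and `cluster_counts` (tibble, empty
#'   when no cluster labels).
#' @export
close_kin <- function(K, cutoff = 0.10, meta = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  ids <- rownames(K)
  ut <- which(upper.tri(K) & K > cutoff, arr.ind = TRUE)
  pairs <- tibble(
    sample1 = ids[ut[, 1]], sample2 = ids[ut[, 2]],
    kinship = K[ut]
  )
  if (!is.null(meta) && nrow(pairs) > 0) {
    m <- meta[match(pairs$sample1, meta$id), ]
    m2 <- meta[match(pairs$sample2, meta$id), ]
    ok <- !is.na(m$latitude) & !is.na(m2$latitude) &
      !is.na(m$longitude) & !is.na(m2$longitude)
    pairs$distance_km <- NA_real_
    if (any(ok))
      pairs$distance_km[ok] <- haversine_km(
        m$latitude[ok], m$longitude[ok], m2$latitude[ok], m2$longitude[ok])
    if ("cluster" %in% names(meta)) {
      pairs$cluster1 <- m$cluster
      pairs$cluster2 <- m2$cluster
      pairs$pair_type <- ifelse(pairs$cluster1 == pairs$cluster2,
                                paste0("within-", pairs$cluster1),
                                "between")
    }
  }
  counts <- if ("pair_type" %in% names(pairs)) {
    pairs %>% group_by(.data$pair_type) %>% summarise(n = n())
  } else {
    tibble(pair_type = character(), n = integer())
  }
  list(pairs = pairs, cluster_counts = counts)
}
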