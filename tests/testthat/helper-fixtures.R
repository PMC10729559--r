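# Shared fixture builders and independent oracles.

# Small genotype matrix built directly from a call matrix.
toy_gm <- function(calls, chrom = NULL, pos = NULL, ploidy = NULL,
                   groups = NULL, het_counts = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  variants <- tibble::tibble(
    chrom = as.integer(chrom), pos = as.integer(pos),
    id = sprintf("v%03d", seq_len(m)), ref = "A", alt = "T"
  )
  samples <- tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    group = if (is.null(groups)) rep("ALG", n) else groups,
    subspecies = NA_character_, latitude = NA_real_,
    longitude = NA_real_, altitude = NA_real_
  )
  genotype_matrix(calls, variants, samples, ploidy = ploidy,
                  het_counts = het_counts)
}

# Hudson Fst estimator (ratio of averages) from two sample-frequency
# vectors and sample sizes — the independent drift-recovery oracle.
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Exhaustive path-sum likelihood for the two-state IBD HMM: enumerates all
# 2^T state paths directly from the model definition.  Independent of the
# scaled forward implementation.
brute_force_loglik <- function(g1, g2, variants, freqs, f, k, rho, eps) {
  em <- aimkit:::pair_emissions(g1, g2, freqs, eps)
  T_ <- length(g1)
  new_chrom <- c(TRUE, diff(variants$chrom) != 0)
  gap <- c(0, diff(variants$pos)); gap[new_chrom] <- 0
  pi <- c(f, 1 - f)
  emit <- rbind(em$ibd, em$dbd)          # state x site
  total <- 0
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  for (r in seq_len(nrow(paths))) {
    s <- unname(as.integer(paths[r, ]))
    pr <- 1
    for (t in seq_len(T_)) {
      if (new_chrom[t]) {
        pr <- pr * pi[s[t]] * emit[s[t], t]
      } else {
        q <- exp(-k * rho * gap[t])
        a <- (s[t] == s[t - 1]) * q + (1 - q) * pi[s[t]]
        pr <- pr * a * emit[s[t], t]
      }
    }
    total <- total + pr
  }
  log(unname(total))
}

# Site-level Jaccard index between two logical masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Default small recombination map shared by tests.
rm16 <- recomb_map()
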