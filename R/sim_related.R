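#' Simulate a queen pedigree of drone brothers
#'
#' A queen is a diploid with two founder haplotypes drawn from per-site
#' allele frequencies; each of her drones is one recombinant gamete
#' (unfertilized egg), so two drones of the same queen share an expected
#' 50% of their genome identical by descent.
#'
#' @param p Per-site allele frequencies of the source population.
#' @param variants Tibble with `chrom`, `pos`.
#' @param recmap A [recomb_map()].
#' @param n_drones Number of gametes to draw.
#' @param seed Integer seed.
#' @return List with `queen` (two haplotypes), `drones` (matrix n_drones x
#'   sites) and `sources` (which queen haplotype each site came from, per
#'   drone) — the sources give the exact pairwise IBD masks.
#' @export
queen_family <- function(p, variants, recmap, n_drones = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q1 <- simulate_drone(p)
  q2 <- simulate_drone(p)
  drones <- matrix(NA_integer_, nrow = n_drones, ncol = length(p))
  sources <- matrix(NA_integer_, nrow = n_drones, ncol = length(p))
  for (d in seq_len(n_drones)) {
    g <- meiosis(q1, q2, variants, recmap)
    drones[d, ] <- g$hap
    sources[d, ] <- g$src
  }
  list(queen = rbind(q1, q2), drones = drones, sources = sources)
}

#' Construct a pair of haploid genomes with controlled IBD
#'
#' Two modes.  In `pedigree` mode (first degree only) the pair are two
#' meiosis gametes of one simulated queen, with expected IBD 0.5 and an
#' exact site-level mask from the gamete sources.  In `tract` mode the pair
#' starts as two independent genomes and IBD tracts (lengths exponential,
#' mean `tract_mean` bp) are copied from the first onto the second until
#' exactly a fraction `2^-degree` of the genome (in bp) is covered — the
#' final tract is trimmed so the bp coverage is exact; degrees 1, 2, 3 give
#' 50%, 25% and 12.5% sharing, the expectations for first- to third-degree
#' relationships.
#'
#' @param p Per-site allele frequencies.
#' @param variants Tibble with `chrom`, `pos`.
#' @param recmap A [recomb_map()].
#' @param degree Relationship degree (1, 2 or 3).
#' @param mode `"tract"` or `"pedigree"`.
#' @param tract_mean Mean IBD tract length in bp (default 2 Mb).
#' @param seed Integer seed.
#' @return List with `g1`, `g2` (haploid genotypes), `ibd_mask` (logical
#'   per site), `ibd_bp_fraction` (realized bp fraction) and `tracts`
#'   (tibble chrom/start/end, tract mode only).
#' @export
make_related_pair <- function(p, variants, recmap, degree = 1,
                              mode = c("tract", "pedigree"),
                              tract_mean = 2e6, seed = NULL) {
  mode <- match.arg(mode)
  if (!degree %in% 1:3) abort("`degree` must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "pedigree") {
    if (degree != 1)
      abort("pedigree mode implements first-degree pairs (drone brothers)")
    fam <- queen_family(p, variants, recmap, n_drones = 2)
    mask <- fam$sources[1, ] == fam$sources[2, ]
    return(list(g1 = fam$drones[1, ], g2 = fam$drones[2, ],
                ibd_mask = mask,
                ibd_bp_fraction = NA_real_,
                tracts = NULL))
  }
  g1 <- simulate_drone(p)
  g2 <- simulate_drone(p)
  genome_len <- sum(recmap$chrom_lengths)
  target <- genome_len * 2^(-degree)
  covered <- vector("list", length(recmap$chrom_lengths))
  total <- 0
  while (total < target) {
    ch <- sample(seq_along(recmap$chrom_lengths), 1,
                 prob = recmap$chrom_lengths)
    L <- recmap$chrom_lengths[ch]
    len <- min(rexp(1, 1 / tract_mean), L)
    start <- runif(1, 0, L - len)
    iv <- c(start, start + len)
    merged <- interval_union(covered[[ch]], iv)
    gain <- interval_total(merged) - interval_total(covered[[ch]])
    if (gain <= 0) next
    if (total + gain > target) {
      # trim: shrink the new tract so the union grows by exactly the deficit
      deficit <- target - total
      iv <- trim_interval(covered[[ch]], iv, deficit)
      merged <- interval_union(covered[[ch]], iv)
      gain <- interval_total(merged) - interval_total(covered[[ch]])
    }
    covered[[ch]] <- merged
    total <- total + gain
  }
  mask <- rep(FALSE, nrow(variants))
  tracts <- list()
  for (ch in seq_along(covered)) {
    if (is.null(covered[[ch]])) next
    ivs <- covered[[ch]]
    for (k in seq_len(nrow(ivs))) {
      ix <- which(variants$chrom == ch &
                    variants$pos >= ivs[k, 1] & variants$pos <= ivs[k, 2])
      mask[ix] <- TRUE
      tracts[[length(tracts) + 1]] <-
        tibble(chrom = ch, start = ivs[k, 1], end = ivs[k, 2])
    }
  }
  g2[mask] <- g1[mask]
  list(g1 = g1, g2 = g2, ibd_mask = mask,
       ibd_bp_fraction = total / genome_len,
       tracts = bind_rows(tracts))
}

# -- interval helpers (matrices with columns start, end) ---------------------

interval_union <- function(ivs, new) {
  m <- rbind(ivs, matrix(new, ncol = 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (k in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[k, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[k, 2])
    } else {
      out <- rbind(out, m[k, ])
    }
  }
  out
}

interval_total <- function(ivs) {
  if (is.null(ivs)) return(0)
  sum(ivs[, 2] - ivs[, 1])
}

# Shrink `new` (keeping its start) so that the union with `ivs` grows by
# exactly `deficit` bp.  Monotone in the end point, so bisect.
trim_interval <- function(ivs, new, deficit) {
  base <- interval_total(ivs)
  gain_at <- function(end) {
    interval_total(interval_union(ivs, c(new[1], end))) - base
  }
  lo <- new[1]; hi <- new[2]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (gain_at(mid) < deficit) lo <- mid else hi <- mid
  }
  c(new[1], hi)
}
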