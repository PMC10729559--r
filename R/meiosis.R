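#' Recombination map
#'
#' Chromosome lengths plus a per-bp, per-meiosis crossover rate.  The
#' default rate matches the honey-bee value used throughout the package
#' (9.04e-7 per bp), one of the highest recombination rates known in
#' animals.
#'
#' @param chrom_lengths Chromosome lengths in bp, indexed by chromosome
#'   number (default 16 x 14 Mb).
#' @param rec_rate Crossover rate per bp per meiosis.
#' @return List of class `recomb_map`.
#' @export
recomb_map <- function(chrom_lengths = rep(14e6, 16),
                       rec_rate = 9.04e-7) {
  stopifnot(rec_rate > 0, all(chrom_lengths > 0))
  structure(list(chrom_lengths = chrom_lengths, rec_rate = rec_rate),
            class = "recomb_map")
}

#' Simulate one meiosis
#'
#' Produces a recombinant gamete from a pair of haplotypes.  Per
#' chromosome, the crossover count is Poisson(rate x length), breakpoints
#' are uniform, the starting haplotype is Bernoulli(0.5); no interference,
#' no mutation.  Any per-site annotation (ancestry labels, haplotype source)
#' is carried along through the same breakpoints.
#'
#' @param h1,h2 Parental haplotypes: integer 0/1 vectors over the variant
#'   sites.
#' @param variants Tibble with `chrom` and `pos` for each site (sorted).
#' @param recmap A [recomb_map()].
#' @return List with `hap` (gamete alleles) and `src` (1/2: which parental
#'   haplotype each site was copied from).
#' @export
meiosis <- function(h1, h2, variants, recmap) {
  stopifnot(length(h1) == nrow(variants), length(h2) == nrow(variants))
  src <- integer(nrow(variants))
  for (ch in unique(variants$chrom)) {
    ix <- which(variants$chrom == ch)
    L <- recmap$chrom_lengths[ch]
    n_x <- rpois(1, recmap$rec_rate * L)
    bp <- sort(runif(n_x, 0, L))
    start <- sample(1:2, 1)
    n_before <- findInterval(variants$pos[ix], bp)
    src[ix] <- ((start - 1L + n_before) %% 2L) + 1L
  }
  hap <- ifelse(src == 1L, h1, h2)
  list(hap = as.integer(hap), src = src)
}
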