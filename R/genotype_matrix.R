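#' Genotype matrix container
#'
#' Holds a samples x variants matrix of alternate-allele counts together with
#' per-sample metadata (including ploidy) and per-variant metadata.  Drones
#' are haploid (calls in \{0, 1\}); simulated hybrids are diploid (calls in
#' \{0, 1, 2\}).  Missing calls are `NA`.  Heterozygous calls observed in
#' haploid samples are genotyping artifacts: they are recorded in a
#' per-variant side count (`het_counts`) and stored as missing, because they
#' are a site-quality signal rather than genotypes.
#'
#' @param calls Integer matrix, samples in rows, variants in columns;
#'   `calls[i, j] <= ploidy[i]` or `NA`.
#' @param variants Tibble with columns `chrom` (integer), `pos` (1-based bp),
#'   `id`, `ref`, `alt`, and optionally `n_alleles` (observed allele number,
#'   defaults to 2).
#' @param samples Tibble with columns `id`, `group`, `subspecies`,
#'   `latitude`, `longitude`, `altitude` (missing metadata may be `NA`).
#' @param ploidy Integer vector, one entry per sample (1 or 2).
#' @param het_counts Integer vector, one entry per variant: number of
#'   heterozygous calls seen in haploid samples at that site.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples, ploidy = NULL,
                            het_counts = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (is.null(ploidy)) ploidy <- rep(1L, nrow(calls))
  ploidy <- as.integer(ploidy)
  if (is.null(het_counts)) het_counts <- rep(0L, ncol(calls))
  het_counts <- as.integer(het_counts)

  if (nrow(calls) != nrow(samples))
    abort("`calls` rows and `samples` rows disagree.")
  if (ncol(calls) != nrow(variants))
    abort("`calls` columns and `variants` rows disagree.")
  if (length(ploidy) != nrow(calls))
    abort("`ploidy` must have one entry per sample.")
  if (length(het_counts) != ncol(calls))
    abort("`het_counts` must have one entry per variant.")
  bad <- which(calls > ploidy[row(calls)])
  if (length(bad) > 0)
    abort("calls exceed sample ploidy.")
  if (!all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
    abort("`variants` needs columns chrom, pos, id, ref, alt.")
  if (!"n_alleles" %in% names(variants)) variants$n_alleles <- 2L
  for (col in c("group", "subspecies", "latitude", "longitude", "altitude"))
    if (!col %in% names(samples)) samples[[col]] <- NA
  if (!"id" %in% names(samples)) abort("`samples` needs an id column.")

  rownames(calls) <- samples$id
  colnames(calls) <- variants$id
  structure(
    list(calls = calls, variants = variants, samples = samples,
         ploidy = ploidy, het_counts = het_counts),
    class = "genotype_matrix"
  )
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              n_samples(x), n_variants(x)))
  pl <- table(x$ploidy)
  cat("  ploidy:", paste(sprintf("%s n=%s", names(pl), pl), collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$variants$chrom)),
      " missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname genotype_matrix
#' @export
n_variants <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample selector (indices, logical, or sample ids).
#' @param j Variant selector (indices, logical, or variant ids).
#' @param ... Unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(i) || anyNA(j)) abort("unknown sample or variant id in subset")
  genotype_matrix(
    calls = x$calls[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE],
    ploidy = x$ploidy[i],
    het_counts = x$het_counts[j]
  )
}

#' Dosage-fraction feature encoding
#'
#' Genotypes divided by sample ploidy, giving values in \[0, 1\] regardless
#' of ploidy (haploid in \{0, 1\}, diploid in \{0, 0.5, 1\}).  This is the
#' common feature encoding used by the classifiers and by PCA, so haploid
#' drones and diploid hybrids live on one scale.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric samples x variants matrix with `NA` for missing calls.
#' @export
dosage <- function(gm) {
  gm$calls / gm$ploidy
}

#' Alternate-allele frequencies
#'
#' Per-variant alternate-allele frequency over a sample subset, computed as
#' the ratio of summed allele counts to summed ploidy over non-missing calls
#' (a missing call contributes to neither sum).  Variants with no non-missing
#' call in the subset get `NA` with a warning.
#'
#' @param gm A `genotype_matrix`.
#' @param sample_subset Sample ids or indices; default all samples.
#' @return Named numeric vector of frequencies in \[0, 1\] (`NA` where
#'   undefined).
#' @export
allele_freq <- function(gm, sample_subset = NULL) {
  if (is.null(sample_subset)) sample_subset <- seq_len(n_samples(gm))
  if (is.character(sample_subset))
    sample_subset <- match(sample_subset, gm$samples$id)
  if (length(sample_subset) == 0 || anyNA(sample_subset))
    abort("empty or unknown sample subset")
  calls <- gm$calls[sample_subset, , drop = FALSE]
  pl <- gm$ploidy[sample_subset]
  obs <- !is.na(calls)
  num <- colSums(calls * obs, na.rm = TRUE)
  den <- colSums(pl * obs)
  p <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(p))
    warn(sprintf("%d variant(s) with all-missing subset: frequency undefined",
                 sum(is.na(p))))
  setNames(p, gm$variants$id)
}

#' Per-sample call rate
#'
#' @param gm A `genotype_matrix`.
#' @return Named numeric vector, fraction of non-missing calls per sample.
#' @export
call_rates <- function(gm) {
  setNames(1 - rowMeans(is.na(gm$calls)), gm$samples$id)
}
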