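#' Site quality-control thresholds
#'
#' Defaults follow the standard drone-sequencing QC recipe: a site is
#' dropped when heterozygous calls are seen in more than 1% of samples
#' (haploid samples cannot be truly heterozygous, so such calls flag
#' repeats or copy-number variation), when more than 5% of genotypes are
#' missing, or when four or more alleles are observed.
#'
#' @param max_het_frac Maximum tolerated fraction of het calls per site.
#' @param max_missing Maximum tolerated missing-genotype fraction per site.
#' @param max_alleles Sites with this many or more observed alleles are
#'   dropped (exclusive bound: the default keeps bi- and tri-allelic sites).
#' @param maf_min Minor-allele-frequency floor used by [ld_prune()].
#' @return A list of thresholds, class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_het_frac = 0.01, max_missing = 0.05,
                          max_alleles = 4L, maf_min = 0.01) {
  stopifnot(max_het_frac >= 0, max_het_frac <= 1,
            max_missing >= 0, max_missing <= 1,
            maf_min >= 0, maf_min <= 1, max_alleles >= 2)
  structure(list(max_het_frac = max_het_frac, max_missing = max_missing,
                 max_alleles = as.integer(max_alleles), maf_min = maf_min),
            class = "qc_thresholds")
}

#' Site quality control
#'
#' Drops variants failing the het-fraction, missingness or allele-number
#' filters and reports per-filter removal counts.  The het fraction is the
#' het count recorded at read time divided by the number of samples.
#'
#' @param gm A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @return List with `gm` (filtered matrix) and `report`, a tibble of
#'   per-filter counts (a site failing several filters appears in each
#'   count; `total_removed` is the union).
#' @export
site_qc <- function(gm, thr = qc_thresholds()) {
  n <- n_samples(gm)
  het_frac <- gm$het_counts / n
  miss_frac <- colMeans(is.na(gm$calls))
  n_alleles <- gm$variants$n_alleles
  fail_het <- het_frac > thr$max_het_frac
  fail_miss <- miss_frac > thr$max_missing
  fail_allele <- n_alleles >= thr$max_alleles
  drop <- fail_het | fail_miss | fail_allele
  report <- tibble(
    filter = c("het_frac", "missing_frac", "n_alleles", "total_removed",
               "retained"),
    n = c(sum(fail_het), sum(fail_miss), sum(fail_allele), sum(drop),
          sum(!drop))
  )
  if (all(drop)) warn("site_qc removed every variant")
  list(gm = gm[, !drop], report = report)
}

#' Sample quality control
#'
#' Drops samples whose call rate falls below `min_call_rate` and refreshes
#' the stored call rates on the retained data.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Retention threshold on the fraction of non-missing
#'   calls (default 0.90).
#' @return The filtered `genotype_matrix`.
#' @export
sample_qc <- function(gm, min_call_rate = 0.90) {
  cr <- call_rates(gm)
  keep <- cr >= min_call_rate
  out <- gm[keep, ]
  out$samples$call_rate <- unname(call_rates(out))
  out
}
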