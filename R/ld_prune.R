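#' PLINK-style windowed LD pruning
#'
#' Removes low-MAF variants, then slides windows of `window_n` SNPs per
#' chromosome (advancing by `ceiling(window_n * (1 - overlap_frac))` so
#' consecutive windows overlap by about `overlap_frac`).  Within each window
#' every pair of still-retained variants whose squared Pearson correlation of
#' dosage fractions (pairwise-complete over samples) exceeds `r2_max` loses
#' its lower-MAF member (tie: the variant with the larger index, i.e. further
#' along the chromosome, is dropped).  After a window is processed no
#' retained pair inside it exceeds `r2_max`.
#'
#' @param gm A [genotype_matrix()] with variants sorted by chrom, pos.
#' @param window_n Window size in SNPs (default 1749, the window that covers
#'   about 100 kb at the SNP density of a dense drone panel).
#' @param overlap_frac Fractional overlap between consecutive windows
#'   (default 0.10).
#' @param r2_max Squared-correlation threshold (default 0.30).
#' @param maf_min Minor-allele-frequency floor applied first (default 0.01).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(gm, window_n = 1749, overlap_frac = 0.10,
                     r2_max = 0.30, maf_min = 0.01) {
  if (window_n < 2) abort("`window_n` must be at least 2")
  v <- gm$variants
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v))))
    abort("variants must be sorted by chrom, pos before pruning")
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  alive <- !is.na(maf) & maf >= maf_min
  X <- dosage(gm)
  step <- max(1L, as.integer(ceiling(window_n * (1 - overlap_frac))))

  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    m <- length(idx)
    starts <- seq(1L, m, by = step)
    for (st in starts) {
      win <- idx[st:min(st + window_n - 1L, m)]
      win <- win[alive[win]]
      if (length(win) < 2) next
      alive[win] <- prune_window(X[, win, drop = FALSE], maf[win], r2_max)
    }
  }
  v$id[alive]
}

# Greedy within-window pass: examine pairs in index order; when both members
# are still alive and r2 > r2_max, drop the lower-MAF member (tie: the later
# variant).  Returns the keep mask for the window's columns.
prune_window <- function(Xw, mafw, r2_max) {
  r <- fast_cor(Xw)
  r2 <- r * r
  w <- ncol(Xw)
  keep <- rep(TRUE, w)
  hits <- which(upper.tri(r2) & r2 > r2_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(keep)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  for (h in seq_len(nrow(hits))) {
    i <- hits[h, 1]; j <- hits[h, 2]
    if (!keep[i] || !keep[j]) next
    drop <- if (mafw[i] < mafw[j]) i else j   # tie -> j (larger index)
    keep[drop] <- FALSE
  }
  keep
}

# Pearson correlation with a BLAS fast path when there is no missing data.
fast_cor <- function(X) {
  if (anyNA(X)) {
    suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  } else {
    suppressWarnings(cor(X))
  }
}

# Called in tests as the O(n^2) oracle: re-enumerates the sliding windows
# independently and checks every retained pair inside each window against
# r2_max.  Returns offending pairs (empty tibble when clean).
check_ld_oracle <- function(gm, retained_ids, window_n, overlap_frac,
                            r2_max) {
  v <- gm$variants
  X <- dosage(gm)
  step <- max(1L, as.integer(ceiling(window_n * (1 - overlap_frac))))
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    m <- length(idx)
    for (st in seq(1L, m, by = step)) {
      win <- idx[st:min(st + window_n - 1L, m)]
      win <- win[v$id[win] %in% retained_ids]
      if (length(win) < 2) next
      r2 <- fast_cor(X[, win, drop = FALSE])^2
      bad <- which(upper.tri(r2) & !is.na(r2) & r2 > r2_max, arr.ind = TRUE)
      if (nrow(bad) > 0)
        out[[length(out) + 1]] <- tibble(id1 = v$id[win[bad[, 1]]],
                                         id2 = v$id[win[bad[, 2]]],
                                         r2 = r2[bad])
    }
  }
  if (length(out) == 0) tibble(id1 = character(), id2 = character(),
                               r2 = numeric())
  else dplyr::distinct(bind_rows(out))
}
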