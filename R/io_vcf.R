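#' Read genotypes from a minimal VCF plus a sample-metadata table
#'
#' Parses a VCF v4.2 subset (GT required; haploid genotypes written as a
#' single allele, diploid as `a/b`) via \pkg{vcfR} and joins the tab-delimited
#' sample metadata.  `./.` and `.` become missing.  A heterozygous call in a
#' haploid sample increments that variant's het count and is stored missing:
#' such calls arise from e.g. copy-number variation or short tandem repeats
#' and are handled as site-level QC signal.
#'
#' @param path VCF file path (plain text).
#' @param meta_path Tab-delimited metadata with header
#'   `id, group, subspecies, latitude, longitude, altitude` (extra columns,
#'   including `ploidy`, are kept).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, meta_path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")   # variants x samples
  if (is.null(gt)) abort("VCF has no GT field")
  fix <- vcf@fix
  n_alt <- ifelse(is.na(fix[, "ALT"]), 0L,
                  lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE)))
  variants <- tibble(
    chrom = as.integer(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    n_alleles = n_alt + 1L
  )
  sample_ids <- colnames(gt)
  missing_meta <- setdiff(sample_ids, meta$id)
  if (length(missing_meta) > 0)
    abort(paste0("sample(s) in VCF absent from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  meta <- meta[match(sample_ids, meta$id), , drop = FALSE]

  # Ploidy: explicit metadata column wins; otherwise infer per sample from
  # the majority GT shape (artifact het calls are rare, so a haploid sample
  # stays haploid under majority vote).
  has_sep <- function(v) grepl("[/|]", v)
  if ("ploidy" %in% names(meta)) {
    ploidy <- as.integer(meta$ploidy)
  } else {
    frac_dip <- colMeans(matrix(has_sep(gt) & !is.na(gt), nrow = nrow(gt)))
    frac_obs <- colMeans(matrix(!is.na(gt) & gt != ".", nrow = nrow(gt)))
    ploidy <- ifelse(frac_obs > 0 & frac_dip / pmax(frac_obs, 1e-12) > 0.5,
                     2L, 1L)
  }

  n_var <- nrow(variants)
  n_smp <- length(sample_ids)
  calls <- matrix(NA_integer_, nrow = n_smp, ncol = n_var)
  het_counts <- integer(n_var)
  for (s in seq_len(n_smp)) {
    g <- gt[, s]
    g[is.na(g) | g == "." | g == "./." | g == ".|."] <- NA
    parts <- strsplit(ifelse(is.na(g), "", g), "[/|]")
    len <- lengths(parts)
    bad <- which(!is.na(g) & (len < 1 | len > 2))
    if (length(bad) > 0)
      abort(sprintf("malformed GT '%s' at VCF record %d (sample %s)",
                    g[bad[1]], bad[1], sample_ids[s]))
    a1 <- suppressWarnings(as.integer(vapply(parts, function(x)
      if (length(x) >= 1) x[1] else NA_character_, character(1))))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(x)
      if (length(x) == 2) x[2] else NA_character_, character(1))))
    bad <- which(!is.na(g) & is.na(a1))
    if (length(bad) > 0)
      abort(sprintf("malformed GT '%s' at VCF record %d (sample %s)",
                    g[bad[1]], bad[1], sample_ids[s]))
    partial <- which(!is.na(a1) & len == 2 & is.na(a2))
    if (length(partial) > 0) a1[partial] <- NA   # e.g. "0/." -> missing
    if (ploidy[s] == 1L) {
      val <- pmin(a1, 1L)
      dip <- which(!is.na(a1) & !is.na(a2))
      het <- dip[a1[dip] != a2[dip]]
      het_counts[het] <- het_counts[het] + 1L
      val[het] <- NA_integer_
      hom_dip <- setdiff(dip, het)
      val[hom_dip] <- pmin(a1[hom_dip], 1L)   # "1/1" in a haploid -> 1
      calls[s, ] <- val
    } else {
      one_allele <- which(!is.na(a1) & len == 1)
      a2[one_allele] <- a1[one_allele]
      calls[s, ] <- pmin(a1, 1L) + pmin(a2, 1L)
    }
  }

  samples <- meta
  gm <- genotype_matrix(calls, variants, samples, ploidy, het_counts)
  gm$samples$call_rate <- unname(call_rates(gm))
  gm
}

#' Write genotypes to a minimal VCF plus a sample-metadata table
#'
#' Inverse of [read_genotypes()]: a plain-text VCF v4.2 subset (haploid
#' samples written as single-allele GT, diploid as unphased `a/b`) and a
#' tab-delimited metadata file.  The round trip `read(write(gm))` restores
#' the genotype calls, ploidy and metadata exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output VCF path.
#' @param meta_path Output metadata path; default replaces the VCF extension
#'   with `.meta.tsv`.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gm, path,
                            meta_path = sub("\\.vcf$", ".meta.tsv", path)) {
  v <- gm$variants
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", sort(unique(v$chrom))),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$id), collapse = "\t")
  )
  gt_char <- matrix("", nrow = n_samples(gm), ncol = n_variants(gm))
  for (s in seq_len(n_samples(gm))) {
    cl <- gm$calls[s, ]
    if (gm$ploidy[s] == 1L) {
      gt_char[s, ] <- ifelse(is.na(cl), ".", as.character(cl))
    } else {
      gt_char[s, ] <- dplyr::case_when(
        is.na(cl) ~ "./.",
        cl == 0L ~ "0/0",
        cl == 1L ~ "0/1",
        TRUE ~ "1/1"
      )
    }
  }
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    sep = "\t"
  )
  if (n_samples(gm) > 0)
    body <- paste(body, apply(gt_char, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)

  meta <- gm$samples
  meta$ploidy <- gm$ploidy
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(path)
}
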