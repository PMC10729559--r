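#' Synthetic population model
#'
#' Parameters of the Balding-Nichols generator that emulates the statistical
#' structure the downstream analyses assume: three differentiated source
#' populations (an Algerian population ALG and two European lineages M and
#' C), a within-Algeria East-West allele-frequency cline correlated with
#' longitude, and configurable per-site missingness and heterozygote-artifact
#' rates.
#'
#' Each population's allele frequency drifts from a shared ancestral
#' frequency `p` as `Beta(p (1-F)/F, (1-p) (1-F)/F)`; the two Algerian
#' sub-backgrounds (West/East) drift from ALG with a much smaller F.  An
#' Algerian sample's genotype is drawn from the mixture frequency
#' `a p_E + (1-a) p_W` where its eastern-ancestry fraction `a` follows a
#' logistic cline in longitude.
#'
#' @param n_variants Number of SNPs to simulate.
#' @param chrom_lengths Chromosome lengths in bp (default 16 x 14 Mb).
#' @param ancestral_range Range of the uniform ancestral-frequency law.
#' @param fst_lineage Drift of ALG, M and C from the ancestor.
#' @param fst_intra_alg Drift of the West/East Algerian backgrounds from ALG.
#' @param cline_steepness Logistic slope (per degree longitude) of eastern
#'   ancestry.
#' @param lon_range,lat_range Sampling-area extent in decimal degrees.
#' @param alt_lat_cor Target correlation between altitude and latitude
#'   (negative: the southernmost sites are the highest).
#' @param n_train,n_test Named sample sizes (`ALG`, `M`, `C`) for the two
#'   dataset splits; defaults follow the reference study layout (82/50/118
#'   training, 20/13/30 test).
#' @param n_O Optional O-lineage reference samples (off by default).
#' @param missing_rate Per-call missingness probability.
#' @param het_artifact_rate Probability a haploid call is recorded as a
#'   heterozygote (QC signal; such calls are stored missing).
#' @param seed Integer seed; every generator below is deterministic in it.
#' @return A list of class `pop_model`.
#' @export
pop_model <- function(n_variants = 5000,
                      chrom_lengths = rep(14e6, 16),
                      ancestral_range = c(0.05, 0.95),
                      fst_lineage = 0.12,
                      fst_intra_alg = 0.02,
                      cline_steepness = 1.0,
                      lon_range = c(-1, 8),
                      lat_range = c(28, 37),
                      alt_lat_cor = -0.6,
                      n_train = c(ALG = 82, M = 50, C = 118),
                      n_test = c(ALG = 20, M = 13, C = 30),
                      n_O = 0,
                      missing_rate = 0,
                      het_artifact_rate = 0,
                      seed = 1L) {
  stopifnot(fst_lineage > 0, fst_lineage < 1,
            fst_intra_alg >= 0, fst_intra_alg < 1,
            alt_lat_cor > -1, alt_lat_cor < 1,
            all(n_train >= 0), all(n_test >= 0),
            missing_rate >= 0, missing_rate <= 1,
            het_artifact_rate >= 0, het_artifact_rate <= 1)
  structure(as.list(environment()), class = "pop_model")
}

# Balding-Nichols draw of daughter frequencies from parent frequencies.
bn_drift <- function(p, fst) {
  if (fst == 0) return(p)
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Draw variant positions and per-population allele frequencies
#'
#' @param model A [pop_model()].
#' @param seed Override of the model seed.
#' @return List with `variants` (tibble: chrom, pos, id, ref, alt) and
#'   `freqs`, an `n_variants x 5` matrix with columns ALG, M, C, ALG_W,
#'   ALG_E.
#' @export
draw_freqs <- function(model, seed = model$seed) {
  set.seed(derive_seed(seed, 1L))
  L <- model$chrom_lengths
  n <- model$n_variants
  chrom <- sort(sample(seq_along(L), n, replace = TRUE, prob = L / sum(L)))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(ix) {
    sort(sample.int(L[chrom[ix[1]]], length(ix)))
  }), use.names = FALSE)
  variants <- tibble(
    chrom = as.integer(chrom), pos = as.integer(pos),
    id = sprintf("snp%05d", seq_len(n)),
    ref = "A", alt = "T", n_alleles = 2L
  )
  p_anc <- runif(n, model$ancestral_range[1], model$ancestral_range[2])
  freqs <- cbind(
    ALG = bn_drift(p_anc, model$fst_lineage),
    M = bn_drift(p_anc, model$fst_lineage),
    C = bn_drift(p_anc, model$fst_lineage)
  )
  freqs <- cbind(freqs,
                 ALG_W = bn_drift(freqs[, "ALG"], model$fst_intra_alg),
                 ALG_E = bn_drift(freqs[, "ALG"], model$fst_intra_alg))
  list(variants = variants, freqs = freqs, p_anc = p_anc)
}

#' Draw one haploid drone genotype from per-site allele frequencies
#'
#' @param p Per-site alternate-allele frequencies.
#' @return Integer vector of 0/1 calls.
#' @export
simulate_drone <- function(p) {
  rbinom(length(p), 1L, p)
}

#' Assign geographic coordinates and cline ancestry
#'
#' Algerian samples receive a longitude uniform over the sampling range, an
#' eastern-ancestry fraction following the logistic cline, a latitude
#' uniform over the range, and an altitude anti-correlated with latitude at
#' the configured coefficient.  European reference samples get fixed
#' per-lineage coordinates with small jitter.
#'
#' @param groups Character vector of group labels (`ALG`, `M`, `C`, `O`).
#' @param model A [pop_model()].
#' @param seed Override of the model seed.
#' @return Tibble with latitude, longitude, altitude and (for ALG)
#'   `ancestry_e`, the true eastern-ancestry fraction.
#' @export
assign_geography <- function(groups, model, seed = model$seed) {
  set.seed(derive_seed(seed, 2L))
  n <- length(groups)
  lon <- lat <- alt <- anc <- rep(NA_real_, n)
  is_alg <- groups == "ALG"
  n_alg <- sum(is_alg)
  if (n_alg > 0) {
    lon[is_alg] <- runif(n_alg, model$lon_range[1], model$lon_range[2])
    mid <- mean(model$lon_range)
    anc[is_alg] <- stats::plogis(model$cline_steepness * (lon[is_alg] - mid))
    lat[is_alg] <- runif(n_alg, model$lat_range[1], model$lat_range[2])
    z_lat <- scale(lat[is_alg])[, 1]
    r <- model$alt_lat_cor
    z_alt <- r * z_lat + sqrt(1 - r^2) * rnorm(n_alg)
    alt[is_alg] <- 800 + 400 * z_alt
  }
  ref_coord <- list(M = c(46, -1), C = c(45.5, 12), O = c(42, 43))
  for (g in names(ref_coord)) {
    ix <- which(groups == g)
    if (length(ix) > 0) {
      lat[ix] <- ref_coord[[g]][1] + rnorm(length(ix), 0, 0.5)
      lon[ix] <- ref_coord[[g]][2] + rnorm(length(ix), 0, 0.5)
      alt[ix] <- pmax(0, rnorm(length(ix), 300, 100))
    }
  }
  tibble(latitude = lat, longitude = lon, altitude = alt, ancestry_e = anc)
}

#' Generate a full synthetic dataset
#'
#' Draws frequencies, geography and genotypes for the training and test
#' splits, applies the configured missingness and heterozygote-artifact
#' rates, and returns the genotype matrix together with truth tables
#' sufficient to score every downstream stage.  With `out_dir` set, also
#' writes the VCF, the metadata TSV and the truth TSVs.
#'
#' @param model A [pop_model()].
#' @param out_dir Optional output directory.
#' @return List with `gm` (a [genotype_matrix()]; `samples` carries `group`,
#'   `split`, coordinates), `truth` (list: `ancestry` tibble, `freqs`
#'   matrix, `variants`), and `model`.
#' @export
generate_dataset <- function(model = pop_model(), out_dir = NULL) {
  fr <- draw_freqs(model)
  groups <- c(
    rep(names(model$n_train), model$n_train),
    rep(names(model$n_test), model$n_test),
    rep("O", model$n_O)
  )
  split <- c(
    rep("train", sum(model$n_train)),
    rep("test", sum(model$n_test)),
    rep("train", model$n_O)
  )
  geo <- assign_geography(groups, model)
  n <- length(groups)
  ids <- sprintf("%s_%s_%03d", groups, split, seq_len(n))

  set.seed(derive_seed(model$seed, 3L))
  calls <- matrix(NA_integer_, nrow = n, ncol = model$n_variants)
  for (i in seq_len(n)) {
    p <- switch(groups[i],
      ALG = geo$ancestry_e[i] * fr$freqs[, "ALG_E"] +
        (1 - geo$ancestry_e[i]) * fr$freqs[, "ALG_W"],
      M = fr$freqs[, "M"],
      C = fr$freqs[, "C"],
      O = fr$p_anc
    )
    calls[i, ] <- simulate_drone(p)
  }
  het_counts <- integer(model$n_variants)
  if (model$het_artifact_rate > 0) {
    hets <- matrix(runif(n * model$n_variants) < model$het_artifact_rate,
                   nrow = n)
    het_counts <- as.integer(colSums(hets))
    calls[hets] <- NA_integer_
  }
  if (model$missing_rate > 0) {
    miss <- matrix(runif(n * model$n_variants) < model$missing_rate,
                   nrow = n)
    calls[miss] <- NA_integer_
  }

  samples <- tibble(
    id = ids, group = groups, split = split,
    subspecies = ifelse(groups == "ALG",
                        ifelse(geo$latitude < mean(model$lat_range),
                               "sahariensis", "intermissa"),
                        groups),
    latitude = geo$latitude, longitude = geo$longitude,
    altitude = geo$altitude
  )
  gm <- genotype_matrix(calls, fr$variants, samples,
                        ploidy = rep(1L, n), het_counts = het_counts)
  gm$samples$call_rate <- unname(call_rates(gm))
  truth <- list(
    ancestry = tibble(id = ids, group = groups, split = split,
                      ancestry_e = geo$ancestry_e),
    freqs = fr$freqs,
    variants = fr$variants
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(gm, file.path(out_dir, "genotypes.vcf"),
                    file.path(out_dir, "samples.meta.tsv"))
    readr::write_tsv(truth$ancestry, file.path(out_dir, "truth_ancestry.tsv"),
                     progress = FALSE)
    readr::write_tsv(
      dplyr::bind_cols(truth$variants,
                       as_tibble(as.data.frame(truth$freqs))),
      file.path(out_dir, "truth_freqs.tsv"), progress = FALSE)
  }
  list(gm = gm, truth = truth, model = model)
}
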