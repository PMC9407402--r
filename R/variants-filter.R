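#' Filter SNPs on biallelic state, missingness and minor allele frequency
#'
#' A record is kept when (in this order of reporting):
#' * it is a biallelic SNP — single-base `ref` and single-base `alt`
#'   (multiallelic records and indels are removed when
#'   `biallelic_only = TRUE`);
#' * its missing-genotype fraction is strictly below
#'   `max_missing_fraction` (default 0.8: sites missing in at least 80%
#'   of accessions are removed);
#' * its minor allele frequency is at least `maf_min` (default 0.05: only
#'   sites with MAF *below* 0.05 are removed). MAF is computed over called
#'   alleles only; genotypes containing a missing allele are excluded from
#'   both numerator and denominator.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param maf_min Minimum minor allele frequency.
#' @param max_missing_fraction Missingness threshold.
#' @param biallelic_only Drop multiallelic/indel records.
#' @return The kept rows, with a `"removal_log"` attribute: a tibble of
#'   `contig`, `pos`, `ref`, `alt`, `reason` for every removed record.
#' @export
filter_variants <- function(variants, maf_min = 0.05,
                            max_missing_fraction = 0.8,
                            biallelic_only = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) abort("maf_min must be in [0, 0.5]")
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    abort("max_missing_fraction must be in [0, 1]")
  }
  samples <- vcf_samples(variants)
  if (length(samples) == 0L) abort("variant table has no sample columns")
  gt <- as.matrix(variants[, samples, drop = FALSE])

  is_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    !grepl(",", variants$alt)
  miss <- matrix(grepl("\\.", gt), nrow = nrow(gt))
  miss_frac <- rowMeans(miss)
  alt_cnt <- rowSums(matrix(gt_dosage(gt), nrow = nrow(gt)), na.rm = TRUE)
  called <- rowSums(!miss)
  maf <- ifelse(called > 0,
                pmin(alt_cnt / (2 * called), 1 - alt_cnt / (2 * called)),
                0)

  reason <- rep(NA_character_, nrow(variants))
  if (biallelic_only) reason[!is_snp] <- "not a biallelic SNP"
  need <- is.na(reason) & miss_frac >= max_missing_fraction
  reason[need] <- sprintf("missing fraction %.2f >= %.2f",
                          miss_frac[need], max_missing_fraction)
  need <- is.na(reason) & maf < maf_min
  reason[need] <- sprintf("MAF %.4f < %.2f", maf[need], maf_min)

  kept <- variants[is.na(reason), , drop = FALSE]
  log <- tibble(contig = variants$contig, pos = variants$pos,
                ref = variants$ref, alt = variants$alt,
                reason = reason)[!is.na(reason), , drop = FALSE]
  attr(kept, "removal_log") <- log
  kept
}

#' Allele-sharing SNP distance matrix
#'
#' For each accession pair, the distance at one biallelic site is half the
#' absolute difference of their alt-allele dosages (so identical genotypes
#' contribute 0, a het against a hom contributes 0.5, opposite homozygotes
#' contribute 1), averaged over the sites at which both genotypes are
#' called. Pairs with no co-called site get the maximal distance 1 with a
#' warning.
#'
#' @param variants Filtered, biallelic variant tibble.
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   accession.
#' @export
snp_distance_matrix <- function(variants) {
  samples <- vcf_samples(variants)
  if (length(samples) < 2L) abort("need at least 2 accessions")
  gt <- as.matrix(variants[, samples, drop = FALSE])
  dos <- matrix(gt_dosage(gt), nrow = nrow(gt),
                dimnames = list(NULL, samples))
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, j])
      if (!any(ok)) {
        warn(sprintf("no co-called site for %s vs %s; distance set to 1",
                     samples[i], samples[j]))
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- mean(abs(dos[ok, i] - dos[ok, j]) / 2)
      }
    }
  }
  d
}
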