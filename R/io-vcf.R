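#' Read a multi-sample VCF into a variant table
#'
#' Variants are returned one row per record with fixed columns `contig`,
#' `pos`, `id`, `ref`, `alt` followed by one genotype column per sample
#' (diploid GT strings such as `"0/1"`; missing calls are normalised to
#' `"./."`). Multiallelic records are parsed as-is with a comma-separated
#' `alt`; removing them is the job of [filter_variants()], not the reader.
#'
#' @param path VCF file (plain or gzipped).
#' @return Variant tibble.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(gt) && nrow(fix) != nrow(gt)) {
    abort("sample genotype rows do not match VCF records")
  }
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  bad <- !grepl("^(\\.|[0-9]+)/(\\.|[0-9]+)$", gt)
  if (any(bad)) {
    abort(sprintf("malformed GT field(s), e.g. '%s'", gt[which(bad)[1]]))
  }
  out <- tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF,
    alt = fix$ALT
  )
  bind_cols_gt(out, gt)
}

bind_cols_gt <- function(fixed, gt) {
  gt_tbl <- as_tibble(as.data.frame(gt, stringsAsFactors = FALSE))
  dplyr::bind_cols(fixed, gt_tbl)
}

#' Sample (accession) names of a variant table
#'
#' @param variants Variant tibble from [read_vcf()].
#' @return Character vector of sample column names.
#' @export
vcf_samples <- function(variants) {
  setdiff(names(variants), c("contig", "pos", "id", "ref", "alt"))
}

#' Write a variant table to VCF
#'
#' Output is gzip-compressed VCF 4.2 (a `.gz` suffix is appended when
#' absent). Round-trips with [read_vcf()]: positions, alleles and genotypes
#' are preserved.
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return The actual path written, invisibly.
#' @export
write_vcf <- function(variants, path) {
  assert_cols(variants, c("contig", "pos", "ref", "alt"), "variants")
  samples <- vcf_samples(variants)
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  fix <- cbind(
    CHROM = variants$contig,
    POS = as.character(variants$pos),
    ID = if ("id" %in% names(variants)) variants$id else ".",
    REF = variants$ref, ALT = variants$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  gt <- cbind(FORMAT = "GT",
              as.matrix(variants[, samples, drop = FALSE]))
  meta <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

# --- genotype helpers (biallelic, diploid) ---------------------------------

# alt-allele dosage 0/1/2; NA when either allele is missing
gt_dosage <- function(gt) {
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0")] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% c("1/1")] <- 2L
  d
}

gt_called <- function(gt) !grepl("\\.", gt)

gt_has_alt <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) any(a != "." & a != "0"), logical(1))
}
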