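# Plain-text readers and writers for every bundle artifact. All formats are
# uncompressed text so a bundle can be inspected, versioned and regenerated
# byte-identically from the same configuration.

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write somatic variant records as a VCFv4.2 file
#'
#' Records are sorted by chromosome and position. Tumor/normal support is
#' carried in INFO keys `SAMPLE`, `DP_T`, `DP_N`, `AD_T`, `VAF_T`, `VAF_N`,
#' `STRANDS` (number of strands supporting the call; 2 means both) and, when
#' present, `GENE` and `PATH` (pathogenic flag).
#'
#' @param variants data.frame as produced by [simulate_variants()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  v <- variants
  chrom_num <- suppressWarnings(as.integer(sub("^chr", "", v$chrom)))
  chrom_num[is.na(chrom_num)] <- 99L
  v <- v[order(chrom_num, v$pos), , drop = FALSE]
  info <- sprintf(
    "SAMPLE=%s;DP_T=%d;DP_N=%d;AD_T=%d;VAF_T=%.8g;VAF_N=%.8g;STRANDS=%d;GENE=%s;PATH=%d",
    v$sample_id, v$dp_tumor, v$dp_normal, v$ad_tumor, v$vaf_tumor,
    v$vaf_normal, ifelse(v$both_strands, 2L, 1L),
    ifelse(v$gene == "", ".", v$gene), as.integer(v$pathogenic))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Tumor sample ID\">",
    "##INFO=<ID=DP_T,Number=1,Type=Integer,Description=\"Tumor depth\">",
    "##INFO=<ID=DP_N,Number=1,Type=Integer,Description=\"Normal depth\">",
    "##INFO=<ID=AD_T,Number=1,Type=Integer,Description=\"Tumor alt reads\">",
    "##INFO=<ID=VAF_T,Number=1,Type=Float,Description=\"Tumor VAF\">",
    "##INFO=<ID=VAF_N,Number=1,Type=Float,Description=\"Normal VAF\">",
    "##INFO=<ID=STRANDS,Number=1,Type=Integer,Description=\"Supporting strands (2 = both)\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PATH,Number=1,Type=Integer,Description=\"Pathogenic flag\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  v$chrom, v$pos, v$ref, v$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a somatic variant VCF written by [write_variants_vcf()]
#'
#' @param path VCF file path.
#' @return data.frame with the same columns as [simulate_variants()] output.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      vaf_tumor = numeric(), vaf_normal = numeric(),
                      dp_tumor = integer(), dp_normal = integer(),
                      ad_tumor = integer(), both_strands = logical(),
                      gene = character(), pathogenic = logical()))
  }
  gene <- vcfR::extract.info(vcf, "GENE")
  data.frame(
    sample_id = vcfR::extract.info(vcf, "SAMPLE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf_tumor = as.numeric(vcfR::extract.info(vcf, "VAF_T")),
    vaf_normal = as.numeric(vcfR::extract.info(vcf, "VAF_N")),
    dp_tumor = as.integer(vcfR::extract.info(vcf, "DP_T")),
    dp_normal = as.integer(vcfR::extract.info(vcf, "DP_N")),
    ad_tumor = as.integer(vcfR::extract.info(vcf, "AD_T")),
    both_strands = as.integer(vcfR::extract.info(vcf, "STRANDS")) == 2L,
    gene = ifelse(is.na(gene) | gene == ".", "", gene),
    pathogenic = as.integer(vcfR::extract.info(vcf, "PATH")) == 1L,
    stringsAsFactors = FALSE
  )
}

write_msi_sites_bed <- function(sites, path) {
  # BED 0-based half-open; name = site_id, score = ref repeat length,
  # extra columns: repeat unit and noncoding flag.
  df <- data.frame(sites$chrom, sites$start, sites$end, sites$site_id,
                   sites$ref_repeat_length, ".", sites$repeat_unit,
                   as.integer(sites$noncoding))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_msi_sites_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(site_id = df$V4, chrom = df$V1, start = df$V2, end = df$V3,
             repeat_unit = df$V7, ref_repeat_length = df$V5,
             noncoding = df$V8 == 1L, stringsAsFactors = FALSE)
}
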