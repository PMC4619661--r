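#' Read a SNP pool table
#'
#' Reads per-SNP pooled allele counts from a TSV file (columns `chrom`,
#' `pos`, `ref`, `alt`, `depth_early`, `alt_early`, `depth_late`,
#' `alt_late`, `parental_alt_freq`, `called_in_both`) or from a VCF 4.x
#' file with two pool samples (`EARLY`, `LATE`) carrying `DP` and `AD`
#' FORMAT fields and the INFO keys `PAF` (parental alternative-allele
#' frequency) and `CB` (flag: called in both pools).  Positions are 1-based
#' in both formats and are kept 1-based throughout the package; only BED
#' output is 0-based.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A SNP pool `data.frame` (see [pool_and_count()] for columns).
#' @export
read_snp_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "tsv") read_snp_tsv(path) else read_snp_vcf(path)
}

snp_table_columns <- c("chrom", "pos", "ref", "alt",
                       "depth_early", "alt_early", "depth_late", "alt_late",
                       "parental_alt_freq", "called_in_both")

read_snp_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(snp_table_columns, names(tab))
  if (length(missing)) {
    stop("SNP TSV ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$called_in_both <- as.logical(tab$called_in_both)
  bad <- which(!is.finite(tab$pos) | tab$depth_early < tab$alt_early |
                 tab$depth_late < tab$alt_late)
  if (length(bad)) {
    stop("malformed SNP rows (data lines ", paste(bad, collapse = ", "),
         "): alt count exceeds depth or bad position", call. = FALSE)
  }
  tab
}

#' Write a SNP pool table as TSV
#'
#' @param tab SNP pool table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(tab, path) {
  check_snp_table(tab)
  cols <- intersect(c(snp_table_columns, "p_early", "p_late"), names(tab))
  write.table(tab[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a SNP pool table as VCF 4.2
#'
#' Emits one record per SNP with two samples (`EARLY`, `LATE`), FORMAT
#' `DP:AD` (`AD` = reference,alternative depths), and INFO keys `PAF`
#' (parental alternative-allele frequency) and the flag `CB` (called in
#' both pools).  Positions are written 1-based, as the format requires.
#'
#' @inheritParams write_snp_tsv
#' @export
write_snp_vcf <- function(tab, path) {
  check_snp_table(tab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepmap",
    paste0("##INFO=<ID=PAF,Number=1,Type=Float,Description=",
           "\"Alternative allele frequency in the alternative parent\">"),
    paste0("##INFO=<ID=CB,Number=0,Type=Flag,Description=",
           "\"Variant called in both pools\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "EARLY", "LATE"), collapse = "\t")), con)
  info <- paste0("PAF=", format(tab$parental_alt_freq, trim = TRUE),
                 ifelse(tab$called_in_both, ";CB", ""))
  early <- sprintf("%d:%d,%d", tab$depth_early,
                   tab$depth_early - tab$alt_early, tab$alt_early)
  late <- sprintf("%d:%d,%d", tab$depth_late,
                  tab$depth_late - tab$alt_late, tab$alt_late)
  writeLines(paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".", "PASS",
                   info, "DP:AD", early, late, sep = "\t"), con)
  invisible(path)
}

read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!all(c("EARLY", "LATE") %in% colnames(vcf@gt)[-1L])) {
    stop("VCF must contain the pool samples EARLY and LATE", call. = FALSE)
  }
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  if (all(is.na(dp)) || all(is.na(ad))) {
    stop("VCF FORMAT fields DP and AD are required", call. = FALSE)
  }
  bad <- which(is.na(dp[, "EARLY"]) | is.na(dp[, "LATE"]) |
                 is.na(ad[, "EARLY"]) | is.na(ad[, "LATE"]))
  if (length(bad)) {
    stop("VCF records missing DP/AD at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  alt_of <- function(x) as.integer(vapply(strsplit(x, ","),
                                          function(v) v[2L], character(1)))
  paf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "PAF")))
  cb <- grepl("(^|;)CB($|;)", fix$INFO)
  data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             depth_early = as.integer(dp[, "EARLY"]),
             alt_early = alt_of(ad[, "EARLY"]),
             depth_late = as.integer(dp[, "LATE"]),
             alt_late = alt_of(ad[, "LATE"]),
             parental_alt_freq = ifelse(is.na(paf), 1, paf),
             called_in_both = cb)
}
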