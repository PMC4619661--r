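#' Write simulated reads as FASTQ
#'
#' Phred+33 encoding with a constant quality character (the simulator does
#' not model quality scores).
#'
#' @param reads A data.frame with `read_id` and `seq` (e.g. from
#'   [simulate_breakpoint_reads()]), a named character vector, or a
#'   `DNAStringSet`.
#' @param path Output path.
#' @param quality Constant quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  df <- read_input_to_df(reads)
  seqs <- Biostrings::DNAStringSet(df$seq)
  names(seqs) <- df$read_id
  quals <- Biostrings::BStringSet(vapply(nchar(df$seq), function(n)
    strrep(quality, n), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path.
#' @return A `data.frame` with columns `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(seqs), seq = as.character(seqs))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a per-nucleotide coverage vector as bedGraph
#'
#' Runs of equal coverage are collapsed into bedGraph intervals (0-based,
#' half-open, as the format requires).
#'
#' @param counts Numeric per-nucleotide coverage, position 1 = `start`.
#' @param path Output path.
#' @param chrom Chromosome/sequence name.
#' @param start 1-based position of `counts[1]` on `chrom`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(counts, path, chrom = "gene", start = 1) {
  r <- rle(as.numeric(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + starts - 1,
                                                start + ends - 1),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a per-nucleotide coverage vector
#'
#' @param path bedGraph path.
#' @return A numeric vector covering positions 1..max(end); positions not
#'   covered by any interval are 0.  The chromosome of the first record is
#'   used.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) return(numeric())
  gr <- gr[GenomicRanges::seqnames(gr) == as.character(
    GenomicRanges::seqnames(gr))[1L]]
  out <- numeric(max(GenomicRanges::end(gr)))
  for (i in seq_along(gr)) {
    out[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      gr$score[i]
  }
  out
}

#' Write mapping intervals as BED
#'
#' BED is 0-based, half-open; the package's interval representation already
#' uses that convention, so coordinates are written as-is.  The name field
#' records the peak position and peak delta-f.
#'
#' @param intervals Interval `data.frame` from [call_mapping_interval()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#chrom", "start", "end", "name", "score", sep = "\t"),
             con)
  if (nrow(intervals)) {
    writeLines(paste(intervals$chrom,
                     format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE),
                     sprintf("peak_pos=%s;peak_delta=%.4f",
                             format(intervals$peak_pos, scientific = FALSE,
                                    trim = TRUE),
                             intervals$peak_delta),
                     format(round(1000 * pmin(pmax(intervals$peak_delta, 0),
                                              1)), trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Extracts the exons of one gene from a GFF3 annotation and converts them
#' to gene-local coordinates oriented 5' to 3' of the gene (minus-strand
#' genes are flipped).
#'
#' @param path GFF3 path.
#' @param gene_id Gene to extract; exons are matched by their `Parent` or
#'   `gene_id`/`ID` attributes containing this identifier.  Default: the
#'   only gene present.
#' @return A [gene_model()].
#' @export
read_gene_model_gff3 <- function(path, gene_id = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) stop("no exon features in ", path, call. = FALSE)
  parent <- vapply(as.list(ex$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  parent <- sub("\\.\\d+$", "", sub("^(transcript|mRNA|gene):", "", parent))
  if (is.null(gene_id)) {
    gene_id <- unique(parent)
    if (length(gene_id) != 1L) {
      stop("multiple genes in GFF3; supply gene_id", call. = FALSE)
    }
  } else {
    ex <- ex[grepl(gene_id, parent, fixed = TRUE)]
    if (!length(ex)) stop("gene ", gene_id, " not found", call. = FALSE)
  }
  strand <- as.character(GenomicRanges::strand(ex))[1L]
  gstart <- min(GenomicRanges::start(ex))
  gend <- max(GenomicRanges::end(ex))
  if (strand == "-") {
    loc_start <- gend - GenomicRanges::end(ex) + 1
    loc_end <- gend - GenomicRanges::start(ex) + 1
  } else {
    loc_start <- GenomicRanges::start(ex) - gstart + 1
    loc_end <- GenomicRanges::end(ex) - gstart + 1
  }
  ord <- order(loc_start)
  gene_model(gene_id,
             data.frame(start = loc_start[ord], end = loc_end[ord]),
             chrom = as.character(GenomicRanges::seqnames(ex))[1L],
             strand = strand)
}

#' Read a qRT-PCR Ct table from TSV
#'
#' @param path TSV with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference_gene,calibrator Recorded as attributes for
#'   [ddct_relative_expression()].
#' @return The Ct `data.frame`.
#' @export
read_ct_table <- function(path, reference_gene = "ACT8", calibrator = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("Ct table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(tab$ct))) stop("non-finite Ct values", call. = FALSE)
  attr(tab, "reference_gene") <- reference_gene
  attr(tab, "calibrator") <- calibrator
  tab
}
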