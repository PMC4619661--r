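#' Build breakpoint junction targets for a known insertion
#'
#' Extracts the two junction reference sequences used to detect an insertion
#' from short reads: each target splices `flank` bases of genomic sequence
#' onto `flank` bases of the insertion end, so that reads spanning a
#' breakpoint of the insertion-bearing allele map contiguously onto exactly
#' one target.
#'
#' `insertion_pos` counts the reference bases 5' of the insertion: the
#' insertion sits between `ref_seq[insertion_pos]` and
#' `ref_seq[insertion_pos + 1]` (1-based).  The left target is
#' `ref[insertion_pos - flank + 1 .. insertion_pos] + insert[1 .. flank]`;
#' the right target is `insert[last flank bases] +
#' ref[insertion_pos + 1 .. insertion_pos + flank]`.  In both, the first
#' base 3' of the breakpoint is at 0-based offset `junction_offset = flank`.
#'
#' @param ref_seq,insert_seq Reference and insertion sequences (character or
#'   `DNAString`).
#' @param insertion_pos Number of reference bases 5' of the insertion.
#' @param flank Flank length in bp (default 140).
#' @return A list of class `"breakpoint_targets"` with elements `left` and
#'   `right`, each a list `(name, sequence, junction_offset)`.
#' @export
build_breakpoint_targets <- function(ref_seq, insert_seq, insertion_pos,
                                     flank = 140) {
  ref_seq <- as_sequence_string(ref_seq, "ref_seq")
  insert_seq <- as_sequence_string(insert_seq, "insert_seq")
  check_scalar(insertion_pos, "insertion_pos", lower = 0, integer = TRUE)
  check_scalar(flank, "flank", lower = 1, integer = TRUE)
  nr <- nchar(ref_seq); ni <- nchar(insert_seq)
  if (insertion_pos > nr) {
    stop("insertion_pos lies outside the reference sequence", call. = FALSE)
  }
  if (flank > insertion_pos) {
    stop("insufficient 5' reference flank for the left breakpoint target",
         call. = FALSE)
  }
  if (flank > nr - insertion_pos) {
    stop("insufficient 3' reference flank for the right breakpoint target",
         call. = FALSE)
  }
  if (flank > ni) {
    stop("insertion shorter than the requested flank", call. = FALSE)
  }
  left <- paste0(substr(ref_seq, insertion_pos - flank + 1, insertion_pos),
                 substr(insert_seq, 1, flank))
  right <- paste0(substr(insert_seq, ni - flank + 1, ni),
                  substr(ref_seq, insertion_pos + 1, insertion_pos + flank))
  structure(list(
    left = list(name = "left", sequence = left, junction_offset = flank),
    right = list(name = "right", sequence = right, junction_offset = flank)),
    class = "breakpoint_targets")
}

read_input_to_df <- function(reads) {
  if (is(reads, "DNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(data.frame(read_id = ids, seq = as.character(reads)))
  }
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "seq") %in% names(reads))) {
      stop("read data.frame needs 'read_id' and 'seq' columns", call. = FALSE)
    }
    return(data.frame(read_id = as.character(reads$read_id),
                      seq = toupper(reads$seq)))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(data.frame(read_id = ids, seq = toupper(reads)))
  }
  stop("unsupported read input", call. = FALSE)
}

#' Map reads end-to-end onto breakpoint targets
#'
#' Aligns each read (and its reverse complement) end-to-end against both
#' junction targets by unit-cost edit distance with free target ends, and
#' retains placements with at most `floor(max_diff_frac * read length)`
#' differences (substitutions and gaps).  A read's placement is *unique* if
#' exactly one placement — across both targets, both strands and all target
#' offsets — attains its minimal retained edit distance.
#'
#' An exact k-mer prefilter (k chosen so that no read within the edit budget
#' can be missed) skips reads that cannot reach the threshold; reads longer
#' than a target are skipped with a warning.
#'
#' @param reads Character vector, `DNAStringSet`, or a data.frame with
#'   columns `read_id` and `seq` (e.g. from [simulate_breakpoint_reads()]).
#' @param targets A `"breakpoint_targets"` object.
#' @param max_diff_frac Maximum differences as a fraction of read length
#'   (default 0.05).
#' @return A `data.frame` with one row per read that has at least one
#'   retained placement: `read_id`, `target` (`"left"`/`"right"`), `strand`,
#'   `start` (0-based target offset), `read_len`, `edit_distance`,
#'   `n_best` (optimal placements over targets/strands/offsets) and
#'   `unique`.  The reported placement is the best one (leftmost end on
#'   ties, `left` target preferred, `+` strand preferred).
#' @export
map_reads_to_targets <- function(reads, targets, max_diff_frac = 0.05) {
  stopifnot(inherits(targets, "breakpoint_targets"))
  check_scalar(max_diff_frac, "max_diff_frac", lower = 0, upper = 1)
  df <- read_input_to_df(reads)
  if (nrow(df) == 0L) stop("no reads supplied", call. = FALSE)
  lens <- nchar(df$seq)
  tlen <- min(nchar(targets$left$sequence), nchar(targets$right$sequence))
  too_long <- lens > tlen
  if (any(too_long)) {
    warning(sum(too_long), " read(s) longer than the targets were skipped")
    df <- df[!too_long, , drop = FALSE]
    lens <- lens[!too_long]
    if (nrow(df) == 0L) return(empty_alignment_df())
  }
  max_edits <- floor(max_diff_frac * lens)
  rc <- revcomp(df$seq)

  ## conservative exact-seed prefilter over both targets and strands
  kmax <- max(1L, floor((min(lens) - max(max_edits)) / (max(max_edits) + 1)))
  k <- min(16L, kmax)
  candidate <- rep(FALSE, nrow(df))
  combos <- list(list(target = "left", strand = "+", seq = df$seq),
                 list(target = "left", strand = "-", seq = rc),
                 list(target = "right", strand = "+", seq = df$seq),
                 list(target = "right", strand = "-", seq = rc))
  if (k >= 8L) {
    for (cb in combos) {
      tseq <- targets[[cb$target]]$sequence
      candidate <- candidate | kmer_prefilter(cb$seq, tseq, k)
    }
  } else {
    candidate[] <- TRUE
  }
  idx <- which(candidate)
  if (!length(idx)) return(empty_alignment_df())

  hits <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    aln <- align_semiglobal(cb$seq[idx], targets[[cb$target]]$sequence)
    hits[[i]] <- data.frame(row = idx, target = cb$target, strand = cb$strand,
                            cost = aln[, "cost"], start = aln[, "start"],
                            n_best = aln[, "n_best"])
  }
  hits <- do.call(rbind, hits)
  hits <- hits[!is.na(hits$cost) & hits$cost <= max_edits[hits$row], ,
               drop = FALSE]
  if (!nrow(hits)) return(empty_alignment_df())

  out <- lapply(split(hits, hits$row), function(h) {
    minc <- min(h$cost)
    best <- h[h$cost == minc, , drop = FALSE]
    n_best <- sum(best$n_best)
    b <- best[1L, ]
    r <- b$row
    data.frame(read_id = df$read_id[r], target = b$target, strand = b$strand,
               start = b$start, read_len = lens[r], edit_distance = minc,
               n_best = n_best, unique = n_best == 1L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_alignment_df <- function() {
  data.frame(read_id = character(), target = character(), strand = character(),
             start = integer(), read_len = integer(),
             edit_distance = integer(), n_best = integer(), unique = logical())
}

#' Classify alignments as core-mapping reads
#'
#' A read supports an insertion breakpoint only if it overlaps the junction
#' with the *inner 50%* of its sequence — i.e. the junction falls at least a
#' quarter read-length away from either read end.  With read length `L` and
#' the junction at 0-based offset `o = junction_offset - start` within the
#' read, the core condition is `ceil(L/4) <= o <= floor(3L/4)` (inclusive
#' bounds); reads not overlapping the junction (`o <= 0` or `o >= L`) are
#' never core.
#'
#' @param alignments Output of [map_reads_to_targets()].
#' @param targets The `"breakpoint_targets"` the reads were mapped to.
#' @return `alignments` with columns `junction_read_offset` and `core`
#'   appended.
#' @export
classify_core_reads <- function(alignments, targets) {
  stopifnot(inherits(targets, "breakpoint_targets"))
  if (!all(c("target", "start", "read_len") %in% names(alignments))) {
    stop("'alignments' must come from map_reads_to_targets()", call. = FALSE)
  }
  joff <- vapply(as.character(alignments$target), function(t)
    targets[[t]]$junction_offset, numeric(1))
  o <- joff - alignments$start
  L <- alignments$read_len
  alignments$junction_read_offset <- as.integer(o)
  alignments$core <- o >= ceiling(L / 4) & o <= floor(3 * L / 4) &
    o > 0 & o < L
  alignments
}

#' Call insertion presence from classified alignments
#'
#' Counts unique core-mapping reads per breakpoint and calls the insertion
#' present iff both breakpoints reach `min_reads` supporting reads.
#'
#' @param alignments Output of [classify_core_reads()].
#' @param min_reads Minimum unique core-mapping reads required at *each*
#'   breakpoint (default 2).
#' @param sample Sample identifier carried into the result.
#' @param dedup If `TRUE`, reads with identical placement (target, strand,
#'   start and read length — i.e. duplicate fragments) are counted once.
#' @return A list of class `"insertion_call"`: `sample`, `support_left`,
#'   `support_right`, `present`, `min_reads`.
#' @export
call_insertion_presence <- function(alignments, min_reads = 2,
                                    sample = "sample", dedup = FALSE) {
  check_scalar(min_reads, "min_reads", lower = 1, integer = TRUE)
  check_flag(dedup, "dedup")
  if (nrow(alignments) && !"core" %in% names(alignments)) {
    stop("alignments must be classified with classify_core_reads() first",
         call. = FALSE)
  }
  sup <- if (nrow(alignments)) {
    alignments[alignments$unique & alignments$core, , drop = FALSE]
  } else alignments
  if (dedup && nrow(sup)) {
    key <- paste(sup$target, sup$strand, sup$start, sup$read_len)
    sup <- sup[!duplicated(key), , drop = FALSE]
  }
  support_left <- sum(sup$target == "left")
  support_right <- sum(sup$target == "right")
  structure(list(sample = sample,
                 support_left = support_left,
                 support_right = support_right,
                 present = support_left >= min_reads &&
                   support_right >= min_reads,
                 min_reads = as.integer(min_reads)),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(sprintf("Insertion call for %s: %s (left %d, right %d; >= %d required)\n",
              x$sample, if (x$present) "PRESENT" else "absent",
              x$support_left, x$support_right, x$min_reads))
  invisible(x)
}

#' Genotype an insertion in one sample
#'
#' End-to-end convenience wrapper: builds the junction targets, maps the
#' reads, classifies core reads and calls presence.
#'
#' @inheritParams build_breakpoint_targets
#' @inheritParams map_reads_to_targets
#' @inheritParams call_insertion_presence
#' @return An `"insertion_call"`, with the classified alignments attached as
#'   attribute `"alignments"`.
#' @export
genotype_insertion <- function(reads, ref_seq, insert_seq, insertion_pos,
                               flank = 140, max_diff_frac = 0.05,
                               min_reads = 2, sample = "sample",
                               dedup = FALSE) {
  targets <- build_breakpoint_targets(ref_seq, insert_seq, insertion_pos,
                                      flank = flank)
  aln <- map_reads_to_targets(reads, targets, max_diff_frac = max_diff_frac)
  aln <- classify_core_reads(aln, targets)
  call <- call_insertion_presence(aln, min_reads = min_reads,
                                  sample = sample, dedup = dedup)
  attr(call, "alignments") <- aln
  call
}
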