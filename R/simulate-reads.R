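#' Simulate short reads tiling an insertion junction
#'
#' Draws fixed-length single-end reads uniformly from either the reference
#' allele (`carrier = FALSE`) or the insertion-bearing allele
#' (`ref[1..insertion_pos] + insert + ref[insertion_pos+1..end]`,
#' `carrier = TRUE`), applies i.i.d. substitution errors, and records for
#' each read its true source offset and whether it spans the left or right
#' insertion junction.  The number of reads is Poisson with mean
#' `depth * source length / read_len`.
#'
#' @inheritParams build_breakpoint_targets
#' @param read_len Read length in bp (default 100).
#' @param depth Expected fold coverage of the source allele (default 20).
#' @param error_rate Per-base substitution probability, in `[0, 0.5)`.
#' @param carrier Whether the sample carries the insertion.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `read_id`, `seq`, `start` (1-based
#'   offset on the source allele), `source` (`"ref"`/`"carrier"`),
#'   `spans_left`, `spans_right`; the source allele sequence is attached as
#'   attribute `"source_seq"`.
#' @export
simulate_breakpoint_reads <- function(ref_seq, insert_seq, insertion_pos,
                                      read_len = 100, depth = 20,
                                      error_rate = 0.005, carrier = TRUE,
                                      seed = 1) {
  ref_seq <- as_sequence_string(ref_seq, "ref_seq")
  insert_seq <- as_sequence_string(insert_seq, "insert_seq")
  check_scalar(insertion_pos, "insertion_pos", lower = 0,
               upper = nchar(ref_seq), integer = TRUE)
  check_scalar(read_len, "read_len", lower = 1, upper = nchar(ref_seq),
               integer = TRUE)
  check_scalar(depth, "depth", lower = 0, strict_lower = TRUE)
  check_scalar(error_rate, "error_rate", lower = 0, upper = 0.5 - 1e-12)
  check_flag(carrier, "carrier")

  if (carrier) {
    source_seq <- paste0(substr(ref_seq, 1, insertion_pos), insert_seq,
                         substr(ref_seq, insertion_pos + 1, nchar(ref_seq)))
    jl <- insertion_pos                       # junction after this base
    jr <- insertion_pos + nchar(insert_seq)
  } else {
    source_seq <- ref_seq
    jl <- jr <- NA_integer_
  }
  L <- nchar(source_seq)
  with_seed(seed, {
    n <- rpois(1, depth * L / read_len)
    start <- if (n > 0) sample.int(L - read_len + 1L, n, replace = TRUE)
             else integer()
    seqs <- substring(source_seq, start, start + read_len - 1L)
    if (error_rate > 0 && n > 0) {
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      nrow = n, byrow = TRUE)
      err <- matrix(runif(n * read_len) < error_rate, nrow = n)
      if (any(err)) {
        bases <- c("A", "C", "G", "T")
        orig <- chars[err]
        repl <- vapply(orig, function(b) sample(setdiff(bases, b), 1L),
                       character(1))
        chars[err] <- repl
        seqs <- apply(chars, 1, paste0, collapse = "")
      }
    }
    spans <- function(j) {
      if (is.na(j)) rep(FALSE, n)
      else start <= j & start + read_len - 1L >= j + 1L
    }
    out <- data.frame(read_id = sprintf("read%05d", seq_len(n)),
                      seq = as.character(seqs), start = as.integer(start),
                      source = if (carrier) "carrier" else "ref",
                      spans_left = spans(jl), spans_right = spans(jr))
    attr(out, "source_seq") <- source_seq
    attr(out, "junctions") <- c(left = jl, right = jr)
    out
  })
}

#' Simulate replicate per-nucleotide coverage with premature termination
#'
#' Models RNA-seq read coverage over a gene whose transcription partially
#' terminates at `termination_pos`: the expected per-nucleotide count is
#' `base_depth` upstream (positions `1..termination_pos`) and
#' `base_depth * (1 - termination_fraction)` downstream.  Counts are drawn
#' per replicate from a negative binomial with dispersion `noise`
#' (variance `mu + noise * mu^2`; `noise = 0` gives Poisson counts).
#'
#' @param gene_length Gene span in bp, or a [gene_model()] whose span is
#'   used.
#' @param n_reps Number of biological replicates (default 3).
#' @param base_depth Expected upstream per-nucleotide count.
#' @param termination_fraction Fraction of transcripts lost at the
#'   termination point, in `[0, 1]`.
#' @param termination_pos Last position (bp, 1-based) with full coverage.
#' @param noise Negative-binomial overdispersion (default 0.05).
#' @param seed Integer seed.
#' @return An integer matrix (`n_reps` x `gene_length`) of class
#'   `"coverage_profiles"`.
#' @export
simulate_coverage_profiles <- function(gene_length, n_reps = 3,
                                       base_depth = 100,
                                       termination_fraction = 0,
                                       termination_pos = NULL,
                                       noise = 0.05, seed = 1) {
  if (inherits(gene_length, "gene_model")) {
    gene_length <- gene_span(gene_length)
  }
  check_scalar(gene_length, "gene_length", lower = 1, integer = TRUE)
  check_scalar(n_reps, "n_reps", lower = 1, integer = TRUE)
  check_scalar(base_depth, "base_depth", lower = 0, strict_lower = TRUE)
  check_scalar(termination_fraction, "termination_fraction",
               lower = 0, upper = 1)
  if (is.null(termination_pos)) termination_pos <- gene_length
  check_scalar(termination_pos, "termination_pos", lower = 1,
               integer = TRUE)
  if (termination_pos > gene_length) {
    stop("termination_pos lies outside the gene span", call. = FALSE)
  }
  check_scalar(noise, "noise", lower = 0)
  mu <- rep(base_depth, gene_length)
  if (termination_pos < gene_length) {
    mu[(termination_pos + 1):gene_length] <-
      base_depth * (1 - termination_fraction)
  }
  with_seed(seed, {
    draw <- function() {
      if (noise > 0) rnbinom(gene_length, size = 1 / noise, mu = mu)
      else rpois(gene_length, mu)
    }
    out <- t(vapply(seq_len(n_reps), function(i) draw(),
                    numeric(gene_length)))
    rownames(out) <- paste0("rep", seq_len(n_reps))
    class(out) <- c("coverage_profiles", class(out))
    out
  })
}

#' Simulate a qRT-PCR Ct table with known fold changes
#'
#' Generates threshold-cycle values consistent with perfect doubling per
#' cycle: `Ct = base_ct - log2(expression)`, where the target-gene
#' expression of each sample equals its true fold change relative to the
#' calibrator and the reference gene is constant across samples.  Gaussian
#' noise of SD `ct_noise_sd` cycles is added independently to every
#' measurement.
#'
#' @param fold_changes Named numeric vector: true target-gene fold change
#'   per sample (relative to `calibrator`), or a numeric matrix with target
#'   genes in rows and samples in columns.
#' @param target_gene Target gene name (ignored when a matrix is given).
#' @param reference_gene Reference (housekeeping) gene name (default
#'   `"ACT8"`).
#' @param calibrator Calibrator sample name (default: first sample); its
#'   fold change should be 1.
#' @param n_reps Technical/biological replicates per measurement.
#' @param ct_noise_sd Measurement noise SD in cycles.
#' @param base_ct Baseline Ct of a unit-expression gene (default 24).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sample`, `gene`, `replicate`, `ct`,
#'   with the calibrator and reference gene recorded as attributes.
#' @export
simulate_ct_table <- function(fold_changes, target_gene = "target",
                              reference_gene = "ACT8", calibrator = NULL,
                              n_reps = 3, ct_noise_sd = 0.1, base_ct = 24,
                              seed = 1) {
  if (is.matrix(fold_changes)) {
    fc <- fold_changes
  } else {
    fc <- matrix(fold_changes, nrow = 1,
                 dimnames = list(target_gene, names(fold_changes)))
  }
  if (is.null(colnames(fc)) || is.null(rownames(fc))) {
    stop("fold changes must be named by sample (and gene)", call. = FALSE)
  }
  if (any(fc <= 0)) stop("fold changes must be positive", call. = FALSE)
  check_scalar(n_reps, "n_reps", lower = 1, integer = TRUE)
  check_scalar(ct_noise_sd, "ct_noise_sd", lower = 0)
  if (is.null(calibrator)) calibrator <- colnames(fc)[1L]
  if (!calibrator %in% colnames(fc)) {
    stop("calibrator sample not found in fold-change table", call. = FALSE)
  }
  samples <- colnames(fc)
  genes <- c(rownames(fc), reference_gene)
  grid <- expand.grid(sample = samples, gene = genes,
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr <- ifelse(grid$gene == reference_gene, 1,
                 fc[cbind(match(grid$gene, rownames(fc)),
                          match(grid$sample, samples))])
  with_seed(seed, {
    grid$ct <- base_ct - log2(expr) + rnorm(nrow(grid), 0, ct_noise_sd)
    attr(grid, "reference_gene") <- reference_gene
    attr(grid, "calibrator") <- calibrator
    grid
  })
}

#' Simulate paired expression/flowering-time observations
#'
#' Expression values are drawn uniformly on `[0, 1]` and flowering time is
#' `intercept + slope * expression + Normal(0, noise_sd)`.  With `x ~
#' U(0,1)` the theoretical coefficient of determination is
#' `slope^2/12 / (slope^2/12 + noise_sd^2)`, which makes targeted
#' recovery experiments straightforward.
#'
#' @param n Number of pairs (>= 3).
#' @param slope Days of flowering-time change per unit expression.
#' @param intercept Baseline flowering time (days).
#' @param noise_sd Residual SD (days).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `expression` and `flowering`.
#' @export
simulate_expression_phenotype <- function(n = 50, slope = -10,
                                          intercept = 60, noise_sd = 1,
                                          seed = 1) {
  check_scalar(n, "n", lower = 3, integer = TRUE)
  check_scalar(slope, "slope")
  check_scalar(intercept, "intercept")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    x <- runif(n)
    data.frame(expression = x,
               flowering = intercept + slope * x + rnorm(n, 0, noise_sd))
  })
}
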