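#' Gene model with labelled exons
#'
#' A minimal gene annotation: ordered, non-overlapping exon intervals in
#' gene-local coordinates (1-based, inclusive), stored 5' to 3' of the gene
#' regardless of genomic strand.
#'
#' @param gene_id Gene identifier.
#' @param exons A `data.frame` with columns `start` and `end` (1-based,
#'   inclusive, gene-local bp) and optionally `label`; rows ordered 5'->3'.
#' @param chrom,strand Optional genomic context.
#' @return A list of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, exons, chrom = NA, strand = "+") {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (any(exons$end < exons$start)) {
    stop("exon end before start", call. = FALSE)
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be ordered 5'->3' and non-overlapping", call. = FALSE)
  }
  if (is.null(exons$label)) exons$label <- paste0("exon", seq_len(nrow(exons)))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons),
            class = "gene_model")
}

gene_span <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  max(model$exons$end)
}

#' Normalize a per-nucleotide coverage profile to the unit interval
#'
#' Divides each value by the profile maximum so the profile ranges from 0
#' (no expression) to 1 (maximum expression).  An all-zero profile is
#' returned unchanged (no division by zero).
#'
#' @param counts Numeric vector of per-nucleotide counts (or a matrix of
#'   replicate rows, normalized row-wise).
#' @return Normalized values of the same shape.
#' @export
normalize_profile <- function(counts) {
  if (is.matrix(counts)) {
    return(t(apply(counts, 1, normalize_profile)))
  }
  if (!length(counts)) stop("empty profile", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  m <- max(counts)
  if (m == 0) return(counts)
  counts / m
}

#' Replicate mean and 5%/95% band of normalized coverage
#'
#' Normalizes replicate profiles to a common `[0, 1]` scale and summarises
#' them pointwise by the mean and the empirical 5% and 95% quantiles across
#' replicates (linear-interpolation quantile rule, [stats::quantile()]
#' type 7; with three replicates these quantiles approach the replicate
#' minimum and maximum).
#'
#' By default all replicates are divided by the maximum of the *mean* raw
#' profile so that the replicates of one genotype share a single scale;
#' `normalize = "per-replicate"` rescales each replicate by its own
#' maximum, and `"none"` skips normalization.
#'
#' @param profiles Numeric matrix, replicates in rows.
#' @param normalize `"shared"` (default), `"per-replicate"`, or `"none"`.
#' @param probs Band quantiles (default `c(0.05, 0.95)`).
#' @return A `data.frame` with columns `pos`, `mean`, `q05`, `q95`.
#' @export
replicate_band <- function(profiles, normalize = c("shared", "per-replicate",
                                                   "none"),
                           probs = c(0.05, 0.95)) {
  normalize <- match.arg(normalize)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) {
    stop("need at least two replicates", call. = FALSE)
  }
  norm <- switch(normalize,
    shared = {
      m <- max(colMeans(profiles))
      if (m == 0) profiles else profiles / m
    },
    `per-replicate` = normalize_profile(profiles),
    none = profiles)
  qs <- apply(norm, 2, quantile, probs = probs, names = FALSE, type = 7)
  data.frame(pos = seq_len(ncol(norm)), mean = colMeans(norm),
             q05 = qs[1, ], q95 = qs[2, ])
}

#' Exon read counts and the exon-1 usage ratio
#'
#' Sums per-nucleotide counts over each exon of a gene model, per
#' replicate, and reports the ratio of the first-exon count to the summed
#' count of all remaining exons — a scale-free measure of premature
#' transcription termination downstream of exon 1.  The mean and sample
#' standard deviation (n-1) across replicates are attached.
#'
#' @param profiles Replicate count matrix (rows = replicates) over the gene
#'   span, raw (unnormalized) counts; the ratio is scale-invariant within a
#'   replicate.
#' @param model A [gene_model()] whose exons lie within the profile span.
#' @return A list of class `"exon_usage"`: `counts` (replicates x exons
#'   matrix), `ratio_exon1` (per replicate; `NA` where the denominator is
#'   zero, excluded from the summary with a warning), `mean`, `sd`.
#' @export
exon_usage <- function(profiles, model) {
  stopifnot(inherits(model, "gene_model"))
  profiles <- as.matrix(profiles)
  if (gene_span(model) > ncol(profiles)) {
    stop("gene model extends beyond the coverage profile", call. = FALSE)
  }
  ex <- model$exons
  counts <- sapply(seq_len(nrow(ex)), function(j)
    rowSums(profiles[, ex$start[j]:ex$end[j], drop = FALSE]))
  counts <- matrix(counts, nrow = nrow(profiles),
                   dimnames = list(rownames(profiles), ex$label))
  denom <- rowSums(counts[, -1L, drop = FALSE])
  ratio <- ifelse(denom > 0, counts[, 1L] / denom, NA_real_)
  if (anyNA(ratio)) {
    warning(sum(is.na(ratio)),
            " replicate(s) had zero counts over exons 2..K; excluded")
  }
  ok <- ratio[!is.na(ratio)]
  structure(list(counts = counts, ratio_exon1 = ratio,
                 mean = mean(ok), sd = if (length(ok) > 1) sd(ok) else NA_real_),
            class = "exon_usage")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Classical comparative-Ct quantification assuming amplification
#' efficiency exactly 2: per replicate, `dCt = Ct_target - Ct_reference`;
#' per sample, `ddCt = mean(dCt) - mean(dCt_calibrator)` and the fold
#' change is `2^-ddCt`.  The standard error of the fold change is
#' propagated from the replicate dCt variances of the sample and the
#' calibrator (delta method: `SE_fold = ln(2) * fold * SE_ddCt`).
#'
#' @param ct_table A `data.frame` with columns `sample`, `gene`,
#'   `replicate`, `ct` (e.g. from [simulate_ct_table()] or
#'   [read_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param reference_gene Reference gene (default: the table's
#'   `reference_gene` attribute, else `"ACT8"`).
#' @param calibrator Calibrator sample (default: the table's attribute,
#'   else the first sample).
#' @return A `data.frame` with one row per sample: `sample`, `n_reps`,
#'   `delta_ct`, `ddct`, `fold_change`, `se`.
#' @export
ddct_relative_expression <- function(ct_table, target_gene,
                                     reference_gene = NULL,
                                     calibrator = NULL) {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct_table)))
  if (is.null(reference_gene)) {
    reference_gene <- attr(ct_table, "reference_gene")
    if (is.null(reference_gene)) reference_gene <- "ACT8"
  }
  if (is.null(calibrator)) {
    calibrator <- attr(ct_table, "calibrator")
    if (is.null(calibrator)) calibrator <- ct_table$sample[1L]
  }
  tgt <- ct_table[ct_table$gene == target_gene, ]
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!nrow(tgt)) stop("target gene not in table", call. = FALSE)
  if (!nrow(ref)) stop("reference gene not in table", call. = FALSE)
  key <- function(d) paste(d$sample, d$replicate, sep = "\r")
  idx <- match(key(tgt), key(ref))
  if (anyNA(idx)) {
    stop("reference-gene Ct missing for some sample/replicate", call. = FALSE)
  }
  dct <- tgt$ct - ref$ct[idx]
  samples <- unique(as.character(tgt$sample))
  if (!calibrator %in% samples) {
    stop("calibrator sample '", calibrator, "' not present", call. = FALSE)
  }
  agg <- lapply(samples, function(s) {
    d <- dct[tgt$sample == s]
    c(n = length(d), mean = mean(d),
      var = if (length(d) > 1) stats::var(d) else 0)
  })
  agg <- do.call(rbind, agg)
  cal <- which(samples == calibrator)
  ddct <- agg[, "mean"] - agg[cal, "mean"]
  se_ddct <- sqrt(agg[, "var"] / agg[, "n"] +
                  ifelse(seq_along(samples) == cal, 0,
                         agg[cal, "var"] / agg[cal, "n"]))
  fold <- 2^(-ddct)
  data.frame(sample = samples, n_reps = as.integer(agg[, "n"]),
             delta_ct = agg[, "mean"], ddct = ddct, fold_change = fold,
             se = log(2) * fold * se_ddct)
}

#' Isoform abundance ratios normalized to a reference accession
#'
#' Given per-accession fold changes of two splice isoforms (each already
#' expressed relative to any common scale), computes the isoform ratio
#' `delta/beta` normalized so that the reference accession equals 1.
#'
#' @param table A `data.frame` with columns `accession`, `beta_fold`,
#'   `delta_fold` (positive).
#' @param reference Reference accession (default `"Col-0"`).
#' @return `table` with a `ratio` column appended; accessions with zero or
#'   missing `beta_fold` get `NA` with a warning.
#' @export
isoform_ratio <- function(table, reference = "Col-0") {
  stopifnot(all(c("accession", "beta_fold", "delta_fold") %in% names(table)))
  i <- match(reference, table$accession)
  if (is.na(i)) stop("reference accession not in table", call. = FALSE)
  if (!is.finite(table$beta_fold[i]) || table$beta_fold[i] <= 0) {
    stop("reference accession has non-positive beta abundance", call. = FALSE)
  }
  bad <- !is.finite(table$beta_fold) | table$beta_fold <= 0
  raw <- ifelse(bad, NA_real_, table$delta_fold / table$beta_fold)
  if (any(bad)) warning(sum(bad), " accession(s) with zero/missing beta; NA")
  table$ratio <- raw / raw[i]
  table
}

#' Linear regression of flowering time on expression
#'
#' Ordinary least squares fit with the coefficient of determination
#' `R^2 = 1 - SSE/SST`.
#'
#' @param pairs A `data.frame` with columns `expression` and `flowering`,
#'   or two numeric vectors via `expression`/`flowering`.
#' @param expression,flowering Alternative vector interface.
#' @return A list of class `"flowering_regression"`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
regress_flowering_on_expression <- function(pairs = NULL, expression = NULL,
                                            flowering = NULL) {
  if (!is.null(pairs)) {
    expression <- pairs$expression
    flowering <- pairs$flowering
  }
  ok <- is.finite(expression) & is.finite(flowering)
  expression <- expression[ok]; flowering <- flowering[ok]
  n <- length(expression)
  if (n < 3) stop("need at least three pairs", call. = FALSE)
  if (stats::var(expression) == 0) {
    stop("expression has zero variance; slope undefined", call. = FALSE)
  }
  fit <- lm(flowering ~ expression)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((flowering - mean(flowering))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (sst > 0) 1 - sse / sst else 0,
                 n = n),
            class = "flowering_regression")
}

#' Mann-Whitney association test between a polymorphism and a quantitative
#' trait
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the values of
#' the two allele groups.  For small samples (`n1 + n2 <= 20`) the p-value
#' is exact: computed by [stats::wilcox.test()] when the data are free of
#' ties, and otherwise by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the mid-rank statistic.  Larger
#' samples use the normal approximation with mid-ranks and tie correction.
#'
#' @param values Numeric trait values.
#' @param groups A two-level factor/vector assigning each value to an
#'   allele group.
#' @return A list: `U` (the Mann-Whitney U of the first group), `p_value`,
#'   `method`, `n1`, `n2`.
#' @export
polymorphism_association <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' lengths differ", call. = FALSE)
  }
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) != 2L || any(table(groups) == 0)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  g1 <- values[groups == levels(groups)[1L]]
  g2 <- values[groups == levels(groups)[2L]]
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  r <- rank(c(g1, g2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(g1, g2)) > 0
  if (N <= 20 && !has_ties) {
    p <- suppressWarnings(wilcox.test(g1, g2, exact = TRUE)$p.value)
    method <- "exact"
  } else if (N <= 20) {
    p <- exact_mw_pvalue_ties(r, n1)
    method <- "exact (enumeration, mid-ranks)"
  } else {
    p <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE,
                                      correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(U = U, p_value = min(p, 1), method = method, n1 = n1, n2 = n2)
}

## Exact permutation two-sided p-value of the Mann-Whitney statistic with
## mid-ranks: enumerate every assignment of n1 of the N ranks to group 1 and
## count assignments whose |U - n1*n2/2| is at least the observed one.
exact_mw_pvalue_ties <- function(ranks, n1) {
  N <- length(ranks)
  n2 <- N - n1
  obs <- abs(sum(ranks[seq_len(n1)]) - n1 * (N + 1) / 2)
  combos <- utils::combn(N, n1)
  sums <- colSums(matrix(ranks[combos], nrow = n1))
  dev <- abs(sums - n1 * (N + 1) / 2)
  mean(dev >= obs - 1e-9)
}
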