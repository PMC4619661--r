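#' Mean pairwise nucleotide differences in an alignment
#'
#' Averages, over all sequence pairs, the number of aligned positions at
#' which both sequences carry an unambiguous base (A/C/G/T) and the bases
#' differ (`k`), together with the number of such comparable positions
#' (`L`).  Alignment gaps and ambiguity codes are excluded from both.
#'
#' @param seqs Aligned sequences of equal length: a character vector, a
#'   `DNAStringSet`, or a path to a multi-FASTA alignment.
#' @return A list: `k` (mean pairwise differences), `L` (mean comparable
#'   sites), `n_seqs`, `pairs` (a per-pair `data.frame`).
#' @export
pairwise_differences <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    seqs <- Biostrings::readDNAStringSet(seqs)
  }
  if (is(seqs, "DNAStringSet") || is(seqs, "XStringSet")) {
    seqs <- as.character(seqs)
  }
  if (!is.character(seqs) || length(seqs) < 2L) {
    stop("need at least two aligned sequences", call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  n <- length(seqs)
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2, function(p) {
    comp <- valid[p[1], ] & valid[p[2], ]
    c(diff = sum(comp & mat[p[1], ] != mat[p[2], ]), sites = sum(comp))
  })
  df <- data.frame(seq1 = ids[pairs[1, ]], seq2 = ids[pairs[2, ]],
                   differences = res["diff", ], sites = res["sites", ])
  list(k = mean(df$differences), L = mean(df$sites), n_seqs = n, pairs = df)
}

#' Date an allele by a neutral mutation clock
#'
#' Converts observed sequence divergence among carriers of a shared allele
#' into an age interval under a star-shaped two-lineage divergence model:
#' the expected number of pairwise differences over `L` compared sites
#' after `T` generations of independent evolution at per-site,
#' per-generation mutation rate `mu` is `2 * mu * L * T` (no multiple-hit
#' correction; differences are assumed much smaller than `L`).  Interval
#' parameters combine conservatively: `gen_lo = k / (2 * mu_hi * L)`,
#' `gen_hi = k / (2 * mu_lo * L)`, `years_lo = gen_lo / g_hi`,
#' `years_hi = gen_hi / g_lo`, where `g` is the number of seed generations
#' per year.
#'
#' @param k Mean pairwise nucleotide differences (e.g. from
#'   [pairwise_differences()]).
#' @param L Compared sites (bp).
#' @param mu Length-2 numeric, the per-site per-generation mutation-rate
#'   interval (default `c(6e-9, 7e-9)`, the spontaneous rate measured in
#'   *A. thaliana* mutation-accumulation lines).
#' @param gen_per_year Length-2 numeric, seed generations per year
#'   (default `c(1, 3)`).
#' @return A list of class `"allele_age"`: `gen_lo`, `gen_hi`, `years_lo`,
#'   `years_hi`, `unresolved` (`TRUE` when `k = 0`, i.e. no divergence
#'   observed and only the age lower bound 0 is meaningful), plus the
#'   inputs.
#' @export
estimate_allele_age <- function(k, L, mu = c(6e-9, 7e-9),
                                gen_per_year = c(1, 3)) {
  check_scalar(k, "k", lower = 0)
  check_scalar(L, "L", lower = 0, strict_lower = TRUE)
  mu <- sort(as.numeric(mu))
  gen_per_year <- sort(as.numeric(gen_per_year))
  if (length(mu) != 2L || any(mu <= 0)) {
    stop("'mu' must be a positive rate interval c(lo, hi)", call. = FALSE)
  }
  if (length(gen_per_year) != 2L || any(gen_per_year <= 0)) {
    stop("'gen_per_year' must be a positive interval c(lo, hi)",
         call. = FALSE)
  }
  gen_lo <- k / (2 * mu[2] * L)
  gen_hi <- k / (2 * mu[1] * L)
  structure(list(k = k, L = L, mu = mu, gen_per_year = gen_per_year,
                 gen_lo = gen_lo, gen_hi = gen_hi,
                 years_lo = gen_lo / gen_per_year[2],
                 years_hi = gen_hi / gen_per_year[1],
                 unresolved = k == 0),
            class = "allele_age")
}

#' @export
print.allele_age <- function(x, ...) {
  cat(sprintf("Allele age from k = %.3g differences over L = %.0f sites\n",
              x$k, x$L))
  if (x$unresolved) {
    cat("  no divergence observed: age lower bound 0 (unresolved)\n")
  }
  cat(sprintf("  generations: %.0f - %.0f\n  years:       %.0f - %.0f\n",
              x$gen_lo, x$gen_hi, x$years_lo, x$years_hi))
  invisible(x)
}
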