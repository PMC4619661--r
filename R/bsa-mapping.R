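#' Per-pool alternative-allele frequencies
#'
#' Computes `f = alternative-read count / depth` for the early and late pool
#' of every SNP record.  Records with zero depth in either pool are not
#' defined and must be removed (e.g. by [filter_snps()]) first.
#'
#' @param tab A SNP pool table (see [read_snp_table()] for the columns).
#' @return `tab` with numeric columns `f_early` and `f_late` appended (they
#'   are recomputed if already present).
#' @examples
#' tab <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "T",
#'                   depth_early = 60, alt_early = 30,
#'                   depth_late = 60, alt_late = 15,
#'                   parental_alt_freq = 1, called_in_both = TRUE)
#' compute_pool_frequency(tab)[, c("f_early", "f_late")]
#' @export
compute_pool_frequency <- function(tab) {
  check_snp_table(tab)
  if (any(tab$depth_early == 0 | tab$depth_late == 0, na.rm = TRUE)) {
    stop("zero-depth records have undefined frequency; filter them first",
         call. = FALSE)
  }
  tab$f_early <- tab$alt_early / tab$depth_early
  tab$f_late <- tab$alt_late / tab$depth_late
  tab
}

check_snp_table <- function(tab) {
  required <- c("chrom", "pos", "depth_early", "alt_early",
                "depth_late", "alt_late", "parental_alt_freq",
                "called_in_both")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("SNP table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' Filter SNPs for allele-frequency mapping
#'
#' Applies the selection rules used before the smoothed allele-frequency
#' scan: a record survives iff (i) its depth lies in `[cov_min, cov_max]` in
#' *both* pools, (ii) its allele frequency exceeds `min_freq` in at least
#' one pool, (iii) it carries a presence call in both pools, and (iv) the
#' homozygous alternative parent showed an alternative-allele frequency of
#' at least `parental_min` (records below are discarded as unreliable
#' calls).  Rules are tested in that order and each rejected record is
#' attributed to the first rule it fails.
#'
#' @param tab SNP pool table.
#' @param cov_min,cov_max Inclusive per-pool depth bounds (default 30-120).
#' @param min_freq Frequency threshold, strict (`f > min_freq`; default 0.20).
#' @param parental_min Minimum parental alternative-allele frequency
#'   (default 0.80).
#' @return The surviving rows (with `f_early`/`f_late` appended), carrying
#'   attributes `rejections` (named counts per rule: `coverage`,
#'   `frequency`, `presence`, `parental`) and `rejected` (a data.frame with
#'   the original row index and failing rule).
#' @export
filter_snps <- function(tab, cov_min = 30, cov_max = 120,
                        min_freq = 0.20, parental_min = 0.80) {
  check_snp_table(tab)
  check_scalar(cov_min, "cov_min", lower = 0)
  check_scalar(cov_max, "cov_max", lower = cov_min)
  check_scalar(min_freq, "min_freq", lower = 0, upper = 1)
  check_scalar(parental_min, "parental_min", lower = 0, upper = 1)
  if (nrow(tab) == 0L) {
    out <- tab
    attr(out, "rejections") <- c(coverage = 0L, frequency = 0L,
                                 presence = 0L, parental = 0L)
    attr(out, "rejected") <- data.frame(row = integer(), rule = character())
    return(out)
  }
  cov_ok <- tab$depth_early >= cov_min & tab$depth_early <= cov_max &
    tab$depth_late >= cov_min & tab$depth_late <= cov_max
  f_early <- ifelse(tab$depth_early > 0, tab$alt_early / tab$depth_early, 0)
  f_late <- ifelse(tab$depth_late > 0, tab$alt_late / tab$depth_late, 0)
  freq_ok <- f_early > min_freq | f_late > min_freq
  pres_ok <- as.logical(tab$called_in_both)
  par_ok <- tab$parental_alt_freq >= parental_min

  rule <- rep(NA_character_, nrow(tab))
  rule[!cov_ok] <- "coverage"
  rule[is.na(rule) & !freq_ok] <- "frequency"
  rule[is.na(rule) & !pres_ok] <- "presence"
  rule[is.na(rule) & !par_ok] <- "parental"

  keep <- is.na(rule)
  out <- tab[keep, , drop = FALSE]
  out$f_early <- f_early[keep]
  out$f_late <- f_late[keep]
  rej <- rule[!keep]
  attr(out, "rejections") <- c(coverage = sum(rej == "coverage"),
                               frequency = sum(rej == "frequency"),
                               presence = sum(rej == "presence"),
                               parental = sum(rej == "parental"))
  attr(out, "rejected") <- data.frame(row = which(!keep), rule = rej)
  out
}

#' Locally weighted scatterplot smoothing (LOESS) of allele frequencies
#'
#' Smooths `values` against `positions` by local polynomial regression with
#' tricube weights: at each evaluation point the `floor(span * n)` nearest
#' observations are fitted by weighted least squares of the given degree,
#' with weights `(1 - (d/h)^3)^3` on distance `d` scaled by the distance
#' `h` to the furthest included neighbour.  No robustness iterations are
#' applied.  This is the classical Cleveland smoother as implemented by
#' [stats::loess()] with an exact (`"direct"`) surface.
#'
#' @param positions Sorted numeric predictor (bp); duplicates are allowed.
#' @param values Numeric response, same length.
#' @param span Fraction of points in each local neighbourhood (default 0.75).
#' @param degree Local polynomial degree, 0, 1 or 2 (default 2).
#' @param at Positions at which to evaluate the fit (default `positions`).
#' @return Numeric vector of fitted values at `at`.
#' @export
loess_smooth <- function(positions, values, span = 0.75, degree = 2,
                         at = positions) {
  if (length(positions) != length(values)) {
    stop("'positions' and 'values' must have equal length", call. = FALSE)
  }
  if (is.unsorted(positions)) {
    stop("'positions' must be sorted in increasing order", call. = FALSE)
  }
  check_scalar(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(degree, "degree", lower = 0, upper = 2, integer = TRUE)
  n <- length(positions)
  if (n < degree + 2) {
    stop(sprintf("need at least %d points for degree-%d smoothing",
                 degree + 2, degree), call. = FALSE)
  }
  fit <- loess(values ~ positions,
               data = data.frame(positions = positions, values = values),
               span = span, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct", statistics = "none"))
  as.numeric(predict(fit, newdata = data.frame(positions = at)))
}

#' Pointwise bootstrap confidence band for a LOESS fit
#'
#' Case-resampling bootstrap: SNPs are resampled with replacement,
#' re-smoothed with [loess_smooth()], and the fitted values at the original
#' positions are summarised by pointwise quantiles (`(1-level)/2` and
#' `1-(1-level)/2`, linear-interpolation rule).
#'
#' @inheritParams loess_smooth
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param level Band level (default 0.95).
#' @param seed Integer seed.
#' @return A list with numeric vectors `lo` and `hi` at `positions`.
#' @export
bootstrap_band <- function(positions, values, span = 0.75, degree = 2,
                           n_boot = 200, level = 0.95, seed = 1) {
  check_scalar(n_boot, "n_boot", lower = 50, integer = TRUE)
  check_scalar(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  n <- length(positions)
  fits <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = n)
    b <- 1L
    attempts <- 0L
    while (b <= n_boot && attempts < 10L * n_boot) {
      attempts <- attempts + 1L
      idx <- sort(sample.int(n, n, replace = TRUE))
      res <- tryCatch(
        suppressWarnings(loess_smooth(positions[idx], values[idx],
                                      span = span, degree = degree,
                                      at = positions)),
        error = function(e) NULL)
      if (!is.null(res) && all(is.finite(res))) {
        out[b, ] <- res
        b <- b + 1L
      }
    }
    if (b <= n_boot) {
      stop("bootstrap_band: too many degenerate resamples", call. = FALSE)
    }
    out
  })
  alpha <- (1 - level) / 2
  list(lo = apply(fits, 2, quantile, probs = alpha, names = FALSE),
       hi = apply(fits, 2, quantile, probs = 1 - alpha, names = FALSE))
}

#' Smooth one pool's allele-frequency profile
#'
#' Convenience wrapper building a smoothed-profile object from raw pool
#' frequencies: LOESS point estimate plus (optionally) a bootstrap band.
#'
#' @inheritParams loess_smooth
#' @inheritParams bootstrap_band
#' @param band If `TRUE`, attach a case-resampling bootstrap band.
#' @return A list of class `"smoothed_profile"` with elements `positions`,
#'   `raw_f`, `smooth_f`, and `band_lo`/`band_hi` (`NULL` unless requested).
#' @export
smooth_pool_profile <- function(positions, values, span = 0.75, degree = 2,
                                band = FALSE, n_boot = 200, level = 0.95,
                                seed = 1) {
  smooth_f <- loess_smooth(positions, values, span = span, degree = degree)
  bd <- if (band) {
    bootstrap_band(positions, values, span = span, degree = degree,
                   n_boot = n_boot, level = level, seed = seed)
  } else list(lo = NULL, hi = NULL)
  structure(list(positions = positions, raw_f = values, smooth_f = smooth_f,
                 band_lo = bd$lo, band_hi = bd$hi,
                 span = span, degree = degree),
            class = "smoothed_profile")
}

#' Allele-frequency difference between two smoothed pool profiles
#'
#' The mapping statistic: the pointwise difference between the smoothed
#' early-pool and late-pool allele frequencies.  With the alternative allele
#' taken from the early (recessive) parent, the causal region produces a
#' positive peak.
#'
#' @param early,late `"smoothed_profile"` objects on identical position
#'   grids (from [smooth_pool_profile()]), or plain numeric vectors of
#'   smoothed frequencies (then `positions` must be supplied).
#' @param positions Position grid when `early`/`late` are plain vectors.
#' @return A list of class `"delta_f_profile"` with `positions` and
#'   `delta_f`.
#' @export
compute_delta_f <- function(early, late, positions = NULL) {
  if (inherits(early, "smoothed_profile") && inherits(late, "smoothed_profile")) {
    if (length(early$positions) != length(late$positions) ||
        any(early$positions != late$positions)) {
      stop("profiles are on different position grids", call. = FALSE)
    }
    positions <- early$positions
    d <- early$smooth_f - late$smooth_f
  } else {
    if (is.null(positions) || length(early) != length(late) ||
        length(early) != length(positions)) {
      stop("'early', 'late' and 'positions' must be equal-length vectors",
           call. = FALSE)
    }
    d <- as.numeric(early) - as.numeric(late)
  }
  structure(list(positions = positions, delta_f = d),
            class = "delta_f_profile")
}

#' Call mapping intervals from a delta-f profile
#'
#' Maximal runs of consecutive positions with `delta_f > threshold` become
#' candidate intervals; each carries the leftmost position attaining the
#' run's maximal delta-f as its peak.  Intervals are reported 0-based
#' half-open (`[first position, last position + 1)`), the convention of the
#' BED output.
#'
#' @param profile A `"delta_f_profile"` from [compute_delta_f()].
#' @param threshold Delta-f threshold, strict (default 0.25).
#' @param chrom Chromosome label for the output (default `"chr"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `peak_pos`,
#'   `peak_delta`, `threshold`; zero rows if nothing exceeds the threshold.
#' @export
call_mapping_interval <- function(profile, threshold = 0.25, chrom = "chr") {
  stopifnot(inherits(profile, "delta_f_profile"))
  check_scalar(threshold, "threshold", lower = -1, upper = 1)
  if (length(profile$positions) == 0L) {
    stop("empty delta-f profile", call. = FALSE)
  }
  above <- profile$delta_f > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_pos = numeric(),
                      peak_delta = numeric(), threshold = numeric()))
  }
  out <- lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    d <- profile$delta_f[idx]
    peak <- idx[which.max(d)]           # which.max: leftmost maximum
    data.frame(chrom = chrom,
               start = profile$positions[starts[i]],
               end = profile$positions[ends[i]] + 1,
               peak_pos = profile$positions[peak],
               peak_delta = profile$delta_f[peak],
               threshold = threshold)
  })
  do.call(rbind, out)
}

#' Rough-mapping marker frequency scan on extreme F2 plants
#'
#' For each marker, computes the alternative-allele frequency of the early
#' and late phenotypic groups (mean genotype / 2) and a two-sided Fisher
#' exact test on the 2x2 allele-count table (early vs late, alternative vs
#' reference allele counts).
#'
#' @param geno_early,geno_late Integer matrices (plants x markers) of
#'   alternative-allele copies (0/1/2), with matching columns.
#' @param marker Optional marker identifiers (default column names or
#'   indices).
#' @param pos Optional marker positions (bp).
#' @return A `data.frame` with columns `marker`, `pos`, `freq_early`,
#'   `freq_late`, `p_value`.  Monomorphic markers yield `p_value = 1`.
#' @export
marker_frequency_scan <- function(geno_early, geno_late,
                                  marker = NULL, pos = NA) {
  geno_early <- as.matrix(geno_early); geno_late <- as.matrix(geno_late)
  if (ncol(geno_early) != ncol(geno_late)) {
    stop("marker sets differ between groups", call. = FALSE)
  }
  if (nrow(geno_early) < 2L || nrow(geno_late) < 2L) {
    stop("need at least two plants per group", call. = FALSE)
  }
  if (!all(unlist(geno_early) %in% 0:2) || !all(unlist(geno_late) %in% 0:2)) {
    stop("genotypes must be coded 0/1/2 alternative-allele copies",
         call. = FALSE)
  }
  m <- ncol(geno_early)
  if (is.null(marker)) {
    marker <- colnames(geno_early)
    if (is.null(marker)) marker <- paste0("M", seq_len(m))
  }
  alt_e <- colSums(geno_early); alt_l <- colSums(geno_late)
  tot_e <- 2 * nrow(geno_early); tot_l <- 2 * nrow(geno_late)
  p <- vapply(seq_len(m), function(j) {
    tb <- matrix(c(alt_e[j], tot_e - alt_e[j],
                   alt_l[j], tot_l - alt_l[j]), nrow = 2)
    fisher.test(tb)$p.value
  }, numeric(1))
  data.frame(marker = marker, pos = rep_len(pos, m),
             freq_early = alt_e / tot_e, freq_late = alt_l / tot_l,
             p_value = p)
}

#' Run the full delta-f scan on a SNP pool table
#'
#' Composes the mapping stage: frequency computation, LOESS smoothing of
#' both pools, the delta-f difference, interval/peak calling and optional
#' bootstrap bands.  Filtering with [filter_snps()] is left to the caller
#' (simulated tables are pre-filtered by construction).
#'
#' @param tab SNP pool table with positive depths.
#' @inheritParams loess_smooth
#' @inheritParams call_mapping_interval
#' @param band Compute bootstrap bands for both pools (slower).
#' @inheritParams bootstrap_band
#' @return A list with `profile` (a `data.frame`: `pos`, `f_early`,
#'   `f_late`, `smooth_early`, `smooth_late`, `delta_f`, and band columns if
#'   requested) and `intervals` (from [call_mapping_interval()]).
#' @export
map_delta_f <- function(tab, span = 0.75, degree = 2, threshold = 0.25,
                        band = FALSE, n_boot = 200, level = 0.95, seed = 1) {
  tab <- compute_pool_frequency(tab)
  ord <- order(tab$pos)
  tab <- tab[ord, , drop = FALSE]
  early <- smooth_pool_profile(tab$pos, tab$f_early, span = span,
                               degree = degree, band = band,
                               n_boot = n_boot, level = level, seed = seed)
  late <- smooth_pool_profile(tab$pos, tab$f_late, span = span,
                              degree = degree, band = band,
                              n_boot = n_boot, level = level,
                              seed = seed + 1L)
  dprof <- compute_delta_f(early, late)
  intervals <- call_mapping_interval(dprof, threshold = threshold,
                                     chrom = as.character(tab$chrom[1L]))
  profile <- data.frame(pos = tab$pos, f_early = tab$f_early,
                        f_late = tab$f_late,
                        smooth_early = early$smooth_f,
                        smooth_late = late$smooth_f,
                        delta_f = dprof$delta_f)
  if (band) {
    profile$band_lo_early <- early$band_lo
    profile$band_hi_early <- early$band_hi
    profile$band_lo_late <- late$band_lo
    profile$band_hi_late <- late$band_hi
  }
  list(profile = profile, intervals = intervals)
}
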