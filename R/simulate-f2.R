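#' Configuration for a simulated F2 mapping population
#'
#' Bundles the parameters of a biparental F2 (optionally once-selfed, i.e.
#' F3) cross segregating a single recessive major-effect flowering-time
#' locus, together with the pooled-sequencing design.  The defaults mirror a
#' fine-mapping experiment in which pools of 15 early and 9 late flowering
#' recombinants were sequenced at roughly 60-fold coverage over ~300 SNPs in
#' a ~1 Mb target region.
#'
#' @param n_f2 Number of F2 individuals.
#' @param genome_len Length of the simulated region in bp.
#' @param genetic_len Genetic length of the region in centimorgans.  The
#'   default of 100 cM gives one expected crossover per gamete in the
#'   region — the standard single-chromosome simulation setting, and the
#'   Poisson emulation of a fine-mapping pool in which plants were
#'   *selected* to carry a recombination breakpoint inside the mapped
#'   interval (without such enrichment a 1 Mb *Arabidopsis* window has only
#'   ~4 cM, far too few breakpoints near the locus for sub-100 kb
#'   localization; see the methods vignette).
#' @param n_snps Number of biallelic markers.  Markers are evenly spaced and
#'   the marker closest to `causal_pos` is moved onto the causal position so
#'   the causal locus is observed directly.
#' @param causal_pos Position (bp) of the causal locus.
#' @param effect_days Flowering-time advance (days) of individuals
#'   homozygous for the alternative (early) allele.  The locus is strictly
#'   recessive: heterozygotes flower like reference homozygotes.
#' @param noise_sd Standard deviation (days) of the environmental noise
#'   added to each phenotype.
#' @param base_days Baseline flowering time (days).
#' @param n_early_pool,n_late_pool Number of phenotypic-extreme individuals
#'   pooled from the early and late tail, respectively.
#' @param mean_depth Expected sequencing depth per SNP per pool.
#' @param self_generations Number of rounds of selfing applied to every
#'   individual before phenotyping/pooling (0 = pool F2 plants directly;
#'   1 approximates pooling one F3 plant per F2 family).
#' @param seed Integer seed; every simulation function in the package is a
#'   pure function of its configuration and seed.
#' @return A list of class `"f2_sim_config"`.
#' @examples
#' cfg <- f2_sim_config(n_f2 = 200, n_snps = 50, seed = 1)
#' truth <- simulate_f2_population(cfg)
#' table(truth$genotypes[, truth$causal_index])
#' @export
f2_sim_config <- function(n_f2 = 1000,
                          genome_len = 1e6,
                          genetic_len = 100,
                          n_snps = 300,
                          causal_pos = 5e5,
                          effect_days = 10,
                          noise_sd = 1,
                          base_days = 60,
                          n_early_pool = 15,
                          n_late_pool = 9,
                          mean_depth = 60,
                          self_generations = 0,
                          seed = 1) {
  check_scalar(n_f2, "n_f2", lower = 1, integer = TRUE)
  check_scalar(genome_len, "genome_len", lower = 1)
  check_scalar(genetic_len, "genetic_len", lower = 0)
  check_scalar(n_snps, "n_snps", lower = 1, integer = TRUE)
  check_scalar(causal_pos, "causal_pos", lower = 0, upper = genome_len,
               strict_lower = TRUE)
  check_scalar(effect_days, "effect_days", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(base_days, "base_days")
  check_scalar(n_early_pool, "n_early_pool", lower = 1, integer = TRUE)
  check_scalar(n_late_pool, "n_late_pool", lower = 1, integer = TRUE)
  if (n_early_pool + n_late_pool > n_f2) {
    stop("pool sizes exceed the population size", call. = FALSE)
  }
  check_scalar(mean_depth, "mean_depth", lower = 0, strict_lower = TRUE)
  check_scalar(self_generations, "self_generations", lower = 0, integer = TRUE)
  structure(
    list(n_f2 = as.integer(n_f2), genome_len = genome_len,
         genetic_len = genetic_len, n_snps = as.integer(n_snps),
         causal_pos = causal_pos, effect_days = effect_days,
         noise_sd = noise_sd, base_days = base_days,
         n_early_pool = as.integer(n_early_pool),
         n_late_pool = as.integer(n_late_pool),
         mean_depth = mean_depth,
         self_generations = as.integer(self_generations),
         seed = seed),
    class = "f2_sim_config")
}

## Draw `n_gam` gametes from heterozygous parents whose two haplotypes are
## `hapA` and `hapB` (rows index parents when matrices are given).
## Crossovers follow the Haldane model: Poisson(genetic_len/100) counts,
## uniform positions, no interference.
recombine_gametes <- function(n_gam, positions, genome_len, genetic_len,
                              hapA = NULL, hapB = NULL) {
  m <- length(positions)
  out <- matrix(0L, nrow = n_gam, ncol = m)
  n_xo <- rpois(n_gam, genetic_len / 100)
  phase0 <- sample(0:1, n_gam, replace = TRUE)
  for (g in seq_len(n_gam)) {
    if (n_xo[g] == 0L) {
      src <- rep(phase0[g], m)
    } else {
      xo <- sort(runif(n_xo[g], 0, genome_len))
      src <- (phase0[g] + findInterval(positions, xo)) %% 2L
    }
    if (is.null(hapA)) {
      out[g, ] <- src                         # F1 parent: haplotypes are 0 and 1
    } else {
      a <- hapA[g, ]; b <- hapB[g, ]
      out[g, ] <- ifelse(src == 0L, a, b)
    }
  }
  out
}

#' Simulate an F2 population segregating one recessive flowering locus
#'
#' Generates `n_f2` individuals from a cross between two fully homozygous
#' parents (reference allele coded 0, alternative allele coded 1 at every
#' marker).  Each gamete recombines the two parental haplotypes with a
#' Poisson number of crossovers (`genetic_len`/100 expected) at uniform
#' positions (Haldane map function, no interference).  Flowering time is
#' `base_days - effect_days` for individuals homozygous for the alternative
#' allele at the causal locus, plus `Normal(0, noise_sd)` noise.
#'
#' @param cfg An [f2_sim_config()] object.
#' @return A list of class `"f2_truth"` with elements `positions` (bp),
#'   `causal_index`, `causal_pos`, `haplotypes` (a list of two `n_f2` x
#'   `n_snps` 0/1 matrices), `genotypes` (`n_f2` x `n_snps` matrix of
#'   alternative-allele copies 0/1/2) and `phenotype` (days).
#' @export
simulate_f2_population <- function(cfg) {
  stopifnot(inherits(cfg, "f2_sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_snps
    positions <- round(seq(from = cfg$genome_len / (m + 1),
                           by = cfg$genome_len / (m + 1), length.out = m))
    positions[which.min(abs(positions - cfg$causal_pos))] <- cfg$causal_pos
    positions <- sort(positions)
    causal_index <- which(positions == cfg$causal_pos)[1L]

    hap1 <- recombine_gametes(cfg$n_f2, positions, cfg$genome_len, cfg$genetic_len)
    hap2 <- recombine_gametes(cfg$n_f2, positions, cfg$genome_len, cfg$genetic_len)
    if (cfg$self_generations > 0L) {
      for (i in seq_len(cfg$self_generations)) {
        new1 <- recombine_gametes(cfg$n_f2, positions, cfg$genome_len,
                                  cfg$genetic_len, hap1, hap2)
        new2 <- recombine_gametes(cfg$n_f2, positions, cfg$genome_len,
                                  cfg$genetic_len, hap1, hap2)
        hap1 <- new1; hap2 <- new2
      }
    }
    geno <- hap1 + hap2
    pheno <- cfg$base_days -
      cfg$effect_days * (geno[, causal_index] == 2L) +
      rnorm(cfg$n_f2, 0, cfg$noise_sd)
    structure(
      list(positions = positions, causal_index = causal_index,
           causal_pos = cfg$causal_pos,
           haplotypes = list(hap1, hap2),
           genotypes = geno, phenotype = pheno),
      class = "f2_truth")
  })
}

#' Pool phenotypic extremes and draw pooled sequencing counts
#'
#' Selects the `n_early_pool` earliest- and `n_late_pool` latest-flowering
#' individuals, computes the true alternative-allele frequency of each pool
#' at every marker, and draws sequencing counts: per SNP and pool the depth
#' is Poisson(`mean_depth`) and the alternative-read count is
#' Binomial(depth, pool frequency).  Sequencing error is folded into the
#' binomial sampling; the scan statistic operates on called allele counts.
#'
#' @param truth An `"f2_truth"` object from [simulate_f2_population()].
#' @param cfg The [f2_sim_config()] used to generate it.
#' @param analytic If `TRUE`, skip read sampling and report the true pool
#'   frequencies in `f_early`/`f_late` (the infinite-depth limit); the count
#'   columns are `NA`.
#' @return A `data.frame` with one row per SNP and columns `chrom`, `pos`,
#'   `ref`, `alt`, `depth_early`, `alt_early`, `depth_late`, `alt_late`,
#'   `parental_alt_freq` (1.0: the alternative parent is homozygous),
#'   `called_in_both`, plus truth columns `p_early`, `p_late` (true pool
#'   frequencies) and, in analytic mode, `f_early`, `f_late`.
#' @export
pool_and_count <- function(truth, cfg, analytic = FALSE) {
  stopifnot(inherits(truth, "f2_truth"), inherits(cfg, "f2_sim_config"))
  check_flag(analytic, "analytic")
  if (cfg$n_early_pool < 1L || cfg$n_late_pool < 1L) {
    stop("both pools must contain at least one individual", call. = FALSE)
  }
  ord <- order(truth$phenotype)
  early <- ord[seq_len(cfg$n_early_pool)]
  late <- rev(ord)[seq_len(cfg$n_late_pool)]
  p_early <- colSums(truth$genotypes[early, , drop = FALSE]) /
    (2 * cfg$n_early_pool)
  p_late <- colSums(truth$genotypes[late, , drop = FALSE]) /
    (2 * cfg$n_late_pool)
  m <- length(truth$positions)

  tab <- with_seed(cfg$seed + 1L, {
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE),
                      ncol = 2)
    same <- alleles[, 1] == alleles[, 2]
    alleles[same, 2] <- vapply(alleles[same, 1], function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1))
    if (analytic) {
      data.frame(chrom = "sim1", pos = truth$positions,
                 ref = alleles[, 1], alt = alleles[, 2],
                 depth_early = NA_integer_, alt_early = NA_integer_,
                 depth_late = NA_integer_, alt_late = NA_integer_,
                 parental_alt_freq = 1.0, called_in_both = TRUE,
                 p_early = p_early, p_late = p_late,
                 f_early = p_early, f_late = p_late)
    } else {
      depth_early <- rpois(m, cfg$mean_depth)
      depth_late <- rpois(m, cfg$mean_depth)
      data.frame(chrom = "sim1", pos = truth$positions,
                 ref = alleles[, 1], alt = alleles[, 2],
                 depth_early = depth_early,
                 alt_early = rbinom(m, depth_early, p_early),
                 depth_late = depth_late,
                 alt_late = rbinom(m, depth_late, p_late),
                 parental_alt_freq = 1.0, called_in_both = TRUE,
                 p_early = p_early, p_late = p_late)
    }
  })
  attr(tab, "pools") <- list(early = early, late = late)
  tab
}
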