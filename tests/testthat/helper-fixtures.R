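# Small fixtures built in code.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

small_cfg <- function(...) {
  defaults <- list(n_f2 = 200, genome_len = 1e6, genetic_len = 100,
                   n_snps = 50, causal_pos = 5e5, effect_days = 10,
                   noise_sd = 1, n_early_pool = 15, n_late_pool = 9,
                   mean_depth = 60, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(f2_sim_config, args)
}

toy_snp_table <- function() {
  data.frame(chrom = "1", pos = c(100, 200, 300),
             ref = c("A", "C", "G"), alt = c("T", "G", "A"),
             depth_early = c(60L, 50L, 40L), alt_early = c(30L, 10L, 40L),
             depth_late = c(55L, 45L, 60L), alt_late = c(5L, 40L, 0L),
             parental_alt_freq = c(1, 0.95, 1),
             called_in_both = c(TRUE, TRUE, TRUE))
}
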