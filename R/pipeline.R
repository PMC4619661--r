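pipeline_defaults <- function() {
  list(
    stages = c("simulate_pools", "mapdelta"),
    seed = 1,
    out_dir = ".",
    verbose = TRUE,
    f2 = list(),                       # overrides for f2_sim_config()
    filter = list(cov_min = 30, cov_max = 120, min_freq = 0.20,
                  parental_min = 0.80, apply = FALSE),
    mapdelta = list(span = 0.75, degree = 2, threshold = 0.25,
                    band = FALSE, n_boot = 200),
    snp_table = NULL,                  # path: use a file instead of simulating
    reads = list(ref_len = 600, insert_len = 600, insertion_pos = 300,
                 read_len = 100, depth = 20, error_rate = 0.005,
                 carrier = TRUE),
    genotype = list(flank = 140, max_diff_frac = 0.05, min_reads = 2,
                    dedup = FALSE),
    coverage = list(gene_length = 1400, n_reps = 3, base_depth = 100,
                    termination_fraction = 0.8, termination_pos = 200,
                    noise = 0.05),
    exons = NULL,                      # data.frame(start, end) for exonusage
    ct = list(fold_changes = c(calibrator = 1, sample = 0.125),
              target_gene = "target", reference_gene = "ACT8",
              n_reps = 3, ct_noise_sd = 0.1),
    phenotype = list(n = 50, slope = -10, intercept = 60, noise_sd = 1),
    age = list(k = 2, L = 5700, mu = c(6e-9, 7e-9), gen_per_year = c(1, 3))
  )
}

known_stages <- c("simulate_pools", "mapdelta", "simulate_reads", "genotype",
                  "simulate_coverage", "exonusage", "simulate_ct", "ddct",
                  "simulate_phenotype", "correlate", "age")

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults.  Unknown keys — at the
#' top level or within a stage block — are rejected, as are parameters
#' outside their documented ranges, before any stage runs.
#'
#' @param config A named list of overrides, or a path to a YAML file
#'   containing one.
#' @param ... Further overrides applied on top (e.g. `seed = 7`); these win
#'   over the file.
#' @return A validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  merge_block <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    base[names(user)] <- user
    base
  }
  overrides <- list(...)
  for (extra in list(config, overrides)) {
    unknown <- setdiff(names(extra), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (key in names(extra)) {
      if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
        defaults[[key]] <- merge_block(defaults[[key]], extra[[key]], key)
      } else {
        defaults[[key]] <- extra[[key]]
      }
    }
  }
  cfg <- defaults
  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  check_scalar(cfg$seed, "seed", integer = TRUE)
  check_scalar(cfg$mapdelta$threshold, "mapdelta$threshold",
               lower = -1, upper = 1)
  check_scalar(cfg$mapdelta$span, "mapdelta$span", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(cfg$filter$cov_min, "filter$cov_min", lower = 0)
  check_scalar(cfg$filter$cov_max, "filter$cov_max",
               lower = cfg$filter$cov_min)
  check_scalar(cfg$genotype$max_diff_frac, "genotype$max_diff_frac",
               lower = 0, upper = 1)
  check_scalar(cfg$genotype$min_reads, "genotype$min_reads", lower = 1,
               integer = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Write stage results to disk with a checksummed manifest
#'
#' Writes each named result in the field's standard format — SNP pool
#' tables as TSV + VCF, delta-f scans as a profile TSV and a BED of
#' intervals, reads as FASTQ plus a truth TSV, coverage as one bedGraph per
#' replicate, Ct/phenotype tables and calls as TSV — and a
#' `manifest.json` listing every file with its MD5 checksum.
#'
#' @param results Named list of stage results.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory ", out_dir, " is not writable", call. = FALSE)
  }
  files <- character()
  emit <- function(path) files <<- c(files, path)
  for (name in names(results)) {
    x <- results[[name]]
    base <- file.path(out_dir, name)
    if (is.data.frame(x) && all(c("depth_early", "alt_early") %in% names(x))) {
      emit(write_snp_tsv(x, paste0(base, ".tsv")))
      emit(write_snp_vcf(x, paste0(base, ".vcf")))
    } else if (is.list(x) && !is.data.frame(x) &&
               all(c("profile", "intervals") %in% names(x))) {
      write.table(x$profile, paste0(base, "_profile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(paste0(base, "_profile.tsv"))
      emit(write_bed_intervals(x$intervals, paste0(base, "_intervals.bed")))
    } else if (is.data.frame(x) && all(c("read_id", "seq") %in% names(x))) {
      emit(write_fastq(x, paste0(base, ".fastq")))
      truth <- x[, setdiff(names(x), "seq"), drop = FALSE]
      write.table(truth, paste0(base, "_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(paste0(base, "_truth.tsv"))
    } else if (inherits(x, "coverage_profiles") ||
               (is.matrix(x) && is.numeric(x))) {
      for (r in seq_len(nrow(x))) {
        p <- paste0(base, "_rep", r, ".bedGraph")
        emit(write_bedgraph(x[r, ], p))
      }
    } else if (inherits(x, "insertion_call")) {
      df <- data.frame(sample = x$sample, support_left = x$support_left,
                       support_right = x$support_right, present = x$present)
      write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(paste0(base, ".tsv"))
    } else if (inherits(x, "allele_age")) {
      jsonlite::write_json(x[c("k", "L", "mu", "gen_per_year", "gen_lo",
                               "gen_hi", "years_lo", "years_hi",
                               "unresolved")],
                           paste0(base, ".json"), auto_unbox = TRUE,
                           digits = NA)
      emit(paste0(base, ".json"))
    } else if (inherits(x, "exon_usage")) {
      df <- data.frame(replicate = rownames(x$counts), x$counts,
                       ratio_exon1 = x$ratio_exon1)
      write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(paste0(base, ".tsv"))
    } else if (inherits(x, "flowering_regression")) {
      jsonlite::write_json(unclass(x), paste0(base, ".json"),
                           auto_unbox = TRUE, digits = NA)
      emit(paste0(base, ".json"))
    } else if (is.data.frame(x)) {
      write.table(x, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(paste0(base, ".tsv"))
    } else {
      jsonlite::write_json(x, paste0(base, ".json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      emit(paste0(base, ".json"))
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order, passing intermediate
#' results forward: `simulate_pools` feeds `mapdelta`; `simulate_reads`
#' feeds `genotype`; `simulate_coverage` feeds `exonusage`; `simulate_ct`
#' feeds `ddct`; `simulate_phenotype` feeds `correlate`; `age` is
#' self-contained.  A stage whose input stage was not selected (and for
#' which no input file is configured) raises a configuration error before
#' anything runs.  All randomness derives from the single configured seed.
#'
#' @param config A [pipeline_config()] (or a list/YAML path coerced by it).
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return A list: `status` (0 on success), `results` (named list of stage
#'   results), `manifest` (file/checksum data.frame).  A JSON run record
#'   (`run_record.json`) with stage parameters, seed and record counts is
#'   written next to the outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  stages <- unique(config$stages)
  say <- function(...) if (isTRUE(config$verbose)) {
    message(sprintf(...))
  }

  needs <- c(mapdelta = "simulate_pools", genotype = "simulate_reads",
             exonusage = "simulate_coverage", ddct = "simulate_ct",
             correlate = "simulate_phenotype")
  for (st in intersect(names(needs), stages)) {
    if (!needs[[st]] %in% stages &&
        !(st == "mapdelta" && !is.null(config$snp_table))) {
      stop("stage '", st, "' requires stage '", needs[[st]],
           "' (or a configured input file)", call. = FALSE)
    }
  }

  results <- list()
  ordered <- intersect(known_stages, stages)
  for (st in ordered) {
    say("[%s] starting (seed %d)", st, config$seed)
    results <- switch(st,
      simulate_pools = {
        f2cfg <- do.call(f2_sim_config, c(config$f2, list(seed = config$seed)))
        truth <- simulate_f2_population(f2cfg)
        tab <- pool_and_count(truth, f2cfg)
        say("[simulate_pools] %d SNPs, %d individuals", nrow(tab), f2cfg$n_f2)
        c(results, list(snp_pools = tab, f2_config = NULL,
                        .f2cfg = f2cfg, .truth = truth))
      },
      mapdelta = {
        tab <- if (!is.null(config$snp_table)) {
          read_snp_table(config$snp_table)
        } else results$snp_pools
        if (isTRUE(config$filter$apply)) {
          tab <- filter_snps(tab, config$filter$cov_min, config$filter$cov_max,
                             config$filter$min_freq, config$filter$parental_min)
        }
        md <- config$mapdelta
        scan <- map_delta_f(tab, span = md$span, degree = md$degree,
                            threshold = md$threshold, band = md$band,
                            n_boot = md$n_boot, seed = config$seed)
        say("[mapdelta] %d interval(s) above delta-f %.2f",
            nrow(scan$intervals), md$threshold)
        c(results, list(mapdelta = scan))
      },
      simulate_reads = {
        rc <- config$reads
        seqs <- with_seed(config$seed, {
          list(ref = paste(sample(c("A", "C", "G", "T"), rc$ref_len,
                                  replace = TRUE), collapse = ""),
               ins = paste(sample(c("A", "C", "G", "T"), rc$insert_len,
                                  replace = TRUE), collapse = ""))
        })
        reads <- simulate_breakpoint_reads(seqs$ref, seqs$ins,
                                           rc$insertion_pos,
                                           read_len = rc$read_len,
                                           depth = rc$depth,
                                           error_rate = rc$error_rate,
                                           carrier = rc$carrier,
                                           seed = config$seed + 1L)
        say("[simulate_reads] %d reads", nrow(reads))
        c(results, list(reads = reads, .ref = seqs$ref, .ins = seqs$ins,
                        .insertion_pos = rc$insertion_pos))
      },
      genotype = {
        gc <- config$genotype
        call <- genotype_insertion(results$reads, results$.ref, results$.ins,
                                   results$.insertion_pos, flank = gc$flank,
                                   max_diff_frac = gc$max_diff_frac,
                                   min_reads = gc$min_reads,
                                   dedup = gc$dedup)
        say("[genotype] %s (left %d, right %d)",
            if (call$present) "present" else "absent",
            call$support_left, call$support_right)
        c(results, list(insertion_call = call))
      },
      simulate_coverage = {
        cc <- config$coverage
        prof <- simulate_coverage_profiles(cc$gene_length, cc$n_reps,
                                           cc$base_depth,
                                           cc$termination_fraction,
                                           cc$termination_pos, cc$noise,
                                           seed = config$seed)
        c(results, list(coverage = prof))
      },
      exonusage = {
        ex <- config$exons
        if (is.null(ex)) {
          len <- config$coverage$gene_length
          bounds <- round(seq(1, len + 1, length.out = 8))
          ex <- data.frame(start = bounds[-8], end = bounds[-1] - 1)
        }
        model <- gene_model("gene", ex)
        usage <- exon_usage(results$coverage, model)
        say("[exonusage] exon-1 ratio %.3f +/- %.3f", usage$mean, usage$sd)
        c(results, list(exon_usage = usage))
      },
      simulate_ct = {
        tc <- config$ct
        ct <- simulate_ct_table(tc$fold_changes, tc$target_gene,
                                tc$reference_gene, n_reps = tc$n_reps,
                                ct_noise_sd = tc$ct_noise_sd,
                                seed = config$seed)
        c(results, list(ct_table = ct))
      },
      ddct = {
        fold <- ddct_relative_expression(results$ct_table,
                                         config$ct$target_gene)
        c(results, list(ddct = fold))
      },
      simulate_phenotype = {
        pc <- config$phenotype
        pairs <- simulate_expression_phenotype(pc$n, pc$slope, pc$intercept,
                                               pc$noise_sd,
                                               seed = config$seed)
        c(results, list(phenotype = pairs))
      },
      correlate = {
        reg <- regress_flowering_on_expression(results$phenotype)
        say("[correlate] slope %.2f, R^2 %.3f", reg$slope, reg$r_squared)
        c(results, list(regression = reg))
      },
      age = {
        ac <- config$age
        est <- estimate_allele_age(ac$k, ac$L, ac$mu, ac$gen_per_year)
        c(results, list(allele_age = est))
      })
  }
  public <- results[!startsWith(names(results), ".") &
                      !vapply(results, is.null, logical(1))]
  manifest <- write_outputs(public, out_dir)
  record <- list(seed = config$seed, stages = ordered,
                 parameters = unclass(config)[setdiff(names(config),
                                                      c("stages", "seed"))],
                 record_counts = lapply(public, function(x)
                   if (is.data.frame(x)) nrow(x)
                   else if (is.matrix(x)) nrow(x) else 1L))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  list(status = 0L, results = public, manifest = manifest)
}
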