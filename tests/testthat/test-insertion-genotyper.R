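test_that("breakpoint targets are the spliced flank sequences", {
  ref <- "AAAACCCCGGGGTTTT"     # 16 bp
  ins <- "ACGTACGT"             # 8 bp
  tg <- build_breakpoint_targets(ref, ins, insertion_pos = 8, flank = 4)
  # left: ref[5..8] + ins[1..4]; right: ins[5..8] + ref[9..12]
  expect_equal(tg$left$sequence, paste0("CCCC", "ACGT"))
  expect_equal(tg$right$sequence, paste0("ACGT", "GGGG"))
  expect_equal(tg$left$junction_offset, 4)
  expect_equal(tg$right$junction_offset, 4)

  # generic check against direct substring arithmetic
  r <- random_dna(400, seed = 1); i <- random_dna(300, seed = 2)
  tg2 <- build_breakpoint_targets(r, i, insertion_pos = 200, flank = 140)
  expect_equal(tg2$left$sequence,
               paste0(substr(r, 61, 200), substr(i, 1, 140)))
  expect_equal(tg2$right$sequence,
               paste0(substr(i, 161, 300), substr(r, 201, 340)))
  expect_equal(nchar(tg2$left$sequence), 280)
})

test_that("target construction rejects insufficient flanks", {
  r <- random_dna(100, seed = 3); i <- random_dna(100, seed = 4)
  expect_error(build_breakpoint_targets(r, i, 10, flank = 20), "5' reference")
  expect_error(build_breakpoint_targets(r, i, 90, flank = 20), "3' reference")
  expect_error(build_breakpoint_targets(r, i, 50, flank = 120),
               "5' reference")
  expect_error(build_breakpoint_targets(r, substr(i, 1, 10), 50, flank = 20),
               "shorter than")
  expect_error(build_breakpoint_targets(r, i, 200, flank = 10), "outside")
})

test_that("semi-global aligner matches the exhaustive substring oracle", {
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:30) {
    m <- sample(30:60, 1)
    subject <- paste(sample(bases, m, replace = TRUE), collapse = "")
    pl <- sample(6:15, 1)
    pattern <- if (rep %% 2 == 0) {
      # embed a mutated substring so low costs are exercised
      s0 <- sample(m - pl, 1)
      p <- strsplit(substr(subject, s0 + 1, s0 + pl), "")[[1]]
      j <- sample(pl, 1)
      p[j] <- sample(setdiff(bases, p[j]), 1)
      paste(p, collapse = "")
    } else {
      paste(sample(bases, pl, replace = TRUE), collapse = "")
    }
    got <- sweepmap:::align_semiglobal(pattern, subject)
    want <- oracle_semiglobal(pattern, subject)
    expect_equal(unname(got[1, "cost"]), want$cost)
    expect_equal(unname(got[1, "n_best"]), want$n_best_ends)
  }
})

test_that("exact junction reads map at the constructed offset", {
  r <- random_dna(600, seed = 11); i <- random_dna(600, seed = 12)
  tg <- build_breakpoint_targets(r, i, insertion_pos = 300, flank = 140)
  read <- substr(tg$left$sequence, 91, 190)    # 0-based start 90
  aln <- map_reads_to_targets(c(jr = read), tg)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$target, "left")
  expect_equal(aln$strand, "+")
  expect_equal(aln$start, 90)
  expect_equal(aln$edit_distance, 0)
  expect_true(aln$unique)

  aln <- classify_core_reads(aln, tg)
  expect_equal(aln$junction_read_offset, 140 - 90)
  expect_true(aln$core)
})

test_that("reverse-complement reads map on the minus strand, same offset", {
  r <- random_dna(600, seed = 13); i <- random_dna(600, seed = 14)
  tg <- build_breakpoint_targets(r, i, insertion_pos = 300, flank = 140)
  fwd <- substr(tg$right$sequence, 101, 200)   # 0-based start 100
  rc <- oracle_revcomp(fwd)
  a_f <- classify_core_reads(map_reads_to_targets(c(x = fwd), tg), tg)
  a_r <- classify_core_reads(map_reads_to_targets(c(x = rc), tg), tg)
  expect_equal(a_r$target, "right")
  expect_equal(a_r$strand, "-")
  expect_equal(a_r$start, a_f$start)
  expect_equal(a_r$edit_distance, 0)
  expect_equal(a_r$core, a_f$core)
})

test_that("edit budget is floor(0.05 * read length) and zero rejects mismatches", {
  r <- random_dna(600, seed = 15); i <- random_dna(600, seed = 16)
  tg <- build_breakpoint_targets(r, i, insertion_pos = 300, flank = 140)
  read <- strsplit(substr(tg$left$sequence, 91, 190), "")[[1]]
  read[50] <- setdiff(c("A", "C", "G", "T"), read[50])[1]
  mm1 <- paste(read, collapse = "")
  expect_equal(nrow(map_reads_to_targets(mm1, tg, max_diff_frac = 0)), 0)
  aln <- map_reads_to_targets(mm1, tg)
  expect_equal(nrow(aln), 1)
  expect_lte(aln$edit_distance, 1)

  # six scattered substitutions exceed the default budget of 5 for 100 bp
  read6 <- strsplit(substr(tg$left$sequence, 91, 190), "")[[1]]
  for (j in c(10, 25, 40, 55, 70, 85)) {
    read6[j] <- setdiff(c("A", "C", "G", "T"), read6[j])[1]
  }
  expect_equal(nrow(map_reads_to_targets(paste(read6, collapse = ""), tg)), 0)
})

test_that("repetitive reads are flagged as non-unique", {
  flankL <- paste(rep("ACGT", 35), collapse = "")   # 140 bp periodic
  refR <- random_dna(140, seed = 17)
  ref <- paste0(flankL, refR)
  ins <- random_dna(200, seed = 18)
  tg <- build_breakpoint_targets(ref, ins, insertion_pos = 140, flank = 140)
  read <- paste(rep("ACGT", 6), collapse = "")      # occurs many times
  aln <- map_reads_to_targets(read, tg)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$edit_distance, 0)
  expect_gt(aln$n_best, 1)
  expect_false(aln$unique)
})

test_that("core rule selects exactly the inner-half junction offsets", {
  r <- random_dna(600, seed = 19); i <- random_dna(600, seed = 20)
  tg <- build_breakpoint_targets(r, i, insertion_pos = 300, flank = 140)
  offs <- -5:105
  aln <- data.frame(read_id = paste0("r", seq_along(offs)),
                    target = "left", strand = "+",
                    start = 140L - offs, read_len = 100L,
                    edit_distance = 0L, n_best = 1L, unique = TRUE)
  cl <- classify_core_reads(aln, tg)
  expect_equal(cl$junction_read_offset, offs)
  expect_equal(offs[cl$core], 25:75)

  # odd read length: L = 10 gives core offsets ceil(2.5)..floor(7.5) = 3..7
  aln$read_len <- 10L
  cl10 <- classify_core_reads(aln, tg)
  expect_equal(offs[cl10$core], 3:7)
})

test_that("reads that do not span the junction are never core", {
  r <- random_dna(600, seed = 21); i <- random_dna(600, seed = 22)
  tg <- build_breakpoint_targets(r, i, insertion_pos = 300, flank = 140)
  # read fully inside the reference flank of the left target
  flank_read <- substr(tg$left$sequence, 11, 110)
  # read fully inside the insertion part of the right target
  ins_read <- substr(tg$right$sequence, 21, 120)
  cl <- classify_core_reads(
    map_reads_to_targets(c(a = flank_read, b = ins_read), tg), tg)
  expect_equal(nrow(cl), 2)
  expect_false(any(cl$core))
})

test_that("presence calls require min_reads at both breakpoints", {
  mk <- function(n_left, n_right) {
    data.frame(read_id = paste0("r", seq_len(n_left + n_right)),
               target = rep(c("left", "right"), c(n_left, n_right)),
               strand = "+", start = seq_len(n_left + n_right) + 50L,
               read_len = 100L, edit_distance = 0L, n_best = 1L,
               unique = TRUE, junction_read_offset = 50L, core = TRUE)
  }
  call <- call_insertion_presence(mk(2, 2))
  expect_true(call$present)
  expect_equal(call$support_left, 2)
  expect_equal(call$support_right, 2)
  # one-sided support is not enough, however deep
  expect_false(call_insertion_presence(mk(1, 5))$present)
  expect_false(call_insertion_presence(mk(5, 0))$present)
  # monotone in min_reads
  expect_true(call_insertion_presence(mk(3, 3), min_reads = 3)$present)
  expect_false(call_insertion_presence(mk(3, 3), min_reads = 4)$present)
  # non-unique or non-core reads never count
  a <- mk(2, 2); a$unique[1] <- FALSE; a$core[3] <- FALSE
  c2 <- call_insertion_presence(a)
  expect_equal(c2$support_left, 1)
  expect_equal(c2$support_right, 1)
  expect_false(c2$present)
  # empty input
  e <- call_insertion_presence(classify_core_reads(
    sweepmap:::empty_alignment_df(),
    build_breakpoint_targets(random_dna(100, seed = 1),
                             random_dna(100, seed = 2), 50, flank = 20)))
  expect_false(e$present)
  expect_equal(e$support_left + e$support_right, 0)
})

test_that("duplicate placements collapse under dedup", {
  a <- data.frame(read_id = paste0("r", 1:6),
                  target = rep(c("left", "right"), each = 3),
                  strand = "+", start = c(60L, 60L, 61L, 70L, 70L, 70L),
                  read_len = 100L, edit_distance = 0L, n_best = 1L,
                  unique = TRUE, junction_read_offset = 70L, core = TRUE)
  no_dd <- call_insertion_presence(a)
  dd <- call_insertion_presence(a, dedup = TRUE)
  expect_equal(c(no_dd$support_left, no_dd$support_right), c(3, 3))
  expect_equal(c(dd$support_left, dd$support_right), c(2, 1))
  expect_true(no_dd$present)
  expect_false(dd$present)
})

test_that("carrier and non-carrier samples genotype correctly end to end", {
  r <- random_dna(600, seed = 31); i <- random_dna(600, seed = 32)
  reads_c <- simulate_breakpoint_reads(r, i, 300, carrier = TRUE, seed = 41)
  reads_n <- simulate_breakpoint_reads(r, i, 300, carrier = FALSE, seed = 42)
  gc <- genotype_insertion(reads_c, r, i, 300, sample = "carrier")
  gn <- genotype_insertion(reads_n, r, i, 300, sample = "noncarrier")
  expect_true(gc$present)
  expect_false(gn$present)
  expect_gte(gc$support_left, 2)
  expect_gte(gc$support_right, 2)
  expect_equal(gn$support_left + gn$support_right, 0)
  expect_s3_class(attr(gc, "alignments"), "data.frame")
  expect_output(print(gc), "PRESENT")
  expect_output(print(gn), "absent")
})

test_that("genotyping is deterministic and read-order invariant", {
  r <- random_dna(600, seed = 33); i <- random_dna(600, seed = 34)
  reads <- simulate_breakpoint_reads(r, i, 300, carrier = TRUE, seed = 43)
  g1 <- genotype_insertion(reads, r, i, 300)
  g2 <- genotype_insertion(reads, r, i, 300)
  expect_identical(unclass(g1)[], unclass(g2)[])
  set.seed(7)
  shuf <- reads[sample(nrow(reads)), ]
  g3 <- genotype_insertion(shuf, r, i, 300)
  expect_equal(g3$support_left, g1$support_left)
  expect_equal(g3$support_right, g1$support_right)
  expect_equal(g3$present, g1$present)
})

test_that("reads longer than the targets are skipped with a warning", {
  r <- random_dna(400, seed = 35); i <- random_dna(400, seed = 36)
  tg <- build_breakpoint_targets(r, i, 200, flank = 60)   # targets 120 bp
  long_read <- random_dna(150, seed = 37)
  ok_read <- substr(tg$left$sequence, 21, 120)
  expect_warning(aln <- map_reads_to_targets(c(a = long_read, b = ok_read), tg),
                 "skipped")
  expect_equal(aln$read_id, "b")
})
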