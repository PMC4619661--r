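test_that("gene models validate exon structure", {
  ex <- data.frame(start = c(1, 11, 31), end = c(8, 20, 40))
  gm <- gene_model("G1", ex)
  expect_equal(gm$exons$label, c("exon1", "exon2", "exon3"))
  expect_equal(sweepmap:::gene_span(gm), 40)
  expect_error(gene_model("G", data.frame(start = 5, end = 2)), "end before")
  expect_error(gene_model("G", data.frame(start = c(1, 5), end = c(10, 20))),
               "non-overlapping")
})

test_that("normalize_profile scales by the maximum", {
  expect_equal(normalize_profile(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_profile(c(0, 0, 0)), c(0, 0, 0))
  m <- rbind(a = c(1, 2), b = c(5, 10))
  expect_equal(unname(normalize_profile(m)),
               rbind(c(0.5, 1), c(0.5, 1)))
  expect_error(normalize_profile(numeric()), "empty")
  expect_error(normalize_profile(c(1, -1)), "negative")
})

test_that("replicate_band matches hand-computed type-7 quantiles", {
  # three replicates at one position with raw values 3, 6, 9
  m <- cbind(c(3, 6, 9))
  bd <- replicate_band(m, normalize = "none")
  # type-7: q(0.05) = x1 + 0.1 (x2 - x1); q(0.95) = x2 + 0.9 (x3 - x2)
  expect_equal(bd$mean, 6)
  expect_equal(bd$q05, 3 + 0.1 * 3)
  expect_equal(bd$q95, 6 + 0.9 * 3)

  # shared normalization divides all replicates by max of the mean profile
  m2 <- rbind(c(10, 20), c(30, 40))     # mean profile (20, 30), max 30
  bs <- replicate_band(m2, normalize = "shared")
  expect_equal(bs$mean, c(20, 30) / 30)
  # per-replicate normalization rescales each row to max 1
  bp <- replicate_band(m2, normalize = "per-replicate")
  expect_equal(bp$mean, c(mean(c(10 / 20, 30 / 40)), 1))
  expect_error(replicate_band(m2[1, , drop = FALSE]), "two replicates")
})

test_that("exon usage counts and the exon-1 ratio are exact", {
  gm <- gene_model("G", data.frame(start = c(1, 5, 8), end = c(4, 7, 10)))
  prof <- rbind(rep1 = rep(1, 10),
                rep2 = c(rep(2, 4), rep(1, 6)))
  eu <- exon_usage(prof, gm)
  expect_equal(unname(eu$counts),
               rbind(c(4, 3, 3), c(8, 3, 3)))
  expect_equal(unname(eu$ratio_exon1), c(4 / 6, 8 / 6))
  expect_equal(eu$mean, mean(c(4 / 6, 8 / 6)))
  expect_equal(eu$sd, sd(c(4 / 6, 8 / 6)))

  # strong termination downstream of exon 1: ratio 6x the uniform case
  prof2 <- rbind(c(rep(6, 4), rep(1, 6)) * 2,
                 c(rep(6, 4), rep(1, 6)) * 5)   # scale-invariant per replicate
  eu2 <- exon_usage(prof2, gm)
  expect_equal(unname(eu2$ratio_exon1), c(4, 4))

  # zero downstream counts give NA with a warning
  prof3 <- rbind(c(rep(5, 4), rep(0, 6)), rep(1, 10))
  expect_warning(eu3 <- exon_usage(prof3, gm), "zero counts")
  expect_true(is.na(eu3$ratio_exon1[1]))
  expect_equal(eu3$mean, 4 / 6)
  expect_true(is.na(eu3$sd))

  expect_error(exon_usage(prof[, 1:8], gm), "beyond")
})

test_that("delta-delta-Ct matches a hand calculation", {
  tab <- data.frame(
    sample = rep(c("cal", "mut"), each = 4),
    gene = rep(rep(c("FLM", "ACT8"), each = 2), 2),
    replicate = rep(1:2, 4),
    ct = c(24.0, 24.4, 20.0, 20.2,    # cal: dCt = 4.0, 4.2
           21.6, 22.0, 20.1, 20.3))   # mut: dCt = 1.5, 1.7
  res <- ddct_relative_expression(tab, "FLM", reference_gene = "ACT8",
                                  calibrator = "cal")
  expect_equal(res$delta_ct, c(4.1, 1.6))
  expect_equal(res$ddct, c(0, -2.5))
  expect_equal(res$fold_change, c(1, 2^2.5))
  # SE: var(dCt) = 0.02 in both samples, n = 2
  se_ddct_mut <- sqrt(0.02 / 2 + 0.02 / 2)
  expect_equal(res$se[2], log(2) * 2^2.5 * se_ddct_mut)
  # the calibrator keeps its own replicate variability around fold 1
  expect_equal(res$se[1], log(2) * sqrt(0.02 / 2))

  # adding a constant to every Ct leaves all fold changes unchanged
  tab2 <- tab; tab2$ct <- tab2$ct + 3.7
  res2 <- ddct_relative_expression(tab2, "FLM", reference_gene = "ACT8",
                                   calibrator = "cal")
  expect_equal(res2$fold_change, res$fold_change)
  expect_equal(res2$se, res$se)
})

test_that("noiseless simulated Ct tables recover the true fold changes", {
  fc <- c(wt = 1, low = 0.125, high = 8)
  tab <- simulate_ct_table(fc, ct_noise_sd = 0, seed = 5)
  res <- ddct_relative_expression(tab, "target")
  expect_equal(res$fold_change[match(names(fc), res$sample)],
               unname(fc), tolerance = 1e-12)
  expect_equal(res$fold_change[res$sample == "wt"], 1)
  expect_equal(res$se, rep(0, 3), tolerance = 1e-9)
})

test_that("delta-delta-Ct input errors are caught", {
  tab <- simulate_ct_table(c(a = 1, b = 2), seed = 1)
  expect_error(ddct_relative_expression(tab, "nope"), "target gene")
  expect_error(ddct_relative_expression(tab, "target", reference_gene = "x"),
               "reference gene")
  expect_error(ddct_relative_expression(tab, "target", calibrator = "zzz"),
               "calibrator")
  drop_ref <- tab[!(tab$gene == "ACT8" & tab$sample == "b" &
                      tab$replicate == 2), ]
  expect_error(ddct_relative_expression(drop_ref, "target"), "missing")
})

test_that("isoform ratios are normalized to the reference accession", {
  tab <- data.frame(accession = c("Col-0", "X", "Y"),
                    beta_fold = c(2, 1, 4),
                    delta_fold = c(1, 2, 1))
  out <- isoform_ratio(tab)
  # raw ratios 0.5, 2, 0.25; reference scaled to 1
  expect_equal(out$ratio, c(1, 4, 0.5))
  tab$beta_fold[3] <- 0
  expect_warning(out2 <- isoform_ratio(tab), "zero/missing")
  expect_true(is.na(out2$ratio[3]))
  expect_equal(out2$ratio[1:2], c(1, 4))
  expect_error(isoform_ratio(tab, reference = "Z"), "not in table")
  tab$beta_fold[1] <- 0
  expect_error(isoform_ratio(tab), "non-positive")
})

test_that("regression matches the closed-form least-squares solution", {
  set.seed(12)
  x <- runif(40); y <- 60 - 10 * x + rnorm(40)
  fit <- regress_flowering_on_expression(expression = x, flowering = y)
  slope <- cov(x, y) / var(x)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(fit$n, 40)

  # exact line: R^2 = 1; constant response: R^2 = 0
  perf <- regress_flowering_on_expression(
    data.frame(expression = x, flowering = 2 + 3 * x))
  expect_equal(perf$r_squared, 1)
  expect_equal(perf$slope, 3, tolerance = 1e-10)
  flat <- regress_flowering_on_expression(expression = x,
                                          flowering = rep(5, 40))
  expect_equal(flat$r_squared, 0)

  expect_error(regress_flowering_on_expression(expression = x[1:2],
                                               flowering = y[1:2]), "three")
  expect_error(regress_flowering_on_expression(expression = rep(1, 10),
                                               flowering = y[1:10]),
               "zero variance")
})

test_that("simulated expression pairs hit the theoretical R-squared", {
  r2 <- vapply(1:100, function(i) {
    regress_flowering_on_expression(
      simulate_expression_phenotype(n = 200, slope = -10, noise_sd = 1,
                                    seed = 1000 + i))$r_squared
  }, numeric(1))
  theo <- (100 / 12) / (100 / 12 + 1)
  expect_lt(abs(mean(r2) - theo), 0.02)
})

test_that("Mann-Whitney test is exact for small tie-free samples", {
  g1 <- c(1.1, 1.7, 2.3, 2.9, 3.4)
  g2 <- c(5.0, 5.5, 6.1, 7.2, 8.0)
  res <- polymorphism_association(c(g1, g2), rep(c("a", "b"), each = 5))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / choose(10, 5))     # complete separation
  expect_equal(res$U, 0)
  set.seed(3)
  for (i in 1:10) {
    v1 <- rnorm(sample(3:8, 1)); v2 <- rnorm(sample(3:8, 1))
    got <- polymorphism_association(c(v1, v2),
                                    rep(1:2, c(length(v1), length(v2))))
    expect_equal(got$p_value, oracle_mw_exact(v1, v2), tolerance = 1e-12)
    expect_equal(got$p_value,
                 wilcox.test(v1, v2, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("tied small samples use exact mid-rank enumeration", {
  v <- c(1, 2, 2, 3, 5, 5, 5, 8)
  g <- c("a", "a", "b", "a", "b", "b", "a", "b")
  res <- polymorphism_association(v, g)
  expect_match(res$method, "enumeration")
  expect_equal(res$p_value, oracle_mw_exact(v[g == "a"], v[g == "b"]),
               tolerance = 1e-12)
  # identical groups: p = 1
  same <- polymorphism_association(c(1, 2, 3, 1, 2, 3),
                                   rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(8)
  v1 <- rnorm(15); v2 <- rnorm(15, 0.8)
  res <- polymorphism_association(c(v1, v2), rep(1:2, each = 15))
  expect_equal(res$method, "normal approximation")
  expect_equal(res$p_value,
               wilcox.test(v1, v2, exact = FALSE, correct = TRUE)$p.value)
})

test_that("association test input validation", {
  expect_error(polymorphism_association(1:4, rep("a", 4)), "two groups")
  expect_error(polymorphism_association(1:4, c("a", "b", "c", "a")),
               "two groups")
  expect_error(polymorphism_association(1:3, c("a", "b")), "lengths differ")
  expect_error(polymorphism_association(c(1, 2, NA), factor(c("a", "a", "b"))),
               "non-empty")
})
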