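test_that("histogram bins are half-open and centered on the 0.05 grid", {
  h <- ratio_histogram(c(1.0, 1.0, 1.0))
  expect_equal(h$frequencies[h$centers == 1.0], 1.0)
  expect_equal(sum(h$frequencies), 1.0)

  # a ratio on an edge goes to the bin on its right
  h2 <- ratio_histogram(c(0.975, 1.024999, 1.025))
  expect_equal(h2$counts[h2$centers == 1.0], 2L)
  expect_equal(h2$counts[h2$centers == 1.05], 1L)

  # capped ratios are excluded but counted
  h3 <- ratio_histogram(c(0.5, 3.0, 7.2))
  expect_equal(h3$n_capped, 2L)
  expect_equal(h3$n_included, 1L)
  expect_equal(sum(h3$frequencies), 1.0)

  # frequency normalization holds for arbitrary draws
  set.seed(4)
  for (k in 1:5) {
    h4 <- ratio_histogram(stats::rlnorm(500, 0, 0.4))
    expect_equal(sum(h4$frequencies), 1.0)
    expect_true(all(diff(h4$bin_lo) > 0))
  }

  expect_error(ratio_histogram(numeric(0)), class = "empty_input")
  expect_error(ratio_histogram(c(1, -2)), class = "domain_error")
})

test_that("the modal bin resolves ties toward 1.0 then smaller centers", {
  expect_equal(modal_bin(ratio_histogram(rep(1, 5))), 1.0)
  # 0.9 vs 1.05: 1.05 is nearer 1.0
  expect_equal(modal_bin(ratio_histogram(c(0.9, 0.9, 1.05, 1.05, 0.5))), 1.05)
  # equidistant 0.95 vs 1.05: smaller center wins
  expect_equal(modal_bin(ratio_histogram(c(0.95, 0.95, 1.05, 1.05))), 0.95)
})

test_that("simulated class peaks land within one bin of the canonical ratio", {
  # at the study dispersion (0.05) the peak region is a couple of bins
  # wide: the modal bin and its runners-up all sit next to the canonical
  # ratio, with the mode itself within two bins
  s <- sim_single(41, n = 2000, dispersion = 0.05)
  rt <- expression_ratio(s$counts, annotation = s$annotation)
  h <- ratio_histogram(rt$ratio)
  expect_lte(abs(modal_bin(h) - 1.0), 0.10 + 1e-9)
  top3 <- h$centers[order(h$frequencies, decreasing = TRUE)][1:3]
  expect_true(all(abs(top3 - 1.0) <= 0.10 + 1e-9))

  s2 <- sim_single(42, n = 4000, mix = c(inverse = 1))
  h2 <- ratio_histogram(expression_ratio(s2$counts)$ratio)
  expect_lte(abs(modal_bin(h2) - 2 / 3), 0.05 + 1e-9)

  # at low dispersion the compensated peak concentrates: >90% of the mass
  # within +/-0.1 of 1.0
  s3 <- sim_single(46, n = 10000, dispersion = 0.001, lib = 1e7,
                   baseline_log_sd = 0.5)
  r3 <- expression_ratio(s3$counts)$ratio
  expect_gt(mean(abs(r3 - 1) <= 0.1), 0.9)
})

test_that("gene response classification matches the canonical table", {
  calls <- classify_gene_response(c(1.5, 1.0, 0.44, 2 / 3, 1.25, 2.8))
  expect_equal(calls$assigned,
               c("dosage_effect", "compensated", "double_inverse", "inverse",
                 "unclassified", "unclassified"))
  # double inverse is exactly the square of inverse
  canon <- dosage_class_ratios()
  expect_identical(canon[["double_inverse"]], canon[["inverse"]]^2)
  # an exact midpoint resolves to the smaller canonical value
  mid <- (canon[["double_inverse"]] + canon[["inverse"]]) / 2
  expect_equal(classify_gene_response(mid, tolerance = 0.2)$assigned,
               "double_inverse")
  expect_error(classify_gene_response(-1), class = "domain_error")
  expect_error(classify_gene_response(numeric(0)), class = "empty_input")
})

test_that("classification recovers planted truth at low dispersion", {
  s <- sim_single(43, n = 2000,
                  mix = c(dosage_effect = 0.25, compensated = 0.25,
                          inverse = 0.25, double_inverse = 0.25),
                  dispersion = 0.001, lib = 1e7, baseline_log_sd = 0.5)
  rt <- expression_ratio(s$counts, annotation = s$annotation)
  calls <- classify_gene_response(rt$ratio, gene_id = rt$gene_id)
  acc <- mean(calls$assigned == unname(s$truth[calls$gene_id]))
  expect_gte(acc, 0.95)
})

test_that("chromosome medians split mRNA from lncRNA", {
  tab <- data.frame(gene_id = letters[1:3], chrom = "2L", biotype = "coding",
                    cpm_control = 1, cpm_case = 1,
                    ratio = c(0.5, 0.7, 0.9))
  expect_equal(chromosome_medians(tab)$median_ratio, 0.7)

  s <- sim_single(44, n = 1500)
  rt <- expression_ratio(s$counts, annotation = s$annotation)
  med <- chromosome_medians(rt)
  expect_lt(abs(med$median_ratio[med$chrom == "X"] - 1), 0.05)

  s2 <- sim_single(45, chrom = "2R", n = 1500, mix = c(inverse = 1))
  rt2 <- expression_ratio(s2$counts, annotation = s2$annotation)
  expect_lt(chromosome_medians(rt2)$median_ratio, 1)
})

test_that("histograms serialize to TSV", {
  h <- ratio_histogram(c(0.4, 0.8, 1.0, 1.2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(h, f)
  back <- read.delim(f)
  expect_equal(names(back), c("bin_lo", "bin_hi", "frequency"))
  expect_equal(sum(back$frequency), 1)
})
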