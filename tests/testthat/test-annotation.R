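test_that("GTF reading parses gene features and validates coordinates", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("3L", "src", "gene", "100", "200", ".", "+", ".",
                   'gene_id "g1"; gene_biotype "protein_coding";',
                   sep = "\t"), f)
  rec <- read_gtf(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$chrom, "3L")
  expect_equal(rec$start, 100L)
  expect_equal(rec$end, 200L)
  expect_equal(rec$strand, "+")
  expect_equal(rec$biotype, "coding")

  # empty file gives an empty annotation
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f2)
  expect_equal(nrow(read_gtf(f2)), 0L)

  # unknown biotypes map to coding with a warning
  f3 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("X", "src", "gene", "5", "9", ".", "-", ".",
                   'gene_id "g2"; gene_biotype "snoRNA";', sep = "\t"), f3)
  expect_warning(rec3 <- read_gtf(f3), "coding")
  expect_equal(rec3$biotype, "coding")

  expect_error(gene_records("g", "X", 10, 5, "+", "coding"),
               class = "validation_error")
  expect_error(gene_records("g", "X", 0, 5, "+", "coding"),
               class = "validation_error")
})

test_that("write_gtf / read_gtf round-trips simulated records", {
  ann <- generate_annotation(sim_config(genes_per_chromosome = c(X = 30, `2R` = 20),
                                        seed = 44))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  a <- ann[order(ann$gene_id), ]
  attr(a, "cis_pairs") <- NULL
  rownames(a) <- NULL
  b <- back[order(back$gene_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("positional classification follows the rule table", {
  lnc <- function(start, end, strand)
    gene_records("lnc", "2L", start, end, strand, "lncRNA")
  host <- gene_records("host", "2L", 1, 10000, "+", "coding")

  # no coding gene on the chromosome -> lincRNA
  far <- gene_records("far", "3R", 500, 900, "+", "lncRNA")
  expect_equal(classify_lncrna_position(far, host)$class, "lincRNA")
  expect_equal(classify_lncrna_position(lnc(500, 600, "-"),
                                        host[0, ])$class, "lincRNA")

  # contained, opposite strand, not spanning -> intronic
  expect_equal(classify_lncrna_position(lnc(500, 600, "-"), host)$class,
               "intronic")
  # overlapping but not contained, opposite strand -> antisense
  expect_equal(classify_lncrna_position(lnc(9500, 10500, "-"), host)$class,
               "antisense")
  # same-strand overlap -> sense (even when contained)
  expect_equal(classify_lncrna_position(lnc(9500, 10500, "+"), host)$class,
               "sense")
  expect_equal(classify_lncrna_position(lnc(500, 600, "+"), host)$class,
               "sense")
  # identical span does not count as containment
  expect_equal(classify_lncrna_position(lnc(1, 10000, "-"), host)$class,
               "antisense")
})

test_that("classification is an exhaustive partition", {
  coding <- generate_annotation(sim_config(genes_per_chromosome = c(X = 80),
                                           lncRNA_fraction = 0, seed = 3,
                                           n_cis_planted = 0))
  planted <- plant_positional_lncrnas(coding, seed = 12)
  cls <- classify_lncrna_position(planted, coding)
  expect_true(all(cls$class %in% c("lincRNA", "intronic", "antisense", "sense")))
  expect_equal(nrow(cls), nrow(planted))
})

test_that("planted positional classes round-trip exactly", {
  coding <- generate_annotation(sim_config(genes_per_chromosome = c(`3L` = 100),
                                           lncRNA_fraction = 0, seed = 8,
                                           n_cis_planted = 0))
  # a reference DEL pie breakdown: 60/37/6/4 of 107 lncRNAs
  planted <- plant_positional_lncrnas(
    coding, n_by_class = c(lincRNA = 60, intronic = 37, antisense = 6, sense = 4),
    seed = 2
  )
  truth <- attr(planted, "truth_class")
  cls <- classify_lncrna_position(planted, coding)
  expect_identical(unname(truth[cls$gene_id]), cls$class)
  smry <- positional_class_summary(cls)
  expect_equal(smry$n, c(60L, 37L, 6L, 4L))
  expect_equal(round(100 * smry$proportion, 2), c(56.07, 34.58, 5.61, 3.74))
})
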