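test_that("annotation generation honors the requested structure", {
  cfg <- sim_config(genes_per_chromosome = c(X = 10), lncRNA_fraction = 0,
                    class_mixture = list(X = c(compensated = 1)),
                    n_cis_planted = 0, n_trans_planted = 0, seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 10L)
  expect_true(all(ann$chrom == "X"))
  expect_true(all(ann$biotype == "coding"))

  # genes on a chromosome never overlap
  big <- generate_annotation(sim_config(seed = 9))
  for (chr in unique(big$chrom)) {
    d <- big[big$chrom == chr, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }

  # mitochondrial genes carry the mito biotype
  expect_true(all(big$biotype[big$chrom == "mito"] == "mito"))

  expect_error(sim_config(genes_per_chromosome = c(X = 0)),
               class = "empty_annotation")
})

test_that("planted cis pairs sit within the 10 kb window", {
  cfg <- sim_config(seed = 21, n_cis_planted = 12)
  ann <- generate_annotation(cfg)
  pairs <- attr(ann, "cis_pairs")
  expect_gte(nrow(pairs), 1L)
  for (i in seq_len(nrow(pairs))) {
    a <- ann[ann$gene_id == pairs$lncRNA_id[i], ]
    b <- ann[ann$gene_id == pairs$target_id[i], ]
    expect_identical(a$chrom, b$chrom)
    expect_identical(a$biotype, "lncRNA")
    expect_identical(b$biotype, "coding")
    gap <- max(0L, max(a$start, b$start) - min(a$end, b$end) - 1L)
    expect_identical(gap, pairs$distance[i])
    expect_lte(gap, 10000L)
  }
})

test_that("identical configs give byte-identical datasets", {
  cfg <- sim_config(genes_per_chromosome = c(`2L` = 60, X = 80),
                    n_cis_planted = 4, n_trans_planted = 4, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$truth_targets, d2$truth_targets)
  expect_identical(d1$truth_class, d2$truth_class)
})

test_that("counts recover the class ratios in the near-noise-free limit", {
  s <- sim_single(3, n = 500, mix = c(dosage_effect = 1),
                  dispersion = 1e-12, lib = 1e7)
  rt <- expression_ratio(s$counts, annotation = s$annotation)
  expect_lt(abs(mean(rt$ratio) - 1.5), 0.02)

  # convergence of the per-class mean ratio at low dispersion
  s2 <- sim_single(4, n = 2000,
                   mix = c(dosage_effect = 0.25, compensated = 0.25,
                           inverse = 0.25, double_inverse = 0.25),
                   dispersion = 0.001, lib = 1e7, baseline_log_sd = 0.5)
  rt2 <- expression_ratio(s2$counts, annotation = s2$annotation)
  canon <- dosage_class_ratios()
  for (cls in names(canon)) {
    ids <- names(s2$truth)[s2$truth == cls]
    expect_lt(abs(mean(rt2$ratio[rt2$gene_id %in% ids]) - canon[[cls]]), 0.03)
  }
})

test_that("a fully compensated genome has median ratio near 1", {
  s <- sim_single(8, n = 2000)
  rt <- expression_ratio(s$counts, annotation = s$annotation)
  expect_lt(abs(median(rt$ratio) - 1), 0.05)
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(nb_dispersion = 0), class = "config_error")
  expect_error(sim_config(library_size = -1), class = "config_error")
  expect_error(sim_config(replicates_per_group = 1), class = "config_error")
  expect_error(sim_config(class_mixture = list(X = c(compensated = 0.7))),
               class = "config_error")
  s <- sim_single(1, n = 10)
  expect_error(simulate_counts(s$annotation, s$truth[-1], s$config),
               class = "config_error")
})

test_that("latent-factor planting drives planted pairs and nothing else", {
  cfg <- sim_config(seed = 13)
  ds <- simulate_dataset(cfg)

  # latent sd 0 leaves counts untouched
  cfg0 <- sim_config(seed = 13, trans_latent_sd = 0)
  ann <- generate_annotation(cfg0)
  truth <- assign_truth_classes(ann, cfg0)
  cm <- simulate_counts(ann, truth, cfg0)
  pairs <- data.frame(lncRNA_id = ann$gene_id[1], target_id = ann$gene_id[2])
  expect_identical(plant_trans_structure(cm, pairs, cfg0)$counts, cm$counts)

  # planted pairs exceed the correlation threshold
  mat <- cpm(ds$counts, lib_sizes = ds$counts$lib_sizes)
  tp <- ds$truth_targets[ds$truth_targets$mode == "trans", ]
  found <- suppressMessages(trans_targets(
    mat[unique(tp$lncRNA_id), , drop = FALSE],
    mat[unique(tp$target_id), , drop = FALSE]
  ))
  hit <- paste(tp$lncRNA_id, tp$target_id) %in%
    paste(found$lncRNA_id, found$target_id)
  expect_gte(mean(hit), 0.9)

  expect_error(
    plant_trans_structure(cm, data.frame(lncRNA_id = "nope", target_id = "x"),
                          cfg0),
    class = "lookup_error"
  )
})

test_that("a written dataset round-trips through its text formats", {
  ds <- simulate_dataset(sim_config(genes_per_chromosome = c(X = 40, `3R` = 30),
                                    n_cis_planted = 3, n_trans_planted = 3,
                                    seed = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ann2 <- read_gtf(file.path(dir, "annotation.gtf"))
  expect_setequal(ann2$gene_id, ds$annotation$gene_id)
  cm2 <- read_counts(file.path(dir, "counts.tsv"),
                     groups = ds$counts$groups,
                     lib_sizes = ds$counts$lib_sizes)
  expect_equal(unname(cm2$counts), unname(ds$counts$counts))
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$seed, 6)
})
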