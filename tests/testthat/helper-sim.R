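# One-chromosome simulation shorthand used across test files.
sim_single <- function(seed, chrom = "X", n = 2000, mix = c(compensated = 1),
                       shift = 1, dispersion = 0.05, lib = 1e6, reps = 3,
                       baseline_log_sd = 0.8) {
  cfg <- sim_config(
    genes_per_chromosome = stats::setNames(n, chrom),
    lncRNA_fraction = 0,
    class_mixture = stats::setNames(list(mix), chrom),
    replicates_per_group = reps,
    nb_dispersion = dispersion,
    library_size = lib,
    baseline_log_sd = baseline_log_sd,
    n_cis_planted = 0, n_trans_planted = 0,
    global_shift = shift, seed = seed
  )
  ann <- generate_annotation(cfg)
  truth <- assign_truth_classes(ann, cfg)
  list(config = cfg, annotation = ann, truth = truth,
       counts = simulate_counts(ann, truth, cfg))
}

# exact-r vector pair via Gram-Schmidt (used for correlation boundary tests)
pair_with_r <- function(r, n = 6, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  z <- rnorm(n)
  z <- as.numeric(scale(stats::resid(stats::lm(z ~ x))))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
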