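#' Simulation configuration for the aneuploid two-group design
#'
#' Parameters of the synthetic transcriptome emulating a trisomic
#' (metafemale-like) vs diploid comparison: per-chromosome gene counts, a
#' minority of lncRNA genes, per-chromosome mixtures of dosage-response
#' classes (each class fixing the true case/control expression ratio, see
#' [dosage_class_ratios()]), log-normal baseline expression, shared
#' negative-binomial dispersion (`var = mu + alpha * mu^2`), planted cis
#' neighbors within 10 kb of a coding gene, planted trans partners driven
#' by a shared log-normal latent factor, and an optional global ratio
#' shift emulating a regulator-knockdown scenario.
#'
#' Default chromosome panel and mixtures qualitatively mirror a triple-X
#' fly: X mostly compensated (ratio 1), autosomes dominated by the inverse
#' dosage effect (2/3) with a double-inverse (4/9) shoulder, chromosome 4
#' tilted upward, and mitochondrial genes mostly following the dosage
#' effect (3/2) with a 4/9 shoulder.
#'
#' @param genes_per_chromosome Named integer vector, chromosome -> gene count.
#' @param lncRNA_fraction Fraction of (non-mitochondrial) genes that are
#'   lncRNAs.
#' @param class_mixture Named list: chromosome -> named proportions over
#'   dosage classes (must sum to 1).  Chromosomes without an entry default
#'   to fully compensated.
#' @param replicates_per_group Replicates per group (>= 2; default 3).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   relative baseline expression weights.
#' @param nb_dispersion Shared NB dispersion alpha (default 0.05).
#' @param library_size Total library depth per sample (default 1e6).
#' @param n_cis_planted Number of planted lncRNA-coding neighbor pairs with
#'   an interval gap <= 10 kb.
#' @param n_trans_planted Number of planted co-expressed lncRNA-coding
#'   pairs.
#' @param trans_latent_sd Log-scale SD of the shared latent factor applied
#'   to planted trans pairs (default 3; strong enough that the planted
#'   cross-sample Pearson correlation exceeds 0.95 at six samples).
#' @param global_shift Multiplicative genome-wide ratio shift applied to
#'   the case group (default 1.0; 1.3 emulates the knockdown scenario).
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genes_per_chromosome = c(`2L` = 250, `2R` = 250,
                                                `3L` = 250, `3R` = 250,
                                                `4` = 40, X = 300, mito = 15),
                       lncRNA_fraction = 0.15,
                       class_mixture = default_class_mixture(),
                       replicates_per_group = 3L,
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 0.8,
                       nb_dispersion = 0.05,
                       library_size = 1e6,
                       n_cis_planted = 20L,
                       n_trans_planted = 20L,
                       trans_latent_sd = 3,
                       global_shift = 1.0,
                       seed = 1L) {
  cfg <- list(
    genes_per_chromosome = genes_per_chromosome,
    lncRNA_fraction = lncRNA_fraction,
    class_mixture = class_mixture,
    replicates_per_group = as.integer(replicates_per_group),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    n_cis_planted = as.integer(n_cis_planted),
    n_trans_planted = as.integer(n_trans_planted),
    trans_latent_sd = trans_latent_sd,
    global_shift = global_shift,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_class_mixture <- function() {
  auto <- c(inverse = 0.60, compensated = 0.30, double_inverse = 0.10)
  list(
    `2L` = auto, `2R` = auto, `3L` = auto, `3R` = auto,
    `4` = c(compensated = 0.55, dosage_effect = 0.45),
    X = c(compensated = 0.80, dosage_effect = 0.20),
    mito = c(dosage_effect = 0.70, double_inverse = 0.30)
  )
}

validate_sim_config <- function(cfg) {
  if (length(cfg$genes_per_chromosome) == 0L ||
      is.null(names(cfg$genes_per_chromosome)))
    stop2("config_error", "genes_per_chromosome must be a named vector")
  if (any(cfg$genes_per_chromosome < 0))
    stop2("config_error", "gene counts must be >= 0")
  if (sum(cfg$genes_per_chromosome) == 0L)
    stop2("empty_annotation", "zero genes requested")
  if (cfg$lncRNA_fraction < 0 || cfg$lncRNA_fraction > 1)
    stop2("config_error", "lncRNA_fraction must be in [0, 1]")
  for (chr in names(cfg$class_mixture)) {
    mix <- cfg$class_mixture[[chr]]
    if (abs(sum(mix) - 1) > 1e-8)
      stop2("config_error", "class mixture for ", chr, " does not sum to 1")
    if (!all(names(mix) %in% names(dosage_class_ratios())))
      stop2("config_error", "unknown dosage class in mixture for ", chr)
  }
  if (cfg$replicates_per_group < 2L)
    stop2("config_error", "replicates_per_group must be >= 2")
  if (cfg$nb_dispersion <= 0)
    stop2("config_error", "nb_dispersion must be positive")
  if (cfg$library_size <= 0)
    stop2("config_error", "library_size must be positive")
  if (cfg$trans_latent_sd < 0)
    stop2("config_error", "trans_latent_sd must be >= 0")
  if (cfg$global_shift <= 0)
    stop2("config_error", "global_shift must be positive")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic gene annotation
#'
#' Lays out non-overlapping genes per chromosome (log-normal lengths and
#' intergenic gaps, 1-based inclusive coordinates, random strand), assigns
#' lncRNA biotypes at `lncRNA_fraction` (mitochondrial genes get biotype
#' `mito`), and plants `n_cis_planted` adjacent lncRNA/coding pairs whose
#' interval gap is at most 10 kb.  The planted pairs are recorded in the
#' `cis_pairs` attribute (columns `lncRNA_id`, `target_id`, `distance`).
#'
#' @param config A [sim_config()].
#' @return Annotation data.frame (see [gene_records()]) with attribute
#'   `cis_pairs`.
#' @export
generate_annotation <- function(config) {
  config <- validate_sim_config(unclass(config))
  with_seed(config$seed + 1L, {
    per_chr <- lapply(names(config$genes_per_chromosome), function(chr) {
      n <- config$genes_per_chromosome[[chr]]
      if (n == 0L) return(NULL)
      len <- pmin(pmax(round(rlnorm(n, 7.3, 0.6)), 200L), 50000L)
      gap <- pmin(pmax(round(rlnorm(n, 8.0, 0.8)), 50L), 100000L)
      biotype <- if (chr == "mito") rep("mito", n) else
        ifelse(runif(n) < config$lncRNA_fraction, "lncRNA", "coding")
      data.frame(
        gene_id = sprintf("%s_g%04d", chr, seq_len(n)),
        chrom = chr, len = len, gap = gap,
        strand = sample(c("+", "-"), n, replace = TRUE),
        biotype = biotype, stringsAsFactors = FALSE
      )
    })
    per_chr <- Filter(Negate(is.null), per_chr)
    lay <- do.call(rbind, per_chr)

    # plant cis pairs: force gene i to be an lncRNA and gene i+1 a coding
    # neighbor on the same chromosome, with a gap <= 10 kb between them
    cis_pairs <- data.frame(lncRNA_id = character(), target_id = character(),
                            distance = integer(), stringsAsFactors = FALSE)
    if (config$n_cis_planted > 0L) {
      elig <- which(lay$chrom != "mito" &
                    c(lay$chrom[-1] == lay$chrom[-nrow(lay)], FALSE))
      elig <- elig[elig %% 2L == 1L]  # avoid overlapping plant positions
      if (length(elig) > 0L) {
        take <- sort(sample(elig, min(config$n_cis_planted, length(elig))))
        lay$biotype[take] <- "lncRNA"
        lay$biotype[take + 1L] <- "coding"
        lay$gap[take + 1L] <- as.integer(round(runif(length(take), 0, 8000)))
        cis_pairs <- data.frame(
          lncRNA_id = lay$gene_id[take], target_id = lay$gene_id[take + 1L],
          distance = lay$gap[take + 1L] , stringsAsFactors = FALSE
        )
      }
    }

    out <- do.call(rbind, lapply(split(lay, lay$chrom), function(d) {
      d <- d[order(match(d$gene_id, lay$gene_id)), ]
      start <- cumsum(c(d$gap[1], d$len[-nrow(d)] + d$gap[-1])) + 1L
      # gap between consecutive closed intervals is start[i+1] - end[i] - 1
      start <- as.integer(start)
      data.frame(gene_id = d$gene_id, chrom = d$chrom, start = start,
                 end = as.integer(start + d$len - 1L), strand = d$strand,
                 biotype = d$biotype, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out <- out[order(match(out$gene_id, lay$gene_id)), ]
    rownames(out) <- NULL
    # planted distance is the intergenic gap minus 1 under closed intervals
    if (nrow(cis_pairs) > 0L) {
      m1 <- match(cis_pairs$lncRNA_id, out$gene_id)
      m2 <- match(cis_pairs$target_id, out$gene_id)
      cis_pairs$distance <- pmax(0L, out$start[m2] - out$end[m1] - 1L)
    }
    attr(out, "cis_pairs") <- cis_pairs
    validate_gene_records(out)
    out
  })
}

#' Draw per-gene dosage-response classes from the configured mixtures
#'
#' @param annotation Annotation data.frame.
#' @param config A [sim_config()].
#' @return Named character vector, gene_id -> class label.
#' @export
assign_truth_classes <- function(annotation, config) {
  with_seed(config$seed + 2L, {
    labels <- character(nrow(annotation))
    for (chr in unique(annotation$chrom)) {
      idx <- annotation$chrom == chr
      mix <- config$class_mixture[[chr]] %||% c(compensated = 1)
      labels[idx] <- sample(names(mix), sum(idx), replace = TRUE, prob = mix)
    }
    stats::setNames(labels, annotation$gene_id)
  })
}

#' Simulate negative-binomial counts for a two-group design
#'
#' Control-group expected counts are proportional to a log-normal baseline,
#' scaled so the expected control column sum equals `library_size`; the
#' case-group expectation multiplies each gene's baseline by its class
#' ratio and the `global_shift`.  Counts are drawn NB with
#' `var = mu + alpha mu^2` (Poisson when `alpha` is negligible).  The
#' nominal `library_size` is stored as the per-sample library size, so CPM
#' ratios computed against it recover `true_ratio * global_shift` rather
#' than being renormalized away by within-matrix column sums.
#'
#' @param annotation Annotation data.frame.
#' @param truth_class Named gene -> class vector (see
#'   [assign_truth_classes()]); may also carry a `custom_ratio` attribute
#'   (named numeric) overriding the canonical ratio per gene.
#' @param config A [sim_config()].
#' @return A [count_matrix()] with samples `control_1..n`, `case_1..n`.
#' @export
simulate_counts <- function(annotation, truth_class, config) {
  config <- validate_sim_config(unclass(config))
  missing <- setdiff(annotation$gene_id, names(truth_class))
  if (length(missing) > 0L)
    stop2("config_error", "no truth class for gene(s): ",
          paste(head(missing, 5L), collapse = ", "))
  canon <- dosage_class_ratios()
  ratio <- canon[truth_class[annotation$gene_id]]
  custom <- attr(truth_class, "custom_ratio")
  if (!is.null(custom)) {
    hit <- annotation$gene_id %in% names(custom)
    ratio[hit] <- custom[annotation$gene_id[hit]]
  }
  if (anyNA(ratio)) stop2("config_error", "unknown dosage class label")
  with_seed(config$seed + 3L, {
    n <- nrow(annotation)
    reps <- config$replicates_per_group
    baseline <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    prop <- baseline / sum(baseline)
    mu_ctrl <- prop * config$library_size
    mu_case <- mu_ctrl * ratio * config$global_shift
    draw <- function(mu) {
      if (config$nb_dispersion < 1e-10) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    cols <- c(
      lapply(seq_len(reps), function(i) draw(mu_ctrl)),
      lapply(seq_len(reps), function(i) draw(mu_case))
    )
    m <- do.call(cbind, cols)
    rownames(m) <- annotation$gene_id
    colnames(m) <- c(paste0("control_", seq_len(reps)),
                     paste0("case_", seq_len(reps)))
    count_matrix(
      m,
      groups = rep(c("control", "case"), each = reps),
      lib_sizes = rep(config$library_size, 2L * reps)
    )
  })
}

#' Plant co-expression structure for trans target pairs
#'
#' For every planted pair, one log-normal latent multiplier per sample
#' (`exp(N(0, trans_latent_sd))`) scales the counts of both members, so
#' their cross-sample correlation is driven toward 1 while remaining
#' independent of all other genes.  A latent SD of 0 leaves the counts
#' unchanged.
#'
#' @param counts A [count_matrix()].
#' @param truth_targets Data.frame with columns `lncRNA_id`, `target_id`.
#' @param config A [sim_config()].
#' @return A new `count_matrix` with perturbed counts.
#' @export
plant_trans_structure <- function(counts, truth_targets, config) {
  m <- counts$counts
  ids <- unique(c(truth_targets$lncRNA_id, truth_targets$target_id))
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0L)
    stop2("lookup_error", "planted pair references missing gene(s): ",
          paste(head(missing, 5L), collapse = ", "))
  if (config$trans_latent_sd == 0 || nrow(truth_targets) == 0L)
    return(counts)
  with_seed(config$seed + 4L, {
    for (i in seq_len(nrow(truth_targets))) {
      f <- exp(rnorm(ncol(m), 0, config$trans_latent_sd))
      for (g in c(truth_targets$lncRNA_id[i], truth_targets$target_id[i]))
        m[g, ] <- round(m[g, ] * f)
    }
    count_matrix(m, counts$groups, counts$lib_sizes)
  })
}

#' Simulate a complete dataset
#'
#' Chains [generate_annotation()], [assign_truth_classes()],
#' [simulate_counts()] and [plant_trans_structure()], additionally drawing
#' `n_trans_planted` disjoint lncRNA-coding pairs (distinct from the
#' planted cis pairs) as trans ground truth.  Identical configs (including
#' the seed) produce identical datasets.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `annotation`,
#'   `counts`, `truth_class`, `truth_targets` (columns `lncRNA_id`,
#'   `target_id`, `mode`, `distance`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(unclass(config))
  annotation <- generate_annotation(config)
  truth_class <- assign_truth_classes(annotation, config)
  counts <- simulate_counts(annotation, truth_class, config)
  cis <- attr(annotation, "cis_pairs")
  trans <- data.frame(lncRNA_id = character(), target_id = character(),
                      stringsAsFactors = FALSE)
  if (config$n_trans_planted > 0L) {
    used <- c(cis$lncRNA_id, cis$target_id)
    lnc_pool <- setdiff(annotation$gene_id[annotation$biotype == "lncRNA"], used)
    cod_pool <- setdiff(annotation$gene_id[annotation$biotype == "coding"], used)
    k <- min(config$n_trans_planted, length(lnc_pool), length(cod_pool))
    trans <- with_seed(config$seed + 5L, data.frame(
      lncRNA_id = sample(lnc_pool, k), target_id = sample(cod_pool, k),
      stringsAsFactors = FALSE
    ))
  }
  counts <- plant_trans_structure(counts, trans, config)
  truth_targets <- rbind(
    if (nrow(cis) > 0L) data.frame(cis[, c("lncRNA_id", "target_id")],
                                   mode = "cis", distance = cis$distance,
                                   stringsAsFactors = FALSE),
    if (nrow(trans) > 0L) data.frame(trans, mode = "trans",
                                     distance = NA_integer_,
                                     stringsAsFactors = FALSE)
  ) %||% data.frame(lncRNA_id = character(), target_id = character(),
                    mode = character(), distance = integer())
  structure(
    list(annotation = annotation, counts = counts, truth_class = truth_class,
         truth_targets = truth_targets, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d genes (%d lncRNA) on %d chromosomes; %d+%d samples; %d planted cis, %d planted trans\n",
    nrow(x$annotation), sum(x$annotation$biotype == "lncRNA"),
    length(unique(x$annotation$chrom)),
    sum(x$counts$groups == "control"), sum(x$counts$groups == "case"),
    sum(x$truth_targets$mode == "cis"), sum(x$truth_targets$mode == "trans")
  ))
  invisible(x)
}

#' Plant lncRNAs of known positional classes into an annotation
#'
#' Appends lncRNA genes constructed to have a fixed positional class
#' relative to the supplied coding genes: `lincRNA` (far from any coding
#' gene), `intronic` (strictly inside a coding gene, opposite strand),
#' `antisense` (partially overlapping a coding gene, opposite strand) and
#' `sense` (partially overlapping, same strand).  Used to validate
#' positional classification against planted ground truth.
#'
#' @param coding Annotation data.frame of coding genes.
#' @param n_by_class Named integer vector over the four class labels.
#' @param seed Integer seed.
#' @return Annotation data.frame of the planted lncRNAs with attribute
#'   `truth_class` (named character vector).
#' @export
plant_positional_lncrnas <- function(coding,
                                     n_by_class = c(lincRNA = 60, intronic = 37,
                                                    antisense = 6, sense = 4),
                                     seed = 1L) {
  stopifnot(nrow(coding) > 0)
  host_ok <- (coding$end - coding$start) >= 400L
  hosts <- coding[host_ok, ]
  if (nrow(hosts) == 0L) stop2("config_error", "no coding gene long enough to host")
  flip <- function(s) ifelse(s == "+", "-", "+")
  with_seed(seed, {
    recs <- list(); labels <- character(0); k <- 0L
    for (cls in names(n_by_class)) {
      for (j in seq_len(n_by_class[[cls]])) {
        k <- k + 1L
        h <- hosts[sample.int(nrow(hosts), 1L), ]
        rec <- switch(
          cls,
          lincRNA = {   # placed beyond every gene on a host chromosome
            far <- max(coding$end[coding$chrom == h$chrom]) + 50000L + k * 3000L
            data.frame(chrom = h$chrom, start = far, end = far + 800L,
                       strand = sample(c("+", "-"), 1L))
          },
          intronic = data.frame(chrom = h$chrom, start = h$start + 100L,
                                end = h$start + 300L, strand = flip(h$strand)),
          antisense = data.frame(chrom = h$chrom, start = h$end - 100L,
                                 end = h$end + 400L, strand = flip(h$strand)),
          sense = data.frame(chrom = h$chrom, start = h$end - 100L,
                             end = h$end + 400L, strand = h$strand)
        )
        recs[[k]] <- data.frame(gene_id = sprintf("lnc_p%04d", k), rec,
                                biotype = "lncRNA", stringsAsFactors = FALSE)
        labels[sprintf("lnc_p%04d", k)] <- cls
      }
    }
    out <- do.call(rbind, recs)[, c("gene_id", "chrom", "start", "end",
                                    "strand", "biotype")]
    rownames(out) <- NULL
    attr(out, "truth_class") <- labels
    out
  })
}

#' Generate a synthetic term-to-gene annotation for enrichment analysis
#'
#' Random gene sets over a gene universe, with term metadata assigning each
#' term a category.  Purely synthetic stand-in for curated ontology /
#' pathway annotations (which are out of scope).
#'
#' @param gene_ids Character vector: the gene universe.
#' @param n_terms Number of terms.
#' @param size_range Term size range (uniform).
#' @param seed Integer seed.
#' @return A list with `term_map` (data.frame `term_id`, `gene_id`) and
#'   `term_meta` (data.frame `term_id`, `term_name`, `category`).
#' @export
synthetic_term_map <- function(gene_ids, n_terms = 40L,
                               size_range = c(10L, 50L), seed = 1L) {
  with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
    term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
    term_map <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
      data.frame(term_id = term_ids[i],
                 gene_id = sample(gene_ids, min(sizes[i], length(gene_ids))),
                 stringsAsFactors = FALSE)
    }))
    term_meta <- data.frame(
      term_id = term_ids,
      term_name = paste0("synthetic term ", seq_len(n_terms)),
      category = sample(c("BP", "MF", "CC", "pathway"), n_terms, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(term_map = term_map, term_meta = term_meta)
  })
}

#' Write a simulated dataset to disk
#'
#' Annotation as GTF, counts as TSV, truth labels/targets as TSV and the
#' configuration as YAML.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(dataset$annotation, file.path(dir, "annotation.gtf"))
  write_counts(dataset$counts, file.path(dir, "counts.tsv"))
  write.table(
    data.frame(gene_id = names(dataset$truth_class),
               class = unname(dataset$truth_class)),
    file.path(dir, "truth_class.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(dataset$truth_targets, file.path(dir, "truth_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$genes_per_chromosome <- as.list(cfg$genes_per_chromosome)
  cfg$class_mixture <- lapply(cfg$class_mixture, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
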