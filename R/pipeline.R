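#' Pipeline configuration
#'
#' Bundles the stage thresholds (defaults are the published screening
#' thresholds: |log2FC| > 1 with padj < 0.05, a 10 kb cis window,
#' |PCC| > 0.95 with p < 0.01, MCC hub threshold 30, NES > 3), the input
#' source (a [sim_config()] for synthetic data, or paths to a counts TSV +
#' GTF annotation), and the global seed.
#'
#' @param sim A [sim_config()] used when no external counts are given.
#' @param counts_path,annotation_path Optional external inputs (TSV / GTF).
#' @param groups Sample-to-group assignment for external counts.
#' @param term_map,term_meta Optional term annotation for the enrichment
#'   stage (see [hypergeom_ora()]); a seeded synthetic term map is used
#'   otherwise.
#' @param min_cpm,bin_width,cap,lfc_min,alpha,cis_window,r_min,trans_alpha,min_mcc,nes_min
#'   Stage thresholds.
#' @param seed Global seed (propagated to simulation and EPC).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, counts_path = NULL,
                            annotation_path = NULL, groups = NULL,
                            term_map = NULL, term_meta = NULL,
                            min_cpm = 1, bin_width = 0.05, cap = 3.0,
                            lfc_min = 1, alpha = 0.05,
                            cis_window = 10000L, r_min = 0.95,
                            trans_alpha = 0.01, min_mcc = 30, nes_min = 3,
                            seed = 1L) {
  stopifnot(min_cpm >= 0, bin_width > 0, cap > 0, lfc_min >= 0,
            alpha > 0, alpha < 1, cis_window >= 0, r_min > 0, r_min < 1,
            trans_alpha > 0, trans_alpha < 1)
  seed <- as.integer(seed)
  structure(list(sim = sim %||% sim_config(seed = seed),
                 counts_path = counts_path,
                 annotation_path = annotation_path, groups = groups,
                 term_map = term_map, term_meta = term_meta,
                 min_cpm = min_cpm, bin_width = bin_width, cap = cap,
                 lfc_min = lfc_min, alpha = alpha,
                 cis_window = cis_window, r_min = r_min,
                 trans_alpha = trans_alpha, min_mcc = min_mcc,
                 nes_min = nes_min, seed = seed),
            class = "pipeline_config")
}

pipe_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage, paste0(...),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain — simulate/ingest, CPM ratio table, binned
#' ratio distributions and per-chromosome medians, dosage-class calls,
#' NB-Wald differential expression, positional classification of the
#' differentially expressed lncRNAs, cis/trans target prediction, bipartite
#' network construction with the centrality suite and MCC hub selection,
#' and over-representation analysis of the target genes — writing every
#' intermediate artifact plus a JSON summary under `output_dir`.  An empty
#' DEL set downstream of the DE stage propagates as empty-but-valid
#' outputs with a warning.  Identical config and seed give an identical
#' bundle.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`dataset`,
#'   `ratios`, `dosage_calls`, `de`, `del_classes`, `targets`, `network`,
#'   `centrality`, `hubs`, `enrichment`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())

  # --- input stage ---------------------------------------------------
  if (is.null(config$counts_path)) {
    dataset <- simulate_dataset(config$sim)
    annotation <- dataset$annotation
    counts <- dataset$counts
  } else {
    dataset <- NULL
    annotation <- read_gtf(config$annotation_path)
    counts <- read_counts(config$counts_path, groups = config$groups)
  }
  write_gtf(annotation, file.path(output_dir, "annotation.gtf"))
  write_counts(counts, file.path(output_dir, "counts.tsv"))
  pipe_log("input", t0, nrow(annotation), " genes, ",
           ncol(counts$counts), " samples")

  # --- ratio stage ----------------------------------------------------
  ratios <- expression_ratio(counts, min_cpm = config$min_cpm,
                             annotation = annotation)
  write_ratio_table(ratios, file.path(output_dir, "ratios.tsv"))
  for (chr in unique(ratios$chrom)) {
    for (bio in c("mRNA", "lncRNA")) {
      sel <- ratios$chrom == chr &
        (if (bio == "lncRNA") ratios$biotype == "lncRNA"
         else ratios$biotype %in% c("coding", "mito"))
      if (!any(sel)) next
      h <- ratio_histogram(ratios$ratio[sel], config$bin_width, config$cap)
      write_histogram(h, file.path(output_dir,
                                   sprintf("hist_%s_%s.tsv", chr, bio)))
    }
  }
  medians <- chromosome_medians(ratios)
  write.table(medians, file.path(output_dir, "chromosome_medians.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dosage_calls <- classify_gene_response(ratios$ratio, gene_id = ratios$gene_id)
  write.table(dosage_calls, file.path(output_dir, "dosage_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipe_log("ratio", t0, nrow(ratios), " genes in ratio table (",
           attr(ratios, "n_filtered"), " filtered)")

  # --- differential expression ---------------------------------------
  de <- call_de(nb_wald_test(counts, annotation = annotation),
                lfc_min = config$lfc_min, alpha = config$alpha)
  write_de_table(de, file.path(output_dir, "de.tsv"))
  dels <- de$gene_id[de$biotype == "lncRNA" & de$status != "ns"]
  pipe_log("de", t0, sum(de$status != "ns"), " DE genes (",
           length(dels), " DELs)")

  # --- DEL positional classes ----------------------------------------
  lnc_ann <- annotation[annotation$gene_id %in% dels, ]
  coding_ann <- annotation[annotation$biotype == "coding", ]
  del_classes <- classify_lncrna_position(lnc_ann, coding_ann)
  write.table(del_classes, file.path(output_dir, "del_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- target prediction ----------------------------------------------
  if (length(dels) == 0L)
    warning("empty DEL set: downstream stages emit empty outputs")
  cis <- cis_targets(lnc_ann, coding_ann, window = config$cis_window)
  mat <- cpm(counts, lib_sizes = counts$lib_sizes)
  trans <- if (length(dels) > 0L && nrow(coding_ann) > 0L) {
    trans_targets(mat[dels, , drop = FALSE],
                  mat[intersect(coding_ann$gene_id, rownames(mat)), ,
                      drop = FALSE],
                  r_min = config$r_min, alpha = config$trans_alpha)
  } else {
    data.frame(lncRNA_id = character(), target_id = character(),
               mode = character(), distance = integer(),
               r = numeric(), p = numeric())
  }
  targets <- rbind(cis, trans)
  write_target_pairs(targets, file.path(output_dir, "targets.tsv"))
  pipe_log("targets", t0, nrow(cis), " cis / ", nrow(trans), " trans pairs")

  # --- network & hubs --------------------------------------------------
  g <- build_network(targets)
  write_sif(g, file.path(output_dir, "network.sif"))
  cent_cfg <- centrality_config(seed = config$seed)
  centrality <- centrality_suite(g, cent_cfg)
  write_centrality_table(centrality, file.path(output_dir, "centrality.tsv"))
  hubs <- if (nrow(centrality) > 0L)
    select_hubs(centrality, g, min_mcc = config$min_mcc)
  else list(hubs = character(0), subnetwork = NULL)
  write_sif(hubs$subnetwork %||% igraph::make_empty_graph(directed = FALSE),
            file.path(output_dir, "hubs.sif"))
  pipe_log("network", t0, igraph::vcount(g), " nodes, ",
           igraph::ecount(g), " edges, ", length(hubs$hubs), " hubs")

  # --- enrichment -------------------------------------------------------
  universe <- coding_ann$gene_id
  study <- intersect(unique(targets$target_id), universe)
  term_map <- config$term_map
  term_meta <- config$term_meta
  if (is.null(term_map) && length(universe) > 0L) {
    tm <- synthetic_term_map(universe, seed = config$seed)
    term_map <- tm$term_map
    term_meta <- tm$term_meta
  }
  enrichment <- if (length(study) > 0L && !is.null(term_map)) {
    hypergeom_ora(study, term_map, universe, term_meta)
  } else {
    data.frame(term_id = character(), term_name = character(),
               category = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p = numeric(), padj = numeric())
  }
  write.table(enrichment, file.path(output_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipe_log("enrich", t0, sum(enrichment$padj < 0.05), " terms at padj < 0.05")

  # --- summary ----------------------------------------------------------
  target_breakdown <- if (nrow(targets) > 0L) {
    summarize_target_regulation(data.frame(
      gene_id = targets$target_id,
      status = de$status[match(targets$target_id, de$gene_id)],
      stringsAsFactors = FALSE
    ))
  } else list(n_down = 0L, n_up = 0L, n_both = 0L, n_ns = 0L, n_total = 0L)
  summary <- list(
    n_genes = nrow(annotation),
    n_samples = ncol(counts$counts),
    class_counts = as.list(table(dosage_calls$assigned)),
    de_counts = de_summary(de),
    n_dels = length(dels),
    del_class_counts = as.list(table(del_classes$class)),
    n_cis = nrow(cis), n_trans = nrow(trans),
    target_regulation = target_breakdown,
    hubs = as.list(hubs$hubs),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log("done", t0, "bundle written to ", output_dir)
  invisible(list(dataset = dataset, ratios = ratios,
                 dosage_calls = dosage_calls, de = de,
                 del_classes = del_classes, targets = targets, network = g,
                 centrality = centrality, hubs = hubs,
                 enrichment = enrichment, summary = summary))
}
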