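#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test per term: with a universe of `N` genes,
#' `K` of which carry the term, and a study set of `n` genes overlapping
#' the term in `k`, `p = P(X >= k)`.  BH adjustment is applied within each
#' category, and rows are sorted by adjusted p.
#'
#' @param study_genes Character vector, a subset of `universe`.
#' @param term_map Data.frame with columns `term_id`, `gene_id`.
#' @param universe Character vector of all considered genes.
#' @param term_meta Optional data.frame with `term_id`, `term_name`,
#'   `category` (one of BP, MF, CC, pathway); terms without metadata get
#'   category `"BP"`.
#' @return A data.frame with columns `term_id`, `term_name`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `padj`.
#' @export
hypergeom_ora <- function(study_genes, term_map, universe, term_meta = NULL) {
  study_genes <- unique(study_genes)
  universe <- unique(universe)
  outside <- setdiff(study_genes, universe)
  if (length(outside) > 0L)
    stop2("validation_error", "study gene(s) absent from universe: ",
          paste(head(outside, 5L), collapse = ", "))
  terms <- split(term_map$gene_id, term_map$term_id)
  terms <- lapply(terms, function(gs) intersect(unique(gs), universe))
  N <- length(universe)
  n <- length(study_genes)
  rows <- lapply(names(terms), function(tid) {
    K <- length(terms[[tid]])
    k <- length(intersect(terms[[tid]], study_genes))
    data.frame(term_id = tid, k = k, K = K, n = n, N = N,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      padj = numeric()))
  }
  if (!is.null(term_meta)) {
    m <- match(out$term_id, term_meta$term_id)
    out$term_name <- term_meta$term_name[m]
    out$category <- term_meta$category[m]
  } else {
    out$term_name <- out$term_id
    out$category <- NA_character_
  }
  out$category[is.na(out$category)] <- "BP"
  out$padj <- NA_real_
  for (cat in unique(out$category)) {
    idx <- out$category == cat
    out$padj[idx] <- bh_adjust(out$p[idx])
  }
  out <- out[order(out$padj, out$p, out$term_id),
             c("term_id", "term_name", "category", "k", "K", "n", "N",
               "p", "padj")]
  rownames(out) <- NULL
  out
}

#' Recovery-curve AUC of a gene set within the top of a ranking
#'
#' Area under the cumulative-recovery curve of `gene_set` over the top
#' `ceiling(top_fraction * length(ranking))` ranks, normalized to `[0, 1]`:
#' the mean, over the top ranks, of the fraction of the gene set recovered
#' by that rank.  A set occupying the first ranks approaches 1; a set
#' entirely outside the top block scores 0.
#'
#' @param ranking Character vector: genes ordered best-first.
#' @param gene_set Character vector, a subset of `ranking`.
#' @param top_fraction Fraction of the ranking forming the top block
#'   (default 0.05).
#' @return The AUC (scalar in `[0, 1]`).
#' @export
motif_auc <- function(ranking, gene_set, top_fraction = 0.05) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L)
    stop2("empty_input", "empty gene set: AUC undefined")
  if (top_fraction <= 0 || top_fraction > 1)
    stop2("domain_error", "top_fraction must be in (0, 1]")
  missing <- setdiff(gene_set, ranking)
  if (length(missing) > 0L)
    stop2("validation_error", "gene set member(s) absent from ranking: ",
          paste(head(missing, 5L), collapse = ", "))
  m <- ceiling(top_fraction * length(ranking))
  rec <- cumsum(ranking[seq_len(m)] %in% gene_set) / length(gene_set)
  mean(rec)
}

#' Normalized enrichment scores over a collection of motif AUCs
#'
#' `NES = (auc - mean(aucs)) / sd(aucs)`; a motif is selected iff its NES
#' strictly exceeds `nes_min`.  When all AUCs are equal (sd = 0) every NES
#' is 0 and nothing is selected.
#'
#' @param aucs Named numeric vector, motif -> AUC (needs >= 3 motifs).
#' @param nes_min Selection threshold (default 3, strict).
#' @return A data.frame with `motif_id`, `auc`, `nes`, `selected`, sorted
#'   by NES descending.
#' @export
motif_nes <- function(aucs, nes_min = 3) {
  if (length(aucs) < 3L)
    stop2("insufficient_data", "need >= 3 motifs to standardize")
  s <- sd(aucs)
  nes <- if (s == 0) rep(0, length(aucs)) else (aucs - mean(aucs)) / s
  out <- data.frame(
    motif_id = names(aucs) %||% paste0("motif_", seq_along(aucs)),
    auc = unname(aucs), nes = unname(nes),
    selected = unname(nes > nes_min),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$nes, out$motif_id), ]
  rownames(out) <- NULL
  out
}

#' Cross-filter selected motifs by the expression status of their factor
#'
#' Keeps selected motifs whose annotated transcription factor is itself
#' differentially expressed (status `up` or `down`).
#'
#' @param motifs Result of [motif_nes()].
#' @param motif_tf Data.frame with `motif_id`, `tf_gene_id`.
#' @param de Called DE table (with `gene_id`, `status`).
#' @return `motifs` with `tf_gene_id` and `tf_status` columns, restricted
#'   to selected motifs whose factor is a DEG.
#' @export
filter_motifs_by_expression <- function(motifs, motif_tf, de) {
  m <- match(motifs$motif_id, motif_tf$motif_id)
  motifs$tf_gene_id <- motif_tf$tf_gene_id[m]
  motifs$tf_status <- de$status[match(motifs$tf_gene_id, de$gene_id)]
  motifs[motifs$selected & !is.na(motifs$tf_status) &
           motifs$tf_status %in% c("up", "down"), ]
}
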