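#' Cis target prediction by co-location
#'
#' A coding gene is a cis target of an lncRNA when both lie on the same
#' chromosome and the gap between their (closed, 1-based) intervals is at
#' most `window` nucleotides, in either direction.  The gap between
#' non-overlapping intervals is `max(starts) - min(ends) - 1`; overlapping
#' genes have distance 0.  The relation is symmetric in the interval
#' geometry.
#'
#' @param lncRNAs Annotation data.frame of lncRNA genes.
#' @param coding_genes Annotation data.frame of coding genes.
#' @param window Maximum gap in nucleotides (default 10000, inclusive).
#' @return A target-pair data.frame: `lncRNA_id`, `target_id`,
#'   `mode = "cis"`, `distance`, `r = NA`, `p = NA`.
#' @export
cis_targets <- function(lncRNAs, coding_genes, window = 10000L) {
  empty <- data.frame(lncRNA_id = character(), target_id = character(),
                      mode = character(), distance = integer(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (nrow(lncRNAs) == 0L || nrow(coding_genes) == 0L) return(empty)
  chroms <- union(lncRNAs$chrom, coding_genes$chrom)
  lgr <- as_gene_granges(lncRNAs, seqlevels = chroms)
  cgr <- as_gene_granges(coding_genes, seqlevels = chroms)
  hits <- GenomicRanges::findOverlaps(lgr, cgr, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lgr[qi], cgr[si], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  data.frame(
    lncRNA_id = lncRNAs$gene_id[qi[keep]],
    target_id = coding_genes$gene_id[si[keep]],
    mode = "cis",
    distance = as.integer(d[keep]),
    r = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Sample Pearson r with the usual test: `t = r sqrt((n-2) / (1-r^2))` on
#' `n - 2` degrees of freedom, two-sided.  |r| is numerically capped at 1,
#' with `p = 0` at the cap.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return A list with elements `r` and `p`.
#' @export
#' @examples
#' # r = 0.95 at n = 6 gives p ~ 0.00365
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    stop2("design_error", "need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop2("constant_vector", "correlation undefined for a constant vector")
  r <- cor(x, y)
  r <- max(min(r, 1), -1)
  if (1 - r^2 < 1e-14) return(list(r = sign(r), p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Trans target prediction by co-expression
#'
#' Tests every lncRNA row of `expr_lnc` against every coding row of
#' `expr_mrna` across the shared sample columns (all samples, both groups
#' pooled) and keeps pairs with `|r| > r_min` and `p < alpha` (both
#' strict).  By default the correlation is computed on `log2(x + 1)` —
#' the standard variance-stabilized scale for co-expression screening,
#' without which a single high-expression sample can dominate the Pearson
#' statistic.  Constant rows are skipped and reported in the `n_skipped`
#' attribute.
#'
#' @param expr_lnc Numeric matrix (lncRNA genes x samples), typically CPM.
#' @param expr_mrna Numeric matrix (coding genes x samples), same columns.
#' @param r_min Minimum |Pearson r| (default 0.95, exclusive).
#' @param alpha Maximum p (default 0.01, exclusive).
#' @param log_transform Correlate `log2(x + 1)` values (default `TRUE`);
#'   set `FALSE` to correlate the supplied values directly.
#' @return A target-pair data.frame: `lncRNA_id`, `target_id`,
#'   `mode = "trans"`, `distance = NA`, `r`, `p`; attribute `n_skipped`.
#' @export
trans_targets <- function(expr_lnc, expr_mrna, r_min = 0.95, alpha = 0.01,
                          log_transform = TRUE) {
  if (log_transform) {
    expr_lnc <- log2(expr_lnc + 1)
    expr_mrna <- log2(expr_mrna + 1)
  }
  if (ncol(expr_lnc) != ncol(expr_mrna))
    stop2("design_error", "expression matrices must share sample columns")
  n <- ncol(expr_lnc)
  if (n < 3L) stop2("design_error", "need >= 3 shared samples")
  const_l <- apply(expr_lnc, 1L, sd) == 0
  const_m <- apply(expr_mrna, 1L, sd) == 0
  n_skipped <- sum(const_l) + sum(const_m)
  if (n_skipped > 0L)
    message("trans_targets: skipping ", n_skipped, " constant gene(s)")
  lm_ <- expr_lnc[!const_l, , drop = FALSE]
  mm_ <- expr_mrna[!const_m, , drop = FALSE]
  out <- data.frame(lncRNA_id = character(), target_id = character(),
                    mode = character(), distance = integer(),
                    r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (nrow(lm_) > 0L && nrow(mm_) > 0L) {
    r <- cor(t(lm_), t(mm_))
    r[r > 1] <- 1; r[r < -1] <- -1
    denom <- pmax(1 - r^2, 1e-14)
    tstat <- r * sqrt((n - 2) / denom)
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p[1 - r^2 < 1e-14] <- 0
    hit <- which(abs(r) > r_min & p < alpha, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      out <- data.frame(
        lncRNA_id = rownames(lm_)[hit[, 1]],
        target_id = rownames(mm_)[hit[, 2]],
        mode = "trans", distance = NA_integer_,
        r = r[hit], p = p[hit],
        stringsAsFactors = FALSE
      )
      out <- out[order(out$lncRNA_id, out$target_id), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Re-validate target pairs against their mode's invariant
#'
#' Checks that every cis pair satisfies `distance <= window` and every
#' trans pair satisfies `|r| > r_min` and `p < alpha`.
#'
#' @param pairs A target-pair data.frame.
#' @param window,r_min,alpha Thresholds to validate against.
#' @return `TRUE` invisibly; otherwise an error listing the offenders.
#' @export
validate_target_pairs <- function(pairs, window = 10000L, r_min = 0.95,
                                  alpha = 0.01) {
  bad_cis <- pairs$mode == "cis" &
    (is.na(pairs$distance) | pairs$distance > window | pairs$distance < 0)
  bad_trans <- pairs$mode == "trans" &
    (is.na(pairs$r) | abs(pairs$r) <= r_min | is.na(pairs$p) | pairs$p >= alpha)
  if (any(bad_cis) || any(bad_trans))
    stop2("validation_error", "target pairs violating their invariant: ",
          paste(head(which(bad_cis | bad_trans), 5L), collapse = ", "))
  invisible(TRUE)
}

#' Write target pairs as TSV
#' @param pairs Target-pair data.frame.
#' @param path Output path.
#' @export
write_target_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
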