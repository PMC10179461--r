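#' Negative-binomial Wald test for differential expression
#'
#' Per-gene case-vs-control test on CPM scale.  The fold change is
#' `log2((mean case CPM + pc) / (mean control CPM + pc))` with pseudocount
#' `pc = 0.5`.  The standard error comes from the NB variance model
#' `var = mu + alpha mu^2` via the delta method, and the Wald statistic
#' `z = log2FC / SE` is referred to a standard normal (two-sided).
#'
#' The dispersion `alpha` is estimated by method of moments on the
#' within-group variances.  With the default `dispersion = "shrunk"` the
#' per-gene estimates are shrunk toward their across-gene median (an
#' information-sharing step in the spirit of DESeq2's shared dispersion
#' fit, without which the normal-reference Wald test is strongly
#' anticonservative at 2-3 replicates per group); `"per_gene"` uses the
#' raw per-gene estimate.  Both are floored at 1e-8.
#'
#' This is a documented approximation of a DESeq2 analysis (no
#' median-of-ratios size factors, no shrinkage of fold changes); externally
#' computed DE tables can be ingested with [read_de_table()].
#'
#' @param x A [count_matrix()] with at least two samples per group.
#' @param pseudocount Pseudocount on the CPM scale (default 0.5).
#' @param dispersion `"shrunk"` (default) or `"per_gene"`.
#' @param annotation Optional annotation data.frame supplying `biotype`.
#' @return A data.frame with columns `gene_id`, `biotype`, `cpm_control`,
#'   `cpm_case`, `log2FC`, `p`.
#' @export
nb_wald_test <- function(x, pseudocount = 0.5,
                         dispersion = c("shrunk", "per_gene"),
                         annotation = NULL) {
  dispersion <- match.arg(dispersion)
  if (!is(x, "count_matrix")) stop2("design_error", "expected a count_matrix")
  ctrl_idx <- x$groups == "control"
  case_idx <- x$groups == "case"
  if (sum(ctrl_idx) < 2L || sum(case_idx) < 2L)
    stop2("design_error", "need >= 2 samples per group")
  if (all(x$counts[, ctrl_idx] == 0) || all(x$counts[, case_idx] == 0))
    stop2("test_error", "a group has all-zero counts for every gene")
  lib <- x$lib_sizes %||% colSums(x$counts)
  mat <- cpm(x, lib_sizes = lib)
  scale_per_sample <- 1e6 / lib   # CPM units per count

  group_stats <- function(idx) {
    m <- mat[, idx, drop = FALSE]
    list(mean = rowMeans(m), var = apply(m, 1L, var), n = sum(idx),
         pois = mean(scale_per_sample[idx]))
  }
  g1 <- group_stats(ctrl_idx)
  g2 <- group_stats(case_idx)

  # method-of-moments dispersion: excess of the within-group variance over
  # the Poisson part, pooled across groups, on the CPM scale
  mom <- function(g) (g$var - g$pois * g$mean) / g$mean^2
  w1 <- g1$n - 1L; w2 <- g2$n - 1L
  alpha_g <- pmax((w1 * mom(g1) + w2 * mom(g2)) / (w1 + w2), 1e-8)
  alpha_g[!is.finite(alpha_g)] <- 1e-8
  if (dispersion == "shrunk") {
    # global ratio-of-sums moment estimator (stable and nearly unbiased,
    # unlike the median of floored per-gene estimates); per-gene estimates
    # are shrunk heavily toward it, reflecting their ~4 df of information.
    # Genes whose raw dispersion vastly exceeds the global fit are treated
    # as dispersion outliers: excluded from the global estimate and left
    # unshrunk, so a handful of wildly variable genes can neither inflate
    # everyone's standard errors nor be flagged as spurious DE themselves.
    outlier <- alpha_g > 10 * pmax(median(alpha_g), 1e-4)
    num <- sum((g1$var - g1$pois * g1$mean)[!outlier], na.rm = TRUE) +
      sum((g2$var - g2$pois * g2$mean)[!outlier], na.rm = TRUE)
    den <- sum(g1$mean[!outlier]^2) + sum(g2$mean[!outlier]^2)
    alpha_global <- max(num / den, 1e-8)
    df_local <- w1 + w2
    w_local <- df_local / (df_local + 40)
    shrunk <- pmax(w_local * alpha_g + (1 - w_local) * alpha_global, 1e-8)
    alpha_g <- ifelse(outlier, alpha_g, shrunk)
  }

  var_log2_mean <- function(g, alpha) {
    v <- (g$pois * g$mean + alpha * g$mean^2) / g$n   # var of the group mean
    v / ((g$mean + pseudocount)^2 * log(2)^2)
  }
  log2fc <- log2((g2$mean + pseudocount) / (g1$mean + pseudocount))
  se <- sqrt(var_log2_mean(g1, alpha_g) + var_log2_mean(g2, alpha_g))
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(
    gene_id = rownames(mat), biotype = NA_character_,
    cpm_control = unname(g1$mean), cpm_case = unname(g2$mean),
    log2FC = unname(log2fc), p = unname(p),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation))
    out$biotype <- annotation$biotype[match(out$gene_id, annotation$gene_id)]
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, returned in input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop2("domain_error", "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Call differential expression status
#'
#' Applies the screening rule: `up` iff `log2FC > lfc_min` and
#' `padj < alpha`; `down` iff `log2FC < -lfc_min` and `padj < alpha`;
#' otherwise `ns`.  Inequalities are strict, so a gene at exactly
#' `log2FC = -1` is not called.
#'
#' @param results Data.frame with `log2FC` and `p` (and optionally `padj`).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `results` with `padj` and `status` columns; attribute `summary`
#'   holds up/down counts split by biotype (see [de_summary()]).
#' @export
call_de <- function(results, lfc_min = 1, alpha = 0.05) {
  if (is.null(results$padj)) results$padj <- bh_adjust(results$p)
  results$status <- ifelse(
    results$log2FC > lfc_min & results$padj < alpha, "up",
    ifelse(results$log2FC < -lfc_min & results$padj < alpha, "down", "ns")
  )
  attr(results, "summary") <- de_summary(results)
  results
}

#' Up/down counts per biotype
#'
#' @param results A called DE table (with `status`).
#' @return Data.frame with columns `biotype`, `n_up`, `n_down`, `n_ns`.
#' @export
de_summary <- function(results) {
  bt <- results$biotype
  bt[is.na(bt)] <- "unknown"
  out <- do.call(rbind, lapply(split(results, bt), function(d) {
    data.frame(biotype = if (is.na(d$biotype[1])) "unknown" else d$biotype[1],
               n_up = sum(d$status == "up"),
               n_down = sum(d$status == "down"),
               n_ns = sum(d$status == "ns"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ingest an externally computed DE table
#'
#' Reads a TSV with at least `gene_id`, `log2FC`, `p` and optionally
#' `padj`, `biotype` — e.g. an exported DESeq2 result — so downstream
#' stages can run on exact external statistics.
#'
#' @param path Path to the TSV.
#' @return A data.frame ready for [call_de()].
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "log2FC", "p")
  if (!all(needed %in% names(df)))
    stop2("validation_error", "DE table needs columns: ",
          paste(needed, collapse = ", "))
  if (is.null(df$biotype)) df$biotype <- NA_character_
  df
}

#' Write a called DE table as TSV
#' @param results Called DE table.
#' @param path Output path.
#' @export
write_de_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
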