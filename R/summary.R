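#' Summarize the regulation status of a target-gene set
#'
#' Aggregates per-gene differential-expression evidence for a set of
#' target genes: a gene supported by both up- and downregulated evidence
#' (e.g. via different transcripts or interaction partners) is counted as
#' `both`; otherwise it is `up`, `down`, or `ns`.  The total is the number
#' of distinct genes.
#'
#' @param target_status Data.frame with columns `gene_id` and `status`
#'   (`up`, `down` or `ns`); multiple rows per gene allowed.
#' @return A list with `n_down`, `n_up`, `n_both`, `n_ns` and `n_total`
#'   (`n_total = n_down + n_up + n_both + n_ns`).
#' @export
summarize_target_regulation <- function(target_status) {
  if (!all(target_status$status %in% c("up", "down", "ns")))
    stop2("validation_error", "status must be up, down or ns")
  per_gene <- split(target_status$status, target_status$gene_id)
  cls <- vapply(per_gene, function(s) {
    if ("up" %in% s && "down" %in% s) "both"
    else if ("up" %in% s) "up"
    else if ("down" %in% s) "down"
    else "ns"
  }, "")
  list(
    n_down = sum(cls == "down"),
    n_up = sum(cls == "up"),
    n_both = sum(cls == "both"),
    n_ns = sum(cls == "ns"),
    n_total = length(cls)
  )
}
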