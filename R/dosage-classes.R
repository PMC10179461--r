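#' Canonical dosage-response ratios
#'
#' Expression ratios (case/control) expected for the four dosage-response
#' classes of a trisomic (e.g. triple-X) tissue relative to a diploid
#' control: a gene following its copy number (`dosage_effect`, 3/2), a fully
#' compensated gene (`compensated`, 1), a gene under the inverse dosage
#' effect exerted by the extra chromosome (`inverse`, 2/3), and a gene hit
#' by the inverse effect twice (`double_inverse`, (2/3)^2 = 4/9, printed as
#' 0.44).
#'
#' @return Named numeric vector of canonical ratios, increasing.
#' @export
#' @examples
#' dosage_class_ratios()
dosage_class_ratios <- function() {
  c(double_inverse = 4 / 9, inverse = 2 / 3, compensated = 1, dosage_effect = 3 / 2)
}

#' Assign genes to dosage-response classes by expression ratio
#'
#' Each ratio is assigned to the nearest canonical class ratio (see
#' [dosage_class_ratios()]) provided the absolute distance does not exceed
#' `tolerance`; otherwise the gene is `unclassified`.  An exact midpoint
#' between two canonical values resolves to the smaller one.
#'
#' @param ratio Numeric vector of positive case/control expression ratios.
#' @param tolerance Maximum |ratio - canonical| for an assignment.  The
#'   default 0.1 is well below half the smallest gap between canonical
#'   ratios (2/3 - 4/9 = 0.22), so assignment regions never overlap.
#' @param gene_id Optional gene identifiers carried into the result.
#' @return A data.frame with columns `gene_id`, `ratio`, `assigned`
#'   (class label or `"unclassified"`) and `distance_to_canonical`.
#' @export
#' @examples
#' classify_gene_response(c(1.5, 1.0, 0.44, 2.5))$assigned
classify_gene_response <- function(ratio, tolerance = 0.1, gene_id = NULL) {
  if (length(ratio) == 0L) stop2("empty_input", "no ratios supplied")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop2("domain_error", "ratios must be positive and finite")
  canon <- dosage_class_ratios()
  d <- abs(outer(ratio, canon, "-"))
  # canonical ratios are sorted increasing and distances tied within float
  # tolerance count as equal, so an exact midpoint resolves to the smaller
  # canonical value
  idx <- apply(d, 1L, function(row) which(row <= min(row) + 1e-12)[1])
  dist <- d[cbind(seq_along(ratio), idx)]
  assigned <- names(canon)[idx]
  assigned[dist > tolerance] <- "unclassified"
  data.frame(
    gene_id = gene_id %||% paste0("gene_", seq_along(ratio)),
    ratio = ratio,
    assigned = assigned,
    distance_to_canonical = dist,
    stringsAsFactors = FALSE
  )
}
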