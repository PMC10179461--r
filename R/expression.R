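#' Construct a count matrix with a case/control design
#'
#' Container for raw RNA-seq counts: an integer genes-by-samples matrix, a
#' sample-to-group assignment (`control`/`case`), and optionally per-sample
#' library sizes.  Stored library sizes are the total depth of the
#' sequencing library the genes were drawn from; they matter when the
#' matrix holds a subset of the transcriptome (or was simulated as one), in
#' which case normalizing against within-matrix column sums would absorb
#' genome-wide expression shifts.
#'
#' @param counts Non-negative integer matrix with gene rownames and sample
#'   colnames.
#' @param groups Character/factor of `"control"`/`"case"`, one per sample
#'   (named or in column order).
#' @param lib_sizes Optional numeric vector of per-sample library sizes.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("validation_error", "counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop2("validation_error", "duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    stop2("validation_error", "duplicate sample ids")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop2("validation_error", "counts must be finite and non-negative")
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  if (length(groups) != ncol(counts) || anyNA(groups))
    stop2("design_error", "every sample needs a group assignment")
  if (!all(groups %in% c("control", "case")))
    stop2("design_error", "groups must be 'control' or 'case'")
  if (!all(c("control", "case") %in% groups))
    stop2("design_error", "both a control and a case group are required")
  if (!is.null(lib_sizes)) {
    if (!is.null(names(lib_sizes))) lib_sizes <- lib_sizes[colnames(counts)]
    if (length(lib_sizes) != ncol(counts) || any(!is.finite(lib_sizes)) ||
        any(lib_sizes <= 0))
      stop2("validation_error", "lib_sizes must be positive, one per sample")
    lib_sizes <- stats::setNames(as.numeric(lib_sizes), colnames(counts))
  }
  structure(
    list(counts = counts,
         groups = stats::setNames(groups, colnames(counts)),
         lib_sizes = lib_sizes),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d control, %d case)%s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "control"), sum(x$groups == "case"),
              if (is.null(x$lib_sizes)) "" else ", stored library sizes"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

resolve_counts <- function(x) {
  if (is(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Counts-per-million normalization
#'
#' `cpm[g, s] = counts[g, s] / libsize(s) * 1e6`.  By default the library
#' size is the column sum, so every column of the result sums to one
#' million; pass `lib_sizes` (e.g. the total depth of the parent library)
#' to normalize against an external denominator instead.
#'
#' @param x A `count_matrix` or plain counts matrix.
#' @param lib_sizes Optional per-sample library sizes overriding column sums.
#' @return Numeric matrix of CPM values.
#' @export
#' @examples
#' m <- matrix(c(250, 750), 2, dimnames = list(c("g1", "g2"), "s1"))
#' cpm(m)  # 250000, 750000
cpm <- function(x, lib_sizes = NULL) {
  counts <- resolve_counts(x)
  if (is.null(lib_sizes)) {
    cs <- colSums(counts)
    if (any(cs == 0))
      stop2("normalization_error", "all-zero sample column(s): ",
            paste(colnames(counts)[cs == 0], collapse = ", "))
    lib_sizes <- cs
  }
  edgeR::cpm(counts, lib.size = lib_sizes)
}

#' Fragments per kilobase per million
#'
#' `fpkm[g, s] = counts[g, s] / (length_kb(g) * libsize(s) / 1e6)`.
#'
#' @inheritParams cpm
#' @param gene_lengths Named numeric vector of gene lengths in nucleotides;
#'   every gene in `x` must be present.
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(x, gene_lengths, lib_sizes = NULL) {
  counts <- resolve_counts(x)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0)
    stop2("lookup_error", "no length for gene(s): ",
          paste(head(missing, 5L), collapse = ", "))
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop2("validation_error", "gene lengths must be positive")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  edgeR::rpkm(counts, gene.length = len, lib.size = lib_sizes)
}

#' Case/control expression-ratio table
#'
#' For every gene passing the expression filter, the ratio of the mean CPM
#' over case samples to the mean CPM over control samples (replicates are
#' averaged on the CPM scale before the ratio).  Genes with mean control
#' CPM below `min_cpm` or mean case CPM of zero are dropped; the number of
#' dropped genes is recorded in the `n_filtered` attribute.
#'
#' @param x A `count_matrix` with both groups present.
#' @param min_cpm Control-mean CPM floor (default 1), guarding against
#'   division by zero and ratio blow-up at negligible expression.
#' @param annotation Optional annotation data.frame supplying `chrom` and
#'   `biotype` per gene.
#' @param use_stored_lib_sizes Normalize against the library sizes stored
#'   in `x` when present (default), rather than column sums.
#' @return A data.frame (`ratio_table`) with columns `gene_id`, `chrom`,
#'   `biotype`, `cpm_control`, `cpm_case`, `ratio`; attribute `n_filtered`.
#' @export
expression_ratio <- function(x, min_cpm = 1, annotation = NULL,
                             use_stored_lib_sizes = TRUE) {
  if (!is(x, "count_matrix"))
    stop2("design_error", "expression_ratio needs a count_matrix with groups")
  lib <- if (use_stored_lib_sizes) x$lib_sizes else NULL
  mat <- cpm(x, lib_sizes = lib)
  ctrl <- rowMeans(mat[, x$groups == "control", drop = FALSE])
  case <- rowMeans(mat[, x$groups == "case", drop = FALSE])
  keep <- ctrl >= min_cpm & case > 0
  tab <- data.frame(
    gene_id = rownames(mat)[keep],
    chrom = NA_character_, biotype = NA_character_,
    cpm_control = unname(ctrl[keep]), cpm_case = unname(case[keep]),
    ratio = unname(case[keep] / ctrl[keep]),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    m <- match(tab$gene_id, annotation$gene_id)
    tab$chrom <- annotation$chrom[m]
    tab$biotype <- annotation$biotype[m]
  }
  attr(tab, "n_filtered") <- sum(!keep)
  tab
}

#' Write / read a counts TSV (gene_id column plus one column per sample)
#'
#' @param x A `count_matrix`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `count_matrix` (reader).
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param groups Sample-to-group assignment for the samples in the file.
#' @param lib_sizes Optional per-sample library sizes.
#' @export
read_counts <- function(path, groups, lib_sizes = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, groups, lib_sizes)
}

#' Write a ratio table as TSV
#'
#' @param tab Result of [expression_ratio()].
#' @param path Output path.
#' @export
write_ratio_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
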