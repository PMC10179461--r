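#' Construct a gene-annotation table
#'
#' The annotation container is a plain data.frame with one row per gene and
#' columns `gene_id`, `chrom`, `start`, `end` (1-based, inclusive; all
#' interval arithmetic in the package treats these as closed intervals),
#' `strand` (`+`/`-`) and `biotype` (`coding`, `lncRNA` or `mito`).
#'
#' @param gene_id,chrom Character vectors.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param biotype Character vector: `coding`, `lncRNA` or `mito`.
#' @return A validated annotation data.frame.
#' @export
gene_records <- function(gene_id, chrom, start, end, strand, biotype) {
  rec <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  validate_gene_records(rec)
}

validate_gene_records <- function(rec) {
  if (anyDuplicated(rec$gene_id))
    stop2("validation_error", "duplicate gene_id in annotation")
  if (any(rec$start < 1L))
    stop2("validation_error", "gene start coordinates must be >= 1")
  if (any(rec$end < rec$start))
    stop2("validation_error", "gene end < start for: ",
          paste(rec$gene_id[rec$end < rec$start], collapse = ", "))
  if (any(!nzchar(rec$chrom)))
    stop2("validation_error", "empty chromosome name")
  if (any(!rec$strand %in% c("+", "-")))
    stop2("validation_error", "strand must be '+' or '-'")
  if (any(!rec$biotype %in% c("coding", "lncRNA", "mito")))
    stop2("validation_error", "biotype must be coding, lncRNA or mito")
  rec
}

# annotation data.frame -> GRanges (closed 1-based intervals, as GTF);
# seqlevels can be widened so ranges from different records are comparable
as_gene_granges <- function(rec, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(rec$chrom, levels = seqlevels %||% unique(rec$chrom)),
    ranges = IRanges::IRanges(start = rec$start, end = rec$end),
    strand = rec$strand,
    gene_id = rec$gene_id,
    biotype = rec$biotype
  )
}

biotype_to_gtf <- c(coding = "protein_coding", lncRNA = "lncRNA", mito = "mito")

#' Read gene models from a GTF file
#'
#' Reads `gene` features (1-based inclusive coordinates) carrying `gene_id`
#' and a biotype attribute (`gene_biotype`).  Biotypes other than
#' `protein_coding`, `lncRNA` and `mito` are mapped to `coding` with a
#' warning.
#'
#' @param path Path to a GTF file.
#' @return An annotation data.frame (see [gene_records()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop2("io_error", "no such file: ", path)
  if (length(readLines(path, warn = FALSE)) == 0L) {
    return(gene_records(character(), character(), integer(), integer(),
                        character(), character()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop2("parse_error", "malformed GTF '", path, "': ",
                              conditionMessage(e))
  )
  if (!is.null(gr$type)) gr <- gr[gr$type == "gene" | is.na(gr$type)]
  bt <- as.character(gr$gene_biotype %||% rep(NA_character_, length(gr)))
  known <- c(protein_coding = "coding", lncRNA = "lncRNA", mito = "mito")
  mapped <- unname(known[bt])
  if (anyNA(mapped)) {
    warning("unknown biotype(s) mapped to 'coding': ",
            paste(unique(bt[is.na(mapped)]), collapse = ", "))
    mapped[is.na(mapped)] <- "coding"
  }
  st <- as.character(BiocGenerics::strand(gr))
  st[!st %in% c("+", "-")] <- "+"
  gene_records(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = st, biotype = mapped
  )
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: `read_gtf(write_gtf(x, path))` reproduces the
#' annotation fields exactly.
#'
#' @param records Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(records, path) {
  records <- validate_gene_records(records)
  gr <- as_gene_granges(records)
  gr$source <- "lncDosage"
  gr$type <- "gene"
  gr$gene_biotype <- unname(biotype_to_gtf[records$biotype])
  gr$biotype <- NULL
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Classify lncRNAs by genomic position relative to coding genes
#'
#' Gene-level positional classification into the four classes used for
#' differentially expressed lncRNAs: `sense` (overlaps a same-strand coding
#' gene), `intronic` (strictly contained inside a coding gene without
#' spanning it entirely, and not overlapping any same-strand coding gene),
#' `antisense` (overlaps an opposite-strand coding gene without being
#' contained in one), and `lincRNA` (intergenic: no coding overlap at all).
#' The four labels are mutually exclusive and exhaustive.
#'
#' The model is gene-level: a coding gene's span stands in for its exonic
#' extent, so containment in a gene body is read as "intronic" and any
#' same-strand overlap as "sense".
#'
#' @param lnc Annotation data.frame of lncRNA genes (`biotype == "lncRNA"`).
#' @param coding Annotation data.frame of protein-coding genes (may be
#'   empty, in which case every lncRNA is `lincRNA`).
#' @return A data.frame with columns `gene_id` and `class`.
#' @export
classify_lncrna_position <- function(lnc, coding) {
  if (nrow(lnc) > 0 && any(lnc$biotype != "lncRNA"))
    stop2("validation_error", "classify_lncrna_position expects lncRNA records")
  cls <- rep("lincRNA", nrow(lnc))
  if (nrow(coding) > 0 && nrow(lnc) > 0) {
    chroms <- union(lnc$chrom, coding$chrom)
    lgr <- as_gene_granges(lnc, seqlevels = chroms)
    cgr <- as_gene_granges(coding, seqlevels = chroms)
    ov <- GenomicRanges::findOverlaps(lgr, cgr, ignore.strand = TRUE)
    for (i in unique(S4Vectors::queryHits(ov))) {
      hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
      same <- lnc$strand[i] == coding$strand[hits]
      contained <- lnc$start[i] >= coding$start[hits] &
        lnc$end[i] <= coding$end[hits] &
        !(lnc$start[i] == coding$start[hits] & lnc$end[i] == coding$end[hits])
      cls[i] <-
        if (any(same)) "sense"
        else if (any(contained)) "intronic"
        else "antisense"
    }
  }
  data.frame(gene_id = lnc$gene_id, class = cls, stringsAsFactors = FALSE)
}

#' Tabulate positional-class proportions
#'
#' @param classes Result of [classify_lncrna_position()].
#' @return A data.frame with columns `class`, `n` and `proportion`, over the
#'   four classes in the fixed order lincRNA, intronic, antisense, sense.
#' @export
positional_class_summary <- function(classes) {
  lev <- c("lincRNA", "intronic", "antisense", "sense")
  n <- table(factor(classes$class, levels = lev))
  data.frame(
    class = lev, n = as.integer(n),
    proportion = if (sum(n) > 0) as.numeric(n) / sum(n) else rep(NA_real_, 4L),
    stringsAsFactors = FALSE
  )
}
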