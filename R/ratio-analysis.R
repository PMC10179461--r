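#' Binned expression-ratio frequency distribution
#'
#' Bins case/control expression ratios into half-open bins of width
#' `bin_width` whose centers sit on the multiples of `bin_width`
#' (0, 0.05, 0.10, ... with defaults), so the canonical dosage-response
#' ratios 1.0 and 1.5 are bin centers.  Bin `c` covers
#' `[c - w/2, c + w/2)`: a ratio falling exactly on an edge goes to the
#' bin on its right.  Ratios at or above `cap` are counted in `n_capped`
#' and excluded; frequencies are normalized over the included genes.
#'
#' @param ratios Positive numeric vector of expression ratios.
#' @param bin_width Bin width (default 0.05).
#' @param cap Upper display cap (default 3.0); ratios `>= cap` overflow.
#' @return An object of class `ratio_histogram`: a list with `bin_width`,
#'   `centers`, `bin_lo`, `bin_hi`, `counts`, `frequencies`, `n_included`,
#'   `n_capped`.
#' @export
ratio_histogram <- function(ratios, bin_width = 0.05, cap = 3.0) {
  if (length(ratios) == 0L) stop2("empty_input", "no ratios to bin")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop2("domain_error", "ratios must be positive and finite")
  if (bin_width <= 0) stop2("domain_error", "bin_width must be positive")
  capped <- ratios >= cap
  kept <- ratios[!capped]
  k_max <- round(cap / bin_width)
  centers <- (0:k_max) * bin_width
  # half-open [c - w/2, c + w/2); the epsilon keeps values landing exactly
  # on an edge (up to float rounding) in the bin on their right
  idx <- floor(kept / bin_width + 0.5 + 1e-9)
  idx[idx > k_max] <- k_max
  counts <- tabulate(idx + 1L, nbins = k_max + 1L)
  structure(
    list(bin_width = bin_width,
         centers = centers,
         bin_lo = centers - bin_width / 2,
         bin_hi = centers + bin_width / 2,
         counts = counts,
         frequencies = if (length(kept) > 0) counts / length(kept) else counts,
         n_included = length(kept),
         n_capped = sum(capped)),
    class = "ratio_histogram"
  )
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat(sprintf("ratio_histogram: %d genes in %d bins of %.3g (%d capped at %.3g); modal center %.3g\n",
              x$n_included, length(x$centers), x$bin_width, x$n_capped,
              max(x$bin_hi), modal_bin(x)))
  invisible(x)
}

#' Center of the modal histogram bin
#'
#' Returns the center of the maximum-frequency bin.  Ties are broken
#' toward the bin whose center is nearest 1.0 (the no-change ratio), and
#' then toward the smaller center.
#'
#' @param hist A `ratio_histogram`.
#' @return The modal bin center (scalar).
#' @export
modal_bin <- function(hist) {
  if (!inherits(hist, "ratio_histogram"))
    stop2("domain_error", "expected a ratio_histogram")
  if (hist$n_included == 0L) stop2("empty_input", "histogram is empty")
  best <- which(hist$frequencies == max(hist$frequencies))
  if (length(best) > 1L) {
    d1 <- abs(hist$centers[best] - 1)
    best <- best[d1 == min(d1)]
    if (length(best) > 1L) best <- best[which.min(hist$centers[best])]
  }
  hist$centers[best]
}

#' Per-chromosome median expression ratios
#'
#' Medians of the case/control ratio per chromosome, computed separately
#' for mRNA (`coding`/`mito`) and `lncRNA` biotypes — the numbers printed
#' above per-chromosome ratio boxplots.
#'
#' @param tab A ratio table from [expression_ratio()] with `chrom` and
#'   `biotype` populated.
#' @return A data.frame with columns `chrom`, `biotype`, `n`,
#'   `median_ratio`.
#' @export
chromosome_medians <- function(tab) {
  if (nrow(tab) == 0L) {
    return(data.frame(chrom = character(), biotype = character(),
                      n = integer(), median_ratio = numeric()))
  }
  grp <- interaction(tab$chrom, tab$biotype, drop = TRUE)
  out <- do.call(rbind, lapply(split(tab, grp), function(d) {
    data.frame(chrom = d$chrom[1], biotype = d$biotype[1],
               n = nrow(d), median_ratio = median(d$ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$biotype, out$chrom), ]
}

#' Write a ratio histogram as TSV (bin_lo, bin_hi, frequency)
#'
#' @param hist A `ratio_histogram`.
#' @param path Output path.
#' @export
write_histogram <- function(hist, path) {
  write.table(
    data.frame(bin_lo = hist$bin_lo, bin_hi = hist$bin_hi,
               frequency = hist$frequencies),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
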