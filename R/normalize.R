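#' Count tags per sliding-window bin
#'
#' Fills the bins x samples raw count matrix: `counts[b, s]` is the number
#' of retained tags of sample `s` with `start <= pos < end` for bin `b`.
#' Because consecutive windows overlap by `bin_size - step_size`, a tag in
#' an overlap region increments both covering bins; this is intentional and
#' is what makes the 50%-overlapping grid smooth.
#'
#' @param tags list of [tag_table]s (one per sample).
#' @param bins `karyo_bins` grid from [make_bins()].
#' @param genome the [genome_def] the grid was built from.
#' @param weight_by_depth if `TRUE`, sum per-tag weights instead of counting
#'   records.
#' @return A `bin_counts` object: list with `bins`, `samples`, and `counts`
#'   (numeric matrix, bins x samples).
#' @export
count_bins <- function(tags, bins, genome, weight_by_depth = FALSE) {
  stopifnot(inherits(bins, "karyo_bins"), inherits(genome, "genome_def"))
  samples <- vapply(tags, function(t) t$sample_id, character(1))
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  gr_bins <- bins_to_granges(bins, genome)
  counts <- matrix(0, nrow = nrow(bins), ncol = length(tags),
                   dimnames = list(NULL, samples))
  for (j in seq_along(tags)) {
    rec <- tags[[j]]$records
    if (nrow(rec) == 0) next
    if (!all(rec$chrom %in% genome$chrom))
      stop("sample ", samples[j], ": tag on chromosome absent from genome")
    len <- genome$length[match(rec$chrom, genome$chrom)]
    if (any(rec$pos < 0 | rec$pos >= len))
      stop("sample ", samples[j],
           ": tag position outside [0, chromosome length) - corrupt input")
    gr_tags <- GenomicRanges::GRanges(
      seqnames = factor(rec$chrom, levels = genome$chrom),
      ranges = IRanges::IRanges(start = rec$pos + 1, width = 1)
    )
    if (weight_by_depth) {
      hits <- GenomicRanges::findOverlaps(gr_bins, gr_tags)
      counts[, j] <- as.numeric(tapply(
        rec$weight[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(bins))),
        sum, default = 0))
    } else {
      counts[, j] <- GenomicRanges::countOverlaps(gr_bins, gr_tags)
    }
  }
  structure(list(bins = bins, samples = samples, counts = counts),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("GBS bin count matrix:", nrow(x$counts), "bins x",
      ncol(x$counts), "samples;",
      format(sum(x$counts), big.mark = ","), "binned tag events\n")
  invisible(x)
}

#' Across-sample total normalization
#'
#' First normalization stage: rescales every sample's bin counts so all
#' samples carry the same total, removing the (heavily skewed) per-sample
#' sequencing-depth differences. The common target is the median of the
#' per-sample totals; the choice of target is immaterial to final dosage
#' calls because the subsequent per-bin median division cancels any common
#' factor.
#'
#' @param m a `bin_counts` object.
#' @return List with `scaled` (numeric matrix), `target_total`, and
#'   `scale_factors` (named per sample).
#' @export
normalize_sample_totals <- function(m) {
  stopifnot(inherits(m, "bin_counts"))
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stop("sample(s) with zero binned tags: ",
         paste(m$samples[totals == 0], collapse = ", "),
         "; exclude them via QC before normalization")
  target <- stats::median(totals)
  f <- target / totals
  list(scaled = sweep(m$counts, 2, f, `*`),
       target_total = target,
       scale_factors = stats::setNames(f, m$samples))
}

#' Per-bin median normalization
#'
#' Second normalization stage: divides each bin's depth-scaled counts by
#' that bin's median across all samples, so a disomic (2x) bin has
#' expectation 1.0, a monosomic bin 0.5, a trisomic bin 1.5, and so on.
#' Bins whose across-sample median is zero cannot be normalized and are
#' masked (no-call) rather than divided. The method therefore assumes most
#' samples are disomic at any given bin; an aberration shared by more than
#' half the cohort shifts the median and is misread or masked.
#'
#' @param m a `bin_counts` object.
#' @param scaled optionally, the output of [normalize_sample_totals()]
#'   (recomputed if omitted).
#' @return A `norm_matrix` object: list with `bins`, `samples`, `values`
#'   (numeric matrix with `NA` in masked bins), `mask` (logical per bin),
#'   and `bin_medians`.
#' @export
normalize_bin_medians <- function(m, scaled = NULL) {
  stopifnot(inherits(m, "bin_counts"))
  if (is.null(scaled)) scaled <- normalize_sample_totals(m)
  sc <- scaled$scaled
  med <- apply(sc, 1, stats::median)
  mask <- med == 0
  values <- sc / med
  values[mask, ] <- NA_real_
  structure(list(bins = m$bins, samples = m$samples, values = values,
                 mask = mask, bin_medians = med,
                 target_total = scaled$target_total),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("Normalized GBS tag counts:", nrow(x$values), "bins x",
      ncol(x$values), "samples;", sum(x$mask), "bin(s) masked\n")
  invisible(x)
}

# shared writer for bins x samples matrices with chrom/start/end key columns
write_bin_matrix <- function(bins, samples, mat, path) {
  df <- data.frame(chrom = bins$chrom,
                   start = format(bins$start, scientific = FALSE, trim = TRUE),
                   end = format(bins$end, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mat))
  names(df) <- c("chrom", "start", "end", samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Serialize count / normalized matrices
#'
#' TSV with columns `chrom`, `start`, `end`, then one column per sample;
#' masked cells are written as `NA`.
#'
#' @param x a `bin_counts` or `norm_matrix` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_counts"))
  write_bin_matrix(x$bins, x$samples, x$counts, path)
}

#' @rdname write_bin_counts
#' @export
write_normalized <- function(x, path) {
  stopifnot(inherits(x, "norm_matrix"))
  write_bin_matrix(x$bins, x$samples, x$values, path)
}
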