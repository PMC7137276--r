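#' Tag position tables
#'
#' A tag position table is the per-sample unit flowing through the pipeline:
#' the genomic positions (0-based) of this sample's retained uniquely-mapped
#' GBS tags, plus the raw/retained alignment accounting used for QC.
#'
#' @param sample_id sample identifier.
#' @param chrom chromosome name per retained tag.
#' @param pos 0-based position per retained tag.
#' @param n_raw_alignments number of alignment records seen before filtering
#'   (defaults to the number of retained records).
#' @param weight optional positive per-tag weight (default 1 per tag); used
#'   only when counting with depth weighting.
#' @return A `tag_table`: list with `sample_id`, `records` (data frame
#'   `chrom`, `pos`, `weight`), `n_raw_alignments`, `n_retained`.
#' @export
tag_table <- function(sample_id, chrom, pos, n_raw_alignments = length(pos),
                      weight = NULL) {
  stopifnot(length(chrom) == length(pos))
  if (is.null(weight)) weight <- rep(1, length(pos))
  if (length(pos) && (anyNA(pos) || any(pos < 0)))
    stop("tag positions must be non-negative")
  structure(
    list(sample_id = as.character(sample_id),
         records = data.frame(chrom = as.character(chrom),
                              pos = as.numeric(pos),
                              weight = as.numeric(weight),
                              stringsAsFactors = FALSE),
         n_raw_alignments = as.integer(n_raw_alignments),
         n_retained = length(pos)),
    class = "tag_table"
  )
}

#' @export
print.tag_table <- function(x, ...) {
  cat("GBS tag table: sample", x$sample_id, "-", x$n_retained,
      "retained tags of", x$n_raw_alignments, "alignment records\n")
  invisible(x)
}

#' Filter a SAM/BAM alignment file to uniquely mapped, anchored tags
#'
#' Applies the unique-mapping filter used for GBS tag karyotyping: a record
#' is retained iff it is mapped, primary (neither secondary nor
#' supplementary), carries no `XS:i` optional field (aligners emit `XS:i`
#' when a secondary alignment score exists, so its absence marks a uniquely
#' mapped read), is anchored to a chromosome present in the genome
#' definition (unanchored scaffolds are dropped), and has a valid leftmost
#' position. Retained 1-based SAM positions are converted to 0-based.
#'
#' @param path a SAM (plain text) or BAM file; one file per sample.
#' @param genome a [genome_def]; its chromosome set is the anchoring
#'   whitelist.
#' @param sample_id sample name; defaults to the file name stem.
#' @param weight_by_depth if `TRUE`, read an optional integer SAM tag `dp`
#'   as a per-record tag-depth weight (records without it weigh 1). Off by
#'   default: the method counts tags, not reads.
#' @return A [tag_table] with filtering counters populated
#'   (`n_raw_alignments`, `n_retained`, and an `n_dropped` breakdown by
#'   rule: unmapped/non-primary, multimapped, unanchored, invalid position).
#' @export
filter_alignments <- function(path, genome, sample_id = NULL,
                              weight_by_depth = FALSE) {
  stopifnot(inherits(genome, "genome_def"))
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("cannot parse SAM file '", path, "': ",
                               conditionMessage(e))
    )
    on.exit(unlink(bam), add = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos"),
    tag = c("XS", "dp")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- rec$flag
  n_raw <- length(flag)
  rname <- as.character(rec$rname)
  pos <- rec$pos
  xs <- rec$tag$XS
  if (is.null(xs)) xs <- rep(NA_integer_, n_raw)
  mapped <- bitwAnd(flag, 0x4L) == 0L
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  unique_map <- is.na(xs)
  anchored <- !is.na(rname) & rname %in% genome$chrom
  valid_pos <- !is.na(pos) & pos >= 1
  # anchored chromosomes carry pos <= length by SAM validity; check anyway
  keep <- mapped & primary & unique_map & anchored & valid_pos
  w <- rep(1, sum(keep))
  if (weight_by_depth && !is.null(rec$tag$dp)) {
    dp <- rec$tag$dp[keep]
    w <- ifelse(is.na(dp) | dp < 1, 1, as.numeric(dp))
  }
  out <- tag_table(sample_id, rname[keep], pos[keep] - 1,
                   n_raw_alignments = n_raw, weight = w)
  # filtering accounting: how many mapped primaries each rule removed
  out$n_dropped <- c(
    unmapped_or_nonprimary = sum(!(mapped & primary)),
    multimapped = sum(mapped & primary & !unique_map),
    unanchored = sum(mapped & primary & unique_map & !anchored),
    invalid_pos = sum(mapped & primary & unique_map & anchored & !valid_pos))
  len <- genome$length[match(out$records$chrom, genome$chrom)]
  if (any(out$records$pos >= len))
    stop("sample ", sample_id, ": alignment position beyond chromosome end")
  out
}

#' Per-sample retained unique-tag totals
#'
#' @param tables a list of [tag_table]s.
#' @return Named integer vector of retained tag counts per sample (the
#'   quantity QC thresholds and total normalization operate on).
#' @export
count_unique_tags <- function(tables) {
  stopifnot(length(tables) > 0)
  stats::setNames(vapply(tables, function(t) t$n_retained, integer(1)),
                  vapply(tables, function(t) t$sample_id, character(1)))
}

#' Read a pre-extracted tag-position table
#'
#' Alternative input route when tags were already extracted: a TSV with
#' columns `sample`, `chrom`, `pos` (0-based). Returns one [tag_table] per
#' sample, in first-appearance order.
#'
#' @param path TSV path.
#' @return List of [tag_table]s.
#' @export
read_tag_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("tag table must have columns sample, chrom, pos")
  ids <- unique(df$sample)
  lapply(ids, function(s) {
    d <- df[df$sample == s, , drop = FALSE]
    tag_table(s, d$chrom, d$pos)
  })
}

#' Write tag-position tables and a QC summary
#'
#' @param tables list of [tag_table]s.
#' @param path output TSV (`sample`, `chrom`, `pos`).
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(tables, path) {
  rows <- lapply(tables, function(t)
    data.frame(sample = t$sample_id, chrom = t$records$chrom,
               pos = format(t$records$pos, scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
write_ingest_qc <- function(tables, path) {
  df <- data.frame(
    sample = vapply(tables, function(t) t$sample_id, character(1)),
    raw = vapply(tables, function(t) t$n_raw_alignments, integer(1)),
    retained = vapply(tables, function(t) t$n_retained, integer(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
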