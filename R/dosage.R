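#' Classify normalized tag counts into dosage classes
#'
#' Piecewise-constant mapping from the normalized tag count (disomic
#' expectation 1.0) to the integer copy-number class:
#' `[0,0.25) -> 0`, `[0.25,0.75) -> 1`, `[0.75,1.25) -> 2`,
#' `[1.25,1.75) -> 3`, `[1.75,2.25) -> 4`, `[2.25,2.75) -> 5`,
#' `[2.75,Inf) -> 6` ("6+ copies"). Intervals are lower-inclusive /
#' upper-exclusive, which makes the mapping a total partition of `[0, Inf)`;
#' boundary hits are measure-zero in practice. `NA` (no-call) propagates.
#'
#' @param value numeric vector of normalized tag counts (>= 0 or `NA`).
#' @return Integer vector of dosage classes 0-6 (`NA` for no-call).
#' @examples
#' classify_dosage(c(0.5, 1.0, 1.5, 2.0))  # 1 2 3 4
#' @export
classify_dosage <- function(value) {
  if (any(value < 0, na.rm = TRUE))
    stop("normalized tag counts must be non-negative")
  breaks <- c(0.25, 0.75, 1.25, 1.75, 2.25, 2.75)
  out <- findInterval(value, breaks, left.open = FALSE)
  as.integer(out)
}

# class boundaries exposed for plotting legends
dosage_breaks <- function() c(0, 0.25, 0.75, 1.25, 1.75, 2.25, 2.75, Inf)

#' Flag samples with too few retained tags
#'
#' Samples with very low tag totals produce unreliable karyotypes (in the
#' motivating dataset two anomalous samples carried 1,868 and 14 tags
#' against a cohort median of ~205k). Failed samples are still normalized
#' (they barely move the medians) but their calls should be treated as
#' unreliable.
#'
#' @param totals named per-sample retained-tag totals, from
#'   [count_unique_tags()].
#' @param min_tags QC threshold (default 10,000 retained tags).
#' @return Data frame `sample`, `retained_tags`, `pass`, `reason`.
#' @export
qc_samples <- function(totals, min_tags = 10000) {
  pass <- totals >= min_tags
  data.frame(
    sample = names(totals),
    retained_tags = as.integer(totals),
    pass = pass,
    reason = ifelse(pass, "",
                    sprintf("retained tags %d < min_tags %d",
                            as.integer(totals), as.integer(min_tags))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build a per-sample dosage track
#'
#' Pairs each bin with its normalized value and dosage class for one sample.
#'
#' @param norm a `norm_matrix` from [normalize_bin_medians()].
#' @param sample_id which sample.
#' @return A `dosage_track`: data frame `chrom`, `start`, `end`, `index`,
#'   `normalized`, `dosage` (with `NA` at masked bins), plus a `sample_id`
#'   attribute.
#' @export
dosage_track <- function(norm, sample_id) {
  stopifnot(inherits(norm, "norm_matrix"))
  j <- match(sample_id, norm$samples)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  v <- norm$values[, j]
  out <- data.frame(chrom = norm$bins$chrom, start = norm$bins$start,
                    end = norm$bins$end, index = norm$bins$index,
                    normalized = v, dosage = classify_dosage(v),
                    stringsAsFactors = FALSE)
  structure(out, sample_id = sample_id,
            class = c("dosage_track", "data.frame"))
}

# label for a whole-chromosome run of a given class
whole_chrom_label <- function(cls) {
  switch(as.character(cls),
         "0" = "nullisomic", "1" = "monosomic", "3" = "trisomic",
         "4" = "tetrasomic", "5" = "pentasomic", "polysomic")
}

#' Summarize a dosage track into aberration event calls
#'
#' Finds maximal runs of consecutive bins (within a chromosome) sharing a
#' dosage class other than 2. No-call bins are transparent: they bridge runs
#' of equal class but are not counted in `n_bins`. Runs shorter than
#' `min_run_length` are suppressed, which absorbs the isolated single-bin
#' noise typical around centromeres (GBS enzymes cut rarely in centromeric
#' heterochromatin, so those bins are undersampled and noisy). Surviving
#' runs are labeled: whole-chromosome runs by aneuploidy type (nullisomic /
#' monosomic / trisomic / tetrasomic), runs of class 0 or 1 touching exactly
#' one chromosome end as "terminal deletion" (class 1 annotated
#' heterozygous/single-copy), everything else "segmental". When a centromere
#' is annotated and a terminal run's interior boundary falls within one bin
#' of it, the label gains an "arm-level" annotation (the double-ditelosomic
#' pattern).
#'
#' Event coordinates are reported on the disjoint step grid (each bin
#' representing its `[start, start + step)` interval, the same reduction the
#' karyotype plot uses), so events within a sample and chromosome never
#' overlap despite the 50%-overlapping analysis windows; ends are clipped to
#' the chromosome length.
#'
#' @param track a [dosage_track()].
#' @param genome the [genome_def].
#' @param min_run_length minimum bins per reported event (default 2).
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `dosage`, `label`, `n_bins`, `terminal`, `whole_chromosome`.
#' @export
call_events <- function(track, genome, min_run_length = 2) {
  stopifnot(inherits(track, "dosage_track"), inherits(genome, "genome_def"))
  if (min_run_length < 1) stop("min_run_length must be >= 1")
  sample_id <- attr(track, "sample_id")
  out <- list()
  for (chr in unique(track$chrom)) {
    d <- track[track$chrom == chr, , drop = FALSE]
    d <- d[order(d$index), , drop = FALSE]
    step <- if (nrow(d) > 1) d$start[2] - d$start[1] else d$end[1] - d$start[1]
    len <- genome$length[match(chr, genome$chrom)]
    obs <- d[!is.na(d$dosage), , drop = FALSE]   # no-call bins transparent
    if (nrow(obs) == 0) next
    r <- rle(obs$dosage)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cen <- genome$centromere[match(chr, genome$chrom)]
    for (k in seq_along(r$values)) {
      cls <- r$values[k]
      if (cls == 2 || r$lengths[k] < min_run_length) next
      first <- obs[starts[k], ]
      last <- obs[ends[k], ]
      touch_start <- starts[k] == 1
      touch_end <- ends[k] == nrow(obs)
      whole <- touch_start && touch_end
      terminal <- touch_start || touch_end
      if (whole) {
        label <- whole_chrom_label(cls)
      } else if (terminal && cls %in% c(0, 1)) {
        label <- "terminal deletion"
        if (cls == 1) label <- paste(label, "(heterozygous/single-copy)")
        if (!is.na(cen)) {
          boundary <- if (touch_start) min(last$start + step, len)
                      else first$start
          bin_w <- stats::median(obs$end - obs$start)
          if (abs(boundary - cen) <= bin_w)
            label <- paste(label, "[arm-level]")
        }
      } else {
        label <- "segmental"
      }
      out[[length(out) + 1]] <- data.frame(
        sample = sample_id, chrom = chr,
        start = max(0, first$start),
        end = min(last$start + step, len),
        dosage = cls, label = label, n_bins = r$lengths[k],
        terminal = terminal, whole_chromosome = whole,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), dosage = integer(),
                      label = character(), n_bins = integer(),
                      terminal = logical(), whole_chromosome = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize dosage tracks and event calls
#'
#' @param track a [dosage_track()] (or list of them for `write_events`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_track <- function(track, path) {
  stopifnot(inherits(track, "dosage_track"))
  df <- data.frame(sample = attr(track, "sample_id"),
                   chrom = track$chrom,
                   start = format(track$start, scientific = FALSE, trim = TRUE),
                   end = format(track$end, scientific = FALSE, trim = TRUE),
                   normalized = track$normalized, dosage = track$dosage)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @param events event-call data frame(s) from [call_events()].
#' @rdname write_dosage_track
#' @export
write_events <- function(events, path) {
  if (is.list(events) && !is.data.frame(events))
    events <- do.call(rbind, events)
  df <- events[, c("chrom", "start", "end", "sample", "dosage", "label",
                   "n_bins", "terminal", "whole_chromosome")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
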