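#' Fit read-depth karyotypes to a GBS cohort
#'
#' The central estimator: from per-sample uniquely-mapped tag positions it
#' (1) counts tags in sliding windows (`bin_size` wide, sliding by
#' `step_size`), (2) rescales every sample to a common total, (3) divides
#' each bin by its across-sample median so the disomic expectation is 1.0,
#' (4) classifies every bin into a dosage class 0x-6x, and (5) summarizes
#' runs of aberrant bins into whole-chromosome aneuploidy and terminal /
#' segmental deletion calls. Samples with fewer than `min_tags` retained
#' tags are flagged as QC failures; they still enter the medians (their
#' influence there is negligible) but their calls are unreliable.
#'
#' The estimator assumes that at any given bin most cohort samples are
#' disomic: the per-bin median is the 2x reference. A cohort in which an
#' aberration is shared by more than half the samples will misread it.
#'
#' @param tags list of [tag_table]s (from [filter_alignments()],
#'   [read_tag_table()] or [simulate_cohort()]).
#' @param genome a [genome_def].
#' @param bin_size window width in bp (default 100 Mb).
#' @param step_size slide step in bp (default 50 Mb).
#' @param min_tags QC threshold on retained tags (default 10,000).
#' @param min_run_length minimum aberrant bins per reported event
#'   (default 2).
#' @param weight_by_depth count per-tag weights instead of records.
#' @return A `gbs_karyotype` object: list with `genome`, `bins`, `counts`
#'   (`bin_counts`), `norm` (`norm_matrix`), `dosage` (bins x samples
#'   integer matrix, `NA` = no-call), `qc`, `events`, `samples`, `params`.
#' @examples
#' g <- toy_wheat_genome(scale = 0.1)
#' specs <- c(lapply(1:5, function(i) aberration_spec(sprintf("eu%02d", i))),
#'            list(aberration_spec("mono1A", regions = data.frame(
#'              chrom = "1A", start = NA, end = NA, multiplier = 0.5),
#'              genome = g)))
#' sim <- simulate_cohort(g, specs, bins = make_bins(g, 10e6, 5e6),
#'                        site_density = 320, centromere_radius_bp = 2.5e6,
#'                        mean_tags = 2e4, seed = 42)
#' fit <- gbs_karyotype(sim$tags, g, bin_size = 10e6, step_size = 5e6,
#'                      min_tags = 1000)
#' fit
#' subset(fit$events, sample == "mono1A")
#' @export
gbs_karyotype <- function(tags, genome, bin_size = 100e6, step_size = 50e6,
                          min_tags = 10000, min_run_length = 2,
                          weight_by_depth = FALSE) {
  stopifnot(inherits(genome, "genome_def"))
  if (inherits(tags, "tag_table")) tags <- list(tags)
  if (!length(tags) || !all(vapply(tags, inherits, logical(1), "tag_table")))
    stop("tags must be a list of tag_table objects")
  bins <- make_bins(genome, bin_size, step_size)
  totals <- count_unique_tags(tags)
  qc <- qc_samples(totals, min_tags = min_tags)
  counts <- count_bins(tags, bins, genome, weight_by_depth = weight_by_depth)
  norm <- normalize_bin_medians(counts)
  dosage <- apply(norm$values, 2, classify_dosage)
  dimnames(dosage) <- list(NULL, norm$samples)
  events <- do.call(rbind, lapply(norm$samples, function(s)
    call_events(dosage_track(norm, s), genome,
                min_run_length = min_run_length)))
  rownames(events) <- NULL
  structure(list(genome = genome, bins = bins, counts = counts, norm = norm,
                 dosage = dosage, qc = qc, events = events,
                 samples = norm$samples,
                 params = list(bin_size = bin_size, step_size = step_size,
                               min_tags = min_tags,
                               min_run_length = min_run_length,
                               weight_by_depth = weight_by_depth)),
            class = "gbs_karyotype")
}

#' @export
print.gbs_karyotype <- function(x, ...) {
  cat("GBS read-depth karyotype fit\n")
  cat("  genome:    ", nrow(x$genome), "chromosomes,",
      format(sum(x$genome$length), big.mark = ","), "bp\n")
  cat("  bins:      ", nrow(x$bins), "windows of",
      format(x$params$bin_size / 1e6, trim = TRUE), "Mb, step",
      format(x$params$step_size / 1e6, trim = TRUE), "Mb;",
      sum(x$norm$mask), "masked\n")
  cat("  samples:   ", length(x$samples), "(",
      sum(!x$qc$pass), "QC-failed at min_tags =",
      format(x$params$min_tags, big.mark = ","), ")\n")
  cat("  events:    ", nrow(x$events), "aberration call(s) in",
      length(unique(x$events$sample)), "sample(s)\n")
  invisible(x)
}

#' @method summary gbs_karyotype
#' @export
summary.gbs_karyotype <- function(object, ...) {
  ev <- object$events
  per_sample <- data.frame(
    sample = object$samples,
    retained_tags = object$qc$retained_tags[
      match(object$samples, object$qc$sample)],
    qc_pass = object$qc$pass[match(object$samples, object$qc$sample)],
    n_events = vapply(object$samples,
                      function(s) sum(ev$sample == s), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_sample = per_sample, events = ev,
                 params = object$params,
                 n_masked = sum(object$norm$mask)),
            class = "summary.gbs_karyotype")
}

#' @export
print.summary.gbs_karyotype <- function(x, ...) {
  cat("Per-sample summary:\n")
  print(x$per_sample, row.names = FALSE)
  cat("\nAberration calls:\n")
  if (nrow(x$events)) {
    show <- x$events
    show$start <- round(show$start / 1e6, 1)
    show$end <- round(show$end / 1e6, 1)
    names(show)[names(show) %in% c("start", "end")] <- c("start_Mb", "end_Mb")
    print(show, row.names = FALSE)
  } else cat("  none\n")
  invisible(x)
}

#' @param x a `gbs_karyotype` fit.
#' @param sample which sample to draw (default: the first).
#' @param out_path optional image path, see [render_karyotype()].
#' @param ... passed to [render_karyotype()].
#' @rdname gbs_karyotype
#' @method plot gbs_karyotype
#' @export
plot.gbs_karyotype <- function(x, sample = x$samples[1], out_path = NULL,
                               ...) {
  render_karyotype(dosage_track(x$norm, sample), x$genome,
                   out_path = out_path, ...)
}

#' Modal dosage class of a chromosome
#'
#' The most frequent per-bin dosage class over a chromosome for one sample —
#' the statistic used to read whole-chromosome aneuploidy off a karyotype.
#' Ties break toward the class closest to 2 (call the least surprising
#' dosage).
#'
#' @param fit a `gbs_karyotype` object.
#' @param sample sample id.
#' @param chrom chromosome name.
#' @return Integer dosage class (`NA` if every bin is masked).
#' @export
modal_dosage <- function(fit, sample, chrom) {
  stopifnot(inherits(fit, "gbs_karyotype"))
  j <- match(sample, fit$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  cls <- fit$dosage[fit$bins$chrom == chrom, j]
  cls <- cls[!is.na(cls)]
  if (!length(cls)) return(NA_integer_)
  tab <- table(cls)
  cand <- as.integer(names(tab)[tab == max(tab)])
  cand[which.min(abs(cand - 2))]
}
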