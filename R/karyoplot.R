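#' Dosage color palette
#'
#' Colorblind-aware 7-class palette for dosage 0x-6x. Disomic (2x) is a
#' neutral grey so aberrations pop; deletions are warm, gains are cool.
#' No-call bins render white.
#'
#' @return Named character vector of colors for classes `0`..`6` plus
#'   `nocall`.
#' @export
dosage_palette <- function() {
  c(`0` = "#D55E00",   # vermillion: nullisomic / deleted
    `1` = "#E69F00",   # orange: single copy
    `2` = "#BFBFBF",   # grey: disomic baseline
    `3` = "#56B4E9",   # sky blue
    `4` = "#0072B2",   # blue
    `5` = "#009E73",   # green
    `6` = "#CC79A7",   # magenta: 6+ copies
    nocall = "#FFFFFF")
}

#' Non-overlapping plotting segments for a dosage track
#'
#' Reduces the 50%-overlapping analysis bins to disjoint step-sized
#' plotting intervals: interval `[k*step, (k+1)*step)` takes the class of
#' the bin starting at `k*step` when that bin exists, else of the covering
#' bin (`reduce = "start"`); `reduce = "max"` instead takes the maximum
#' class among covering bins. The returned segments tile each chromosome
#' exactly, which is asserted in tests independently of any rendering
#' backend.
#'
#' @param track a [dosage_track()].
#' @param genome the [genome_def].
#' @param reduce `"start"` (default) or `"max"`.
#' @return Data frame `chrom`, `start`, `end`, `dosage` (`NA` = no-call)
#'   with disjoint, tiling segments per chromosome.
#' @export
karyo_segments <- function(track, genome, reduce = c("start", "max")) {
  stopifnot(inherits(track, "dosage_track"), inherits(genome, "genome_def"))
  reduce <- match.arg(reduce)
  out <- list()
  for (chr in unique(track$chrom)) {
    d <- track[track$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    step <- if (nrow(d) > 1) d$start[2] - d$start[1] else d$end[1] - d$start[1]
    len <- genome$length[match(chr, genome$chrom)]
    starts <- d$start                    # bin starts are the step grid
    seg_start <- starts
    seg_end <- pmin(starts + step, len)
    cls <- vapply(seq_along(starts), function(i) {
      covering <- which(d$start <= seg_start[i] & d$end >= seg_end[i])
      if (reduce == "start") {
        exact <- covering[d$start[covering] == seg_start[i]]
        pick <- if (length(exact)) exact[1] else covering[1]
        as.numeric(d$dosage[pick])
      } else {
        v <- d$dosage[covering]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }
    }, numeric(1))
    out[[chr]] <- data.frame(chrom = chr, start = seg_start, end = seg_end,
                             dosage = as.integer(cls),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a karyotype ideogram for one sample
#'
#' One vertical bar per chromosome (ordered as in the genome definition),
#' y-axis in Mb along the chromosome, each step interval filled with its
#' dosage color; centromeres drawn as a black line with a diamond; legend
#' mapping colors to 0x-6x. Output is deterministic for fixed input.
#'
#' @param track a [dosage_track()].
#' @param genome the [genome_def].
#' @param out_path optional output file; extension selects the device
#'   (`.png`, `.pdf`, `.svg`). If `NULL`, draws on the current device.
#' @param palette color map from [dosage_palette()].
#' @param reduce overlap-reduction rule, see [karyo_segments()].
#' @param main plot title (defaults to the sample id).
#' @return The segment table used for drawing, invisibly.
#' @export
render_karyotype <- function(track, genome, out_path = NULL,
                             palette = dosage_palette(),
                             reduce = "start", main = NULL) {
  stopifnot(inherits(track, "dosage_track"))
  if (!all(unique(track$chrom) %in% genome$chrom))
    stop("track contains chromosomes absent from the genome definition")
  if (all(is.na(track$dosage)) && all(is.na(track$normalized)))
    stop("track has no classified bins; classify dosage first")
  if (!all(as.character(0:6) %in% names(palette)) ||
      !"nocall" %in% names(palette))
    stop("palette must cover classes 0-6 and 'nocall'")
  segs <- karyo_segments(track, genome, reduce = reduce)
  if (is.null(main)) main <- attr(track, "sample_id")
  dev <- NULL
  if (!is.null(out_path)) {
    ext <- tolower(tools::file_ext(out_path))
    switch(ext,
           png = grDevices::png(out_path, width = 1400, height = 700,
                                res = 110),
           pdf = grDevices::pdf(out_path, width = 12, height = 6),
           svg = grDevices::svg(out_path, width = 12, height = 6),
           stop("unsupported plot format: ", ext))
    dev <- grDevices::dev.cur()
    on.exit(grDevices::dev.off(dev), add = TRUE)
  }
  chroms <- genome$chrom[genome$chrom %in% unique(segs$chrom)]
  n <- length(chroms)
  max_mb <- max(genome$length[match(chroms, genome$chrom)]) / 1e6
  op <- graphics::par(mar = c(2.5, 4, 4, 6), xpd = NA)
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(max_mb * 1.02, 0),
                 xlab = "", ylab = "Position (Mb)", axes = FALSE,
                 main = main)
  graphics::axis(2)
  graphics::axis(3, at = seq_len(n), labels = chroms, tick = FALSE,
                 line = -0.8, cex.axis = 0.8)
  half_w <- 0.32
  for (i in seq_len(n)) {
    s <- segs[segs$chrom == chroms[i], , drop = FALSE]
    col <- ifelse(is.na(s$dosage), palette[["nocall"]],
                  palette[as.character(s$dosage)])
    graphics::rect(i - half_w, s$start / 1e6, i + half_w, s$end / 1e6,
                   col = col, border = NA)
    len <- genome$length[match(chroms[i], genome$chrom)]
    graphics::rect(i - half_w, 0, i + half_w, len / 1e6, border = "black",
                   lwd = 0.6)
    cen <- genome$centromere[match(chroms[i], genome$chrom)]
    if (!is.na(cen)) {
      graphics::segments(i - half_w, cen / 1e6, i + half_w, cen / 1e6,
                         lwd = 1.4)
      graphics::points(i, cen / 1e6, pch = 18, cex = 1.1)
    }
  }
  graphics::legend("right", inset = -0.06,
                   legend = c(paste0(0:6, "x"), "no call"),
                   fill = c(dosage_palette()[as.character(0:6)],
                            palette[["nocall"]]),
                   border = "grey40", bty = "n", cex = 0.8)
  invisible(segs)
}

#' Render karyotypes for a whole cohort
#'
#' Writes one ideogram image per sample (named by sample id) into `out_dir`
#' plus a cohort-wide event summary TSV (`events.tsv`) concatenating
#' [call_events()] output across samples.
#'
#' @param norm a `norm_matrix` for the cohort.
#' @param genome the [genome_def].
#' @param out_dir output directory (created if missing).
#' @param format image format: `"png"`, `"pdf"` or `"svg"`.
#' @param min_run_length passed to [call_events()].
#' @return Invisible list with `images` (paths) and `events` (data frame).
#' @export
render_cohort_report <- function(norm, genome, out_dir, format = "png",
                                 min_run_length = 2) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (length(norm$samples) == 0) stop("no samples to report")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  images <- character(0)
  events <- list()
  for (s in norm$samples) {
    tr <- dosage_track(norm, s)
    img <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", s),
                                     ".", format))
    render_karyotype(tr, genome, out_path = img)
    images <- c(images, img)
    events[[s]] <- call_events(tr, genome, min_run_length = min_run_length)
  }
  ev <- do.call(rbind, events)
  rownames(ev) <- NULL
  write_events(ev, file.path(out_dir, "events.tsv"))
  invisible(list(images = images, events = ev))
}
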