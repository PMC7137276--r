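#' Genome definitions and the sliding-window bin grid
#'
#' A genome definition is the coordinate frame shared by every stage of the
#' pipeline: an ordered table of chromosomes with their lengths and
#' (optionally) centromere midpoints. All internal coordinates are 0-based,
#' half-open `[start, end)`; 1-based SAM positions are converted once at the
#' ingest boundary.
#'
#' @param chrom character vector of unique, non-empty chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp (> 0).
#' @param centromere optional centromere midpoints in bp (`NA` = unknown);
#'   must satisfy `0 < centromere < length` where given.
#' @return A `genome_def`: a data frame with columns `chrom`, `length`,
#'   `centromere`, preserving the input order.
#' @examples
#' genome_def(c("1A", "1B"), c(594102056, 689851870), c(213e6, 240e6))
#' @export
genome_def <- function(chrom, length, centromere = NA_real_) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere <- rep_len(as.numeric(centromere), base::length(chrom))
  if (base::length(chrom) == 0L)
    stop("genome definition needs at least one chromosome")
  if (anyNA(chrom) || any(!nzchar(chrom)))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name(s): ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (anyNA(length) || any(length <= 0))
    stop("chromosome lengths must be positive")
  bad <- !is.na(centromere) & (centromere <= 0 | centromere >= length)
  if (any(bad))
    stop("centromere outside (0, length) for: ",
         paste(chrom[bad], collapse = ", "))
  structure(
    data.frame(chrom = chrom, length = length, centromere = centromere,
               stringsAsFactors = FALSE),
    class = c("genome_def", "data.frame")
  )
}

#' Read a genome definition table
#'
#' Parses a tab-separated file with header columns `chrom`, `length`,
#' `centromere` (the centromere column may be empty or absent). Lines
#' starting with `#` are ignored. Chromosome order in the file is preserved
#' and defines plotting / output order everywhere downstream; the set of
#' chromosome names is also the whitelist used to drop alignments to
#' unanchored scaffolds.
#'
#' @param path path to the TSV file.
#' @return A [genome_def] object.
#' @export
read_genome <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse genome definition '", path, "': ",
                             conditionMessage(e))
  )
  need <- c("chrom", "length")
  if (!all(need %in% names(df)))
    stop("genome definition must have columns 'chrom' and 'length'")
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len)) {
    bad <- which(is.na(len))[1]
    stop("malformed length at data row ", bad, " of '", path, "'")
  }
  cen <- if ("centromere" %in% names(df)) {
    raw <- df$centromere
    out <- suppressWarnings(as.numeric(raw))
    blank <- is.na(raw) | !nzchar(trimws(raw))
    if (any(is.na(out) & !blank)) {
      bad <- which(is.na(out) & !blank)[1]
      stop("malformed centromere at data row ", bad, " of '", path, "'")
    }
    out
  } else NA_real_
  genome_def(df$chrom, len, cen)
}

#' Write a genome definition table
#' @param genome a [genome_def].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_def"))
  df <- as.data.frame(genome)
  df$length <- format(df$length, scientific = FALSE, trim = TRUE)
  df$centromere <- ifelse(is.na(df$centromere), "",
                          format(df$centromere, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the sliding-window bin grid
#'
#' Tiles every chromosome with windows of width `bin_size` starting at
#' 0, `step_size`, 2*`step_size`, ... for every start strictly below the
#' chromosome length; a window extending past the end is truncated to the
#' chromosome length. With the defaults (100 Mb windows sliding by 50 Mb)
#' every position is covered by one or two windows. Terminal short windows
#' are kept: the per-bin median normalization cancels their smaller expected
#' counts across samples.
#'
#' @param genome a [genome_def].
#' @param bin_size window width in bp (default 100 Mb).
#' @param step_size slide step in bp (default 50 Mb); `0 < step <= bin`.
#' @return A `karyo_bins` data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `index` (0-based ordinal within chromosome),
#'   ordered by genome chromosome order then start; `bin_size` and
#'   `step_size` are stored as attributes.
#' @examples
#' g <- genome_def("chr1", 250e6)
#' make_bins(g)  # 5 bins: starts 0, 50, 100, 150, 200 Mb
#' @export
make_bins <- function(genome, bin_size = 100e6, step_size = 50e6) {
  stopifnot(inherits(genome, "genome_def"))
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0")
  if (!is.numeric(step_size) || step_size <= 0 || step_size > bin_size)
    stop("step_size must satisfy 0 < step_size <= bin_size")
  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1e-9, by = step_size)
    starts <- starts[starts < len]
    data.frame(chrom = genome$chrom[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               index = seq_along(starts) - 1L,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  rownames(bins) <- NULL
  structure(bins, bin_size = bin_size, step_size = step_size,
            class = c("karyo_bins", "data.frame"))
}

#' Export the bin grid as BED
#'
#' BED3 plus a fourth column carrying the within-chromosome bin index, for
#' auditing the grid against other tools.
#'
#' @param bins a `karyo_bins` grid from [make_bins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  stopifnot(inherits(bins, "karyo_bins"))
  df <- data.frame(bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE),
                   bins$index)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of the bin grid (1-based closed intervals for IRanges).
bins_to_granges <- function(bins, genome) {
  GenomicRanges::GRanges(
    seqnames = factor(bins$chrom, levels = genome$chrom),
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}

#' Toy wheat-like genome for simulation and examples
#'
#' A 21-chromosome hexaploid-wheat-like genome (1A..7D) with realistic
#' relative chromosome lengths (roughly 470-830 Mb at full scale) and
#' centromeres placed at 40-48% of each chromosome. `scale` shrinks all
#' coordinates, e.g. `scale = 0.1` gives a 1:10 genome suited to fast
#' simulations with 10 Mb / 5 Mb bins.
#'
#' @param scale multiplicative coordinate scale (default 1).
#' @return A [genome_def].
#' @export
toy_wheat_genome <- function(scale = 1) {
  stopifnot(is.numeric(scale), scale > 0)
  nm <- paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  len <- c(594, 689, 495, 781, 801, 651, 750, 830, 615, 744, 673, 509,
           709, 713, 566, 618, 720, 473, 736, 750, 638) * 1e6
  frac <- rep(c(0.36, 0.42, 0.47), 7)  # varied metacentric positions
  genome_def(nm, round(len * scale), round(len * frac * scale))
}
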